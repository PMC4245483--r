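## Variant calling and classification from pairwise alignments, using
## event-level counting: a maximal run of contiguous mismatch columns is one
## SNP (length 1) or one multi-nucleotide variant (MNV, length >= 2); a
## maximal gap run in the query is one deletion and in the reference one
## insertion. Each event counts once regardless of its length. Columns
## containing the ambiguity code N never contribute to any variant or
## difference.

column_classes <- function(rv, qv) {
  cls <- character(length(rv))
  gr <- rv == "-"; gq <- qv == "-"
  if (any(gr & gq)) abort("alignment contains a gap/gap column")
  hasN <- rv == "N" | qv == "N"
  cls[!gr & !gq & rv == qv] <- "match"
  cls[!gr & !gq & rv != qv] <- "mismatch"
  cls[gr] <- "insertion"
  cls[gq] <- "deletion"
  cls[hasN & !gr & !gq] <- "match"      # N: no evidence of difference
  cls
}

#' Call variants from a pairwise alignment
#'
#' Scans alignment columns and emits one event per maximal run: mismatch
#' runs become SNPs (length 1) or MNVs (length >= 2), query gap runs
#' deletions, reference gap runs insertions. Indels abutting mismatch runs
#' are separate events, never merged. Positions are 1-based on the
#' degapped reference; an insertion is placed at the position of the first
#' reference base after the inserted material.
#'
#' @param pair one or more rows from [align_pair()].
#' @return a tibble: `ref_id`, `qry_id`, `type` (`SNP`, `MNV`,
#'   `insertion`, `deletion`), `ref_position`, `ref_allele`, `alt_allele`,
#'   `length`. Empty alleles denote pure insertions/deletions.
#' @export
call_variants <- function(pair) {
  check_pair_alignment(pair)
  out <- lapply(seq_len(nrow(pair)), function(r) {
    v <- call_variants_one(pair$ref_aln[r], pair$qry_aln[r])
    if (nrow(v)) {
      v$ref_id <- pair$ref_id[r]; v$qry_id <- pair$qry_id[r]
    } else {
      v$ref_id <- character(0); v$qry_id <- character(0)
    }
    v
  })
  dplyr::bind_rows(out) |>
    dplyr::relocate("ref_id", "qry_id")
}

call_variants_one <- function(raln, qaln) {
  rv <- seq_chars(raln); qv <- seq_chars(qaln)
  cls <- column_classes(rv, qv)
  refpos <- cumsum(rv != "-")
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "match"
  if (!any(keep)) {
    return(tibble(type = character(0), ref_position = integer(0),
                  ref_allele = character(0), alt_allele = character(0),
                  length = integer(0)))
  }
  starts <- starts[keep]; ends <- ends[keep]; what <- r$values[keep]
  mk <- function(i) {
    s <- starts[i]; e <- ends[i]; len <- e - s + 1L
    switch(what[i],
      mismatch = tibble(type = if (len == 1L) "SNP" else "MNV",
                        ref_position = refpos[s],
                        ref_allele = paste0(rv[s:e], collapse = ""),
                        alt_allele = paste0(qv[s:e], collapse = ""),
                        length = len),
      deletion = tibble(type = "deletion", ref_position = refpos[s],
                        ref_allele = paste0(rv[s:e], collapse = ""),
                        alt_allele = "", length = len),
      insertion = tibble(type = "insertion",
                         ref_position = refpos[s] + 1L,
                         ref_allele = "",
                         alt_allele = paste0(qv[s:e], collapse = ""),
                         length = len))
  }
  dplyr::bind_rows(lapply(seq_along(starts), mk)) |>
    dplyr::arrange(.data$ref_position)
}

#' Classify SNPs as transitions or transversions
#'
#' A\eqn{\leftrightarrow}G and C\eqn{\leftrightarrow}T exchanges are
#' transitions; every other base exchange is a transversion.
#'
#' @param ref,alt single-base character vectors (recycled together).
#' @return character vector of `"transition"` / `"transversion"`.
#' @export
classify_ts_tv <- function(ref, alt) {
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L) ||
      any(ref == alt) ||
      any(!ref %in% DNA_BASES) || any(!alt %in% DNA_BASES)) {
    abort("classify_ts_tv() expects single-base SNP alleles",
          class = "plastocmp_not_snp")
  }
  purine <- c("A", "G")
  same_class <- (ref %in% purine) == (alt %in% purine)
  ifelse(same_class, "transition", "transversion")
}

#' Per-pair variant summary
#'
#' Event counts by type plus the transition/transversion split of the
#' SNPs, one row per (reference, query) pair.
#'
#' @param variants tibble from [call_variants()].
#' @return a tibble: `ref_id`, `qry_id`, `n_variants`, `n_deletions`,
#'   `n_insertions`, `n_mnv`, `n_snp`, `n_transitions`, `n_transversions`.
#' @export
variant_summary <- function(variants) {
  variants |>
    dplyr::group_by(.data$ref_id, .data$qry_id) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_deletions = sum(.data$type == "deletion"),
      n_insertions = sum(.data$type == "insertion"),
      n_mnv = sum(.data$type == "MNV"),
      n_snp = sum(.data$type == "SNP"),
      n_transitions = {
        idx <- .data$type == "SNP"
        if (!any(idx)) 0L else {
          sum(classify_ts_tv(.data$ref_allele[idx],
                             .data$alt_allele[idx]) == "transition")
        }
      },
      n_transversions = .data$n_snp - .data$n_transitions,
      .groups = "drop")
}

#' Count nucleotide differences in a pairwise alignment
#'
#' The number of alignment columns at which the two rows differ; every gap
#' column counts as one non-identical base. Columns containing N never
#' contribute.
#'
#' @param pair one or more rows from [align_pair()].
#' @return integer vector, one count per row of `pair`.
#' @export
nucleotide_differences <- function(pair) {
  check_pair_alignment(pair)
  vapply(seq_len(nrow(pair)), function(r) {
    cls <- column_classes(seq_chars(pair$ref_aln[r]),
                          seq_chars(pair$qry_aln[r]))
    sum(cls != "match")
  }, integer(1))
}

#' All-pairs distance table
#'
#' Aligns every pair of genomes and reports both distance definitions:
#' the number of variant events (each event counted once regardless of
#' length) and the number of nucleotide differences (non-identical bases,
#' gap columns included). By default distances are computed on IR-reduced
#' sequences so inverted-repeat events are counted once.
#'
#' @param plastomes plastome tibble (>= 2 rows).
#' @param reduce_ir detect the quadripartite structure and drop one IR
#'   copy before aligning.
#' @param min_ir_length passed to [detect_quadripartite()].
#' @param scoring,method,k passed to [align_pair()].
#' @return a tibble: `taxon_a`, `taxon_b`, `n_variants`,
#'   `n_nucleotide_differences`, one row per unordered pair.
#' @export
distance_matrices <- function(plastomes, reduce_ir = TRUE,
                              min_ir_length = 1000L,
                              scoring = default_scoring(),
                              method = c("auto", "anchored", "full"),
                              k = 21L) {
  method <- match.arg(method)
  check_plastomes(plastomes)
  if (nrow(plastomes) < 2L) {
    abort("need at least two genomes for a distance matrix")
  }
  if (reduce_ir) {
    quad <- detect_quadripartite(plastomes, min_ir_length)
    plastomes <- reduce_single_ir(plastomes, quad)
  }
  prs <- utils::combn(plastomes$id, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(cidx) {
    a <- prs[1, cidx]; b <- prs[2, cidx]
    pa <- align_pair(plastomes, a, b, scoring, method, k)
    tibble(taxon_a = a, taxon_b = b,
           n_variants = nrow(call_variants(pa)),
           n_nucleotide_differences = nucleotide_differences(pa))
  })
  dplyr::bind_rows(rows)
}

#' Distance table to symmetric matrix
#'
#' @param distances tibble from [distance_matrices()].
#' @param metric `"variants"` or `"nucleotide_differences"`.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
as_dist_matrix <- function(distances,
                           metric = c("variants",
                                      "nucleotide_differences")) {
  metric <- match.arg(metric)
  col <- if (metric == "variants") "n_variants" else
    "n_nucleotide_differences"
  ids <- unique(c(distances$taxon_a, distances$taxon_b))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(distances))) {
    m[distances$taxon_a[r], distances$taxon_b[r]] <- distances[[col]][r]
    m[distances$taxon_b[r], distances$taxon_a[r]] <- distances[[col]][r]
  }
  m
}

#' Assign variants to genomic regions
#'
#' Each variant is assigned by its reference start position to one of
#' coding, intron or intergenic (exons of any gene category count as
#' coding).
#'
#' @param variants tibble from [call_variants()] in reference coordinates.
#' @param features feature tibble for the reference genome.
#' @param genome_length length of the reference genome.
#' @return a tibble: `region`, `n`, `proportion` (proportions sum to 1).
#' @export
region_distribution <- function(variants, features, genome_length) {
  lab <- region_labels(features, genome_length)
  lab[lab %in% c("protein_coding", "tRNA", "rRNA")] <- "coding"
  pos <- variants$ref_position
  if (any(pos < 1L | pos > genome_length)) {
    abort("variant position outside the genome")
  }
  reg <- factor(lab[pos], levels = c("coding", "intron", "intergenic"))
  tab <- table(reg)
  tibble(region = names(tab), n = as.integer(tab),
         proportion = as.numeric(tab) / max(1L, length(pos)))
}

#' Write variants as minimal VCF v4.2
#'
#' Indels are anchored on the previous reference base per VCF convention;
#' the event-level (empty-allele) representation is preserved in the
#' native TSV written by [write_variant_table()].
#'
#' @param variants tibble from [call_variants()] (single reference).
#' @param ref_genome one-row plastome tibble for the reference taxon.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, ref_genome, path) {
  seq <- ref_genome$sequence
  chrom <- ref_genome$id
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(seq)),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt <- function(r) {
    pos <- variants$ref_position[r]
    ref <- variants$ref_allele[r]; alt <- variants$alt_allele[r]
    type <- variants$type[r]
    if (type %in% c("insertion", "deletion")) {
      anchor_at <- if (type == "insertion") pos - 1L else pos - 1L
      if (anchor_at >= 1L) {
        anchor <- substr(seq, anchor_at, anchor_at)
        pos <- anchor_at
        ref <- paste0(anchor, ref); alt <- paste0(anchor, alt)
      } else {  # event at position 1: anchor on the following base
        nxt <- substr(seq, pos + nchar(ref), pos + nchar(ref))
        ref <- paste0(ref, nxt); alt <- paste0(alt, nxt)
      }
    }
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=%s;QRY=%s",
            chrom, pos, ref, alt, type, variants$qry_id[r])
  }
  body <- vapply(seq_len(nrow(variants)), fmt, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write the native event-level variant table
#'
#' @param variants tibble from [call_variants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
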