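## Coding-effect prediction. Coding substitutions are evaluated at the
## codon level on the exon-concatenated, strand-corrected CDS and
## translated with the plastid/bacterial genetic code (translation table
## 11); MNVs inside one codon are evaluated as a unit. Coding indels whose
## length is not a multiple of 3 are frameshifts, with the truncated
## protein length measured up to (excluding) the first in-frame stop of
## the shifted sequence.

genetic_code_table <- function(code = "11") {
  Biostrings::getGeneticCode(code)
}

translate_cds <- function(cds, gc) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

## transcription-ordered genome positions of a gene copy's CDS
cds_positions <- function(fx) {
  fx <- fx[order(fx$exon), , drop = FALSE]
  unlist(lapply(seq_len(nrow(fx)), function(r) {
    if (fx$strand[r] == "+") fx$start[r]:fx$end[r] else fx$end[r]:fx$start[r]
  }), use.names = FALSE)
}

cds_sequence <- function(fx, genome) {
  pos <- cds_positions(fx)
  ch <- seq_chars(genome)[pos]
  if (fx$strand[1] == "-") ch <- COMPLEMENT[ch]
  paste0(ch, collapse = "")
}

owner_map <- function(features, genome_length) {
  owner <- rep(NA_character_, genome_length)
  for (r in seq_len(nrow(features))) {
    owner[features$start[r]:features$end[r]] <- features$gene_id[r]
  }
  owner
}

#' Predict coding consequences of variants
#'
#' For each variant in reference coordinates: substitutions inside a
#' protein-coding exon are classified synonymous or non-synonymous by
#' rebuilding and translating the affected codon(s); coding indels of
#' length not divisible by 3 are frameshifts with the truncated protein
#' length; everything else has effect `none`. Variants spanning an exon
#' boundary are flagged composite rather than silently dropped.
#'
#' @param variants tibble from [call_variants()] against one reference.
#' @param features feature tibble for the reference genome.
#' @param ref_genome one-row plastome tibble for the reference taxon.
#' @param code NCBI genetic code id; `"11"` (bacterial/plastid) by
#'   default.
#' @return a tibble: the variant columns plus `gene`, `gene_id`, `copy`,
#'   `region`, `effect` (`synonymous`, `nonsynonymous`, `frameshift`,
#'   `none`), `aa_position`, `aa_ref`, `aa_alt`, `truncated_length`,
#'   `composite`, `note`.
#' @export
variant_effect <- function(variants, features, ref_genome, code = "11") {
  check_features(features)
  gc <- genetic_code_table(code)
  genome <- ref_genome$sequence
  L <- nchar(genome)
  lab <- region_labels(features, L)
  own <- owner_map(features, L)
  gene_tbl <- features |>
    dplyr::distinct(.data$gene_id, .data$gene, .data$category, .data$copy)
  cds_cache <- new.env(parent = emptyenv())
  get_cds <- function(gid) {
    if (!is.null(cds_cache[[gid]])) return(cds_cache[[gid]])
    fx <- features[features$gene_id == gid, , drop = FALSE]
    val <- list(fx = fx, pos = cds_positions(fx),
                cds = cds_sequence(fx, genome))
    cds_cache[[gid]] <- val
    val
  }
  rows <- lapply(seq_len(nrow(variants)), function(r) {
    variant_effect_one(variants[r, ], lab, own, gene_tbl, get_cds, gc,
                       genome)
  })
  dplyr::bind_cols(variants, dplyr::bind_rows(rows))
}

blank_effect <- function(region = "intergenic", effect = "none",
                         gene = NA_character_, gene_id = NA_character_,
                         copy = NA_character_, aa_position = NA_integer_,
                         aa_ref = NA_character_, aa_alt = NA_character_,
                         truncated_length = NA_integer_,
                         composite = FALSE, note = NA_character_) {
  tibble(gene = gene, gene_id = gene_id, copy = copy, region = region,
         effect = effect, aa_position = aa_position, aa_ref = aa_ref,
         aa_alt = aa_alt, truncated_length = truncated_length,
         composite = composite, note = note)
}

variant_effect_one <- function(v, lab, own, gene_tbl, get_cds, gc,
                               genome) {
  p <- v$ref_position
  if (p < 1L || p > length(lab)) abort("variant position outside genome")
  span <- if (v$type %in% c("SNP", "MNV", "deletion")) {
    p:(p + v$length - 1L)
  } else p
  regions <- lab[span]
  region0 <- regions[1]
  if (region0 == "intron") return(blank_effect("intron"))
  if (region0 == "intergenic") return(blank_effect("intergenic"))
  gid <- own[p]
  info <- gene_tbl[gene_tbl$gene_id == gid, ]
  base <- blank_effect("coding", gene = info$gene, gene_id = gid,
                       copy = info$copy)
  if (info$category != "protein_coding") return(base)
  cdsinfo <- get_cds(gid)
  if (v$type %in% c("SNP", "MNV")) {
    ci <- match(span, cdsinfo$pos)
    if (anyNA(ci) || length(unique(own[span])) != 1L) {
      base$composite <- TRUE
      base$note <- "spans exon boundary; composite effect"
      return(base)
    }
    alt <- seq_chars(v$alt_allele)
    if (cdsinfo$fx$strand[1] == "-") alt <- COMPLEMENT[alt]
    mut <- seq_chars(cdsinfo$cds)
    mut[ci] <- alt
    codons <- sort(unique((ci - 1L) %/% 3L + 1L))
    ref_aa <- vapply(codons, function(cd) {
      gc[[substr(cdsinfo$cds, 3L * cd - 2L, 3L * cd)]]
    }, character(1))
    alt_aa <- vapply(codons, function(cd) {
      gc[[paste0(mut[(3L * cd - 2L):(3L * cd)], collapse = "")]]
    }, character(1))
    diffat <- which(ref_aa != alt_aa)
    if (length(diffat) == 0L) {
      base$effect <- "synonymous"
      base$aa_position <- codons[1]
      base$aa_ref <- ref_aa[1]; base$aa_alt <- alt_aa[1]
    } else {
      base$effect <- "nonsynonymous"
      base$aa_position <- codons[diffat[1]]
      base$aa_ref <- ref_aa[diffat[1]]; base$aa_alt <- alt_aa[diffat[1]]
      if (length(diffat) > 1L) base$note <- "multiple codons changed"
    }
    return(base)
  }
  # indel
  if (v$length %% 3L == 0L) {
    base$note <- "in-frame indel"
    return(base)
  }
  mutated <- mutate_cds_indel(v, cdsinfo, own)
  if (is.null(mutated)) {
    base$composite <- TRUE
    base$note <- "indel spans exon boundary; composite effect"
    return(base)
  }
  base$effect <- "frameshift"
  prot <- translate_cds(mutated, gc)
  stop_at <- regexpr("*", prot, fixed = TRUE)
  if (stop_at > 0L) {
    base$truncated_length <- as.integer(stop_at) - 1L
  } else {
    base$note <- "no stop codon in shifted frame"
  }
  base
}

## apply a coding indel to the CDS; NULL when it crosses an exon boundary
mutate_cds_indel <- function(v, cdsinfo, own) {
  strand <- cdsinfo$fx$strand[1]
  cds <- cdsinfo$cds
  if (v$type == "deletion") {
    span <- v$ref_position:(v$ref_position + v$length - 1L)
    ci <- match(span, cdsinfo$pos)
    if (anyNA(ci)) return(NULL)
    keep <- setdiff(seq_len(nchar(cds)), ci)
    return(paste0(seq_chars(cds)[keep], collapse = ""))
  }
  # insertion before reference position p (genome orientation)
  p <- v$ref_position
  ins <- v$alt_allele
  if (strand == "+") {
    cp <- match(p, cdsinfo$pos)
    if (is.na(cp)) return(NULL)
    paste0(substr(cds, 1L, cp - 1L), ins, substr(cds, cp, nchar(cds)))
  } else {
    # transcript runs on descending genome coordinates: the gap between
    # p-1 and p follows the transcript position of p
    cp <- match(p, cdsinfo$pos)
    if (is.na(cp)) return(NULL)
    paste0(substr(cds, 1L, cp), revcomp(ins),
           substr(cds, cp + 1L, nchar(cds)))
  }
}

#' Summarise coding effects per pair
#'
#' @param effects tibble from [variant_effect()].
#' @return a tibble per (`ref_id`, `qry_id`): `n_synonymous`,
#'   `n_nonsynonymous`, `n_frameshift`.
#' @export
effect_summary <- function(effects) {
  if (nrow(effects) == 0L) {
    return(tibble(ref_id = character(0), qry_id = character(0),
                  n_synonymous = integer(0), n_nonsynonymous = integer(0),
                  n_frameshift = integer(0)))
  }
  effects |>
    dplyr::group_by(.data$ref_id, .data$qry_id) |>
    dplyr::summarise(
      n_synonymous = sum(.data$effect == "synonymous"),
      n_nonsynonymous = sum(.data$effect == "nonsynonymous"),
      n_frameshift = sum(.data$effect == "frameshift"),
      .groups = "drop")
}

#' Build a per-event allele table
#'
#' Expands substitutions to one row per reference position and keeps
#' indels as events, then records every taxon's allele at every key
#' (taxa without a variant carry the reference allele). The reference
#' taxon itself is included.
#'
#' @param variants tibble from [call_variants()], one reference, several
#'   queries.
#' @param ref_id the reference taxon id.
#' @param taxa taxon ids the table must cover (defaults to reference +
#'   queries present).
#' @return a tibble: `key`, `position`, `kind`, `taxon`, `allele`.
#' @export
build_allele_table <- function(variants, ref_id,
                               taxa = union(ref_id,
                                            unique(variants$qry_id))) {
  subs <- variants[variants$type %in% c("SNP", "MNV"), , drop = FALSE]
  sub_rows <- if (nrow(subs)) {
    dplyr::bind_rows(lapply(seq_len(nrow(subs)), function(r) {
      off <- seq_len(subs$length[r]) - 1L
      tibble(position = subs$ref_position[r] + off,
             kind = "substitution",
             ref = seq_chars(subs$ref_allele[r]),
             taxon = subs$qry_id[r],
             allele = seq_chars(subs$alt_allele[r]))
    }))
  } else {
    tibble(position = integer(0), kind = character(0), ref = character(0),
           taxon = character(0), allele = character(0))
  }
  ind <- variants[variants$type %in% c("insertion", "deletion"), ,
                  drop = FALSE]
  ind_rows <- if (nrow(ind)) {
    tibble(position = ind$ref_position,
           kind = ind$type,
           ref = ifelse(ind$type == "deletion", ind$ref_allele, ""),
           taxon = ind$qry_id,
           allele = ifelse(ind$type == "deletion", "del",
                           ind$alt_allele))
  } else {
    tibble(position = integer(0), kind = character(0), ref = character(0),
           taxon = character(0), allele = character(0))
  }
  ev <- dplyr::bind_rows(sub_rows, ind_rows) |>
    dplyr::mutate(key = paste(.data$kind, .data$position, .data$ref,
                              sep = ":"))
  if (nrow(ev) == 0L) {
    return(tibble(key = character(0), position = integer(0),
                  kind = character(0), taxon = character(0),
                  allele = character(0)))
  }
  keys <- ev |> dplyr::distinct(.data$key, .data$position, .data$kind,
                                .data$ref)
  full <- tidyr::crossing(keys, taxon = taxa) |>
    dplyr::left_join(ev |> dplyr::select("key", "taxon", "allele"),
                     by = c("key", "taxon")) |>
    dplyr::mutate(allele = dplyr::coalesce(.data$allele, .data$ref)) |>
    dplyr::select("key", "position", "kind", "taxon", "allele") |>
    dplyr::arrange(.data$position, .data$key, .data$taxon)
  full
}

#' Partition variant positions by clade
#'
#' A key is clade-specific when every member of one clade carries one
#' allele and every member of the other clade a different allele; the
#' focal taxon is counted with the clade whose allele it shares, and the
#' key is labelled after the clade whose shared allele differs from the
#' focal taxon's. A key is focal-unique when the focal taxon's allele
#' occurs in no other taxon. The two kinds of sets are disjoint
#' (focal-unique takes precedence).
#'
#' @param allele_tbl tibble from [build_allele_table()].
#' @param clade_map tibble with columns `id`, `clade` assigning every
#'   non-focal taxon to one of exactly two clades (exclude the outgroup).
#' @param focal id of the focal taxon (the reference the variants were
#'   called against).
#' @return a tibble: `key`, `position`, `kind`, `set`, `focal_allele`,
#'   plus one allele column per clade. Keys with missing taxa are skipped
#'   with a warning; the number skipped is in attribute `n_skipped`.
#' @export
clade_partition <- function(allele_tbl, clade_map, focal) {
  clades <- unique(clade_map$clade)
  if (length(clades) != 2L) abort("`clade_map` must define exactly 2 clades")
  need_taxa <- c(focal, clade_map$id)
  out <- list(); skipped <- 0L
  for (k in unique(allele_tbl$key)) {
    at <- allele_tbl[allele_tbl$key == k, , drop = FALSE]
    if (!all(need_taxa %in% at$taxon)) {
      skipped <- skipped + 1L
      next
    }
    al <- setNames(at$allele, at$taxon)
    af <- al[[focal]]
    a1 <- unique(al[clade_map$id[clade_map$clade == clades[1]]])
    a2 <- unique(al[clade_map$id[clade_map$clade == clades[2]]])
    others <- al[setdiff(names(al), focal)]
    set <- NA_character_
    if (!af %in% others) {
      set <- "focal_unique"
    } else if (length(a1) == 1L && length(a2) == 1L && a1 != a2) {
      deviating <- if (af == a1) clades[2] else clades[1]
      set <- paste0(deviating, "_specific")
    }
    if (!is.na(set)) {
      out[[length(out) + 1L]] <- tibble(
        key = k, position = at$position[1], kind = at$kind[1], set = set,
        focal_allele = af,
        !!clades[1] := paste(a1, collapse = "/"),
        !!clades[2] := paste(a2, collapse = "/"))
    }
  }
  if (skipped > 0L) {
    warn(sprintf("%d positions skipped (missing taxa)", skipped))
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(key = character(0), position = integer(0), kind = character(0),
           set = character(0), focal_allele = character(0))
  attr(res, "n_skipped") <- skipped
  res
}
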