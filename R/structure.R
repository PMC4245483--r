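## Quadripartite structure: detection of the two inverted repeats (IRs), the
## large and small single-copy regions (LSC/SSC), IR reduction, and
## composition / gene-inventory summaries.

kmer_starts <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

## Find the maximal pair of disjoint segments of `seq` that are exact
## reverse complements of each other. Returns NULL or list(a1,a2,b1,b2)
## with a2 < b1 on the linear sequence.
find_best_ir_pair <- function(seq, min_ir_length, k = 31L) {
  L <- nchar(seq)
  if (L < 2L * k) return(NULL)
  rc <- revcomp(seq)
  ks <- kmer_starts(seq, k)
  kr <- kmer_starts(rc, k)
  uS <- !(duplicated(ks) | duplicated(ks, fromLast = TRUE))
  uR <- !(duplicated(kr) | duplicated(kr, fromLast = TRUE))
  posS <- which(uS)
  posR <- which(uR)
  hit <- match(ks[posS], kr[posR])
  ok <- !is.na(hit)
  if (!any(ok)) return(NULL)
  i <- posS[ok]                      # k-mer start in seq
  j <- posR[hit[ok]]                 # k-mer start in revcomp(seq)
  # partner occurrence in seq coordinates: starts at L - j - k + 2; keep
  # only the left-hand member of each mirrored pair
  jp <- L - j - k + 2L
  keep <- i < jp
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(NULL)
  # the partner occurrence in seq coordinates ends at L - j + 1
  anti <- i + (L - j + 1L)           # constant along a palindromic run
  best <- NULL
  for (d in unique(anti)) {
    ii <- i[anti == d]
    a1 <- min(ii); a2 <- max(ii) + k - 1L
    b1 <- d - a2; b2 <- d - a1
    # extend outward while still an exact reverse-complement pair
    while (a1 > 1L && b2 < L && a2 + 1L < b1 &&
           substr(seq, a1 - 1L, a1 - 1L) ==
           COMPLEMENT[[substr(seq, b2 + 1L, b2 + 1L)]]) {
      a1 <- a1 - 1L; b2 <- b2 + 1L
    }
    while (a2 + 1L < b1 - 1L &&
           substr(seq, a2 + 1L, a2 + 1L) ==
           COMPLEMENT[[substr(seq, b1 - 1L, b1 - 1L)]]) {
      a2 <- a2 + 1L; b1 <- b1 - 1L
    }
    len <- a2 - a1 + 1L
    if (a2 >= b1) next               # overlapping pair: not quadripartite
    if (is.null(best) || len > best$len) {
      best <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, len = len)
    }
  }
  if (is.null(best) || best$len < min_ir_length) return(NULL)
  best
}

rotate_seq <- function(seq, offset) {
  # new sequence starts at position offset + 1 of the old one
  L <- nchar(seq)
  offset <- offset %% L
  if (offset == 0L) return(seq)
  paste0(substr(seq, offset + 1L, L), substr(seq, 1L, offset))
}

#' Detect the quadripartite plastome structure
#'
#' Locates the maximal pair of disjoint segments that are exact reverse
#' complements of each other (the inverted repeats IR\eqn{_A} and
#' IR\eqn{_B}), then labels the shorter inter-repeat arc as the small
#' single-copy region (SSC) and the longer as the large single-copy region
#' (LSC). Intervals are reported 1-based inclusive on a linearisation that
#' starts at LSC position 1.
#'
#' Exact identity of the repeats is required by default: plastid IRs are
#' perfect repeats, and the detector's contract is exactness. Input is
#' assumed already linearised with neither IR wrapping the origin; set
#' `rotate = TRUE` to search start-point rotations of the circular molecule
#' when that assumption may not hold.
#'
#' @param plastomes plastome tibble (see [read_plastomes()]); one row per
#'   taxon.
#' @param min_ir_length smallest acceptable repeat length in bases. The
#'   default 1000 is far above tRNA-scale repeats and far below the
#'   20--26 kb IRs of plastomes.
#' @param rotate try start-point rotations of the circular genome.
#' @return a tibble with one row per taxon: `id`, `lsc_start`, `lsc_end`,
#'   `ira_start`, `ira_end`, `ssc_start`, `ssc_end`, `irb_start`,
#'   `irb_end`, `ir_length`, `offset` (rotation applied to the input to
#'   obtain the LSC-first linearisation).
#' @export
detect_quadripartite <- function(plastomes, min_ir_length = 1000L,
                                 rotate = FALSE) {
  check_plastomes(plastomes)
  rows <- lapply(seq_len(nrow(plastomes)), function(r) {
    detect_quadripartite_one(plastomes$id[r], plastomes$sequence[r],
                             min_ir_length, rotate)
  })
  dplyr::bind_rows(rows)
}

detect_quadripartite_one <- function(id, seq, min_ir_length, rotate) {
  L <- nchar(seq)
  if (L <= 2L * min_ir_length) {
    abort(sprintf("sequence '%s' shorter than 2 * min_ir_length", id))
  }
  offsets <- 0L
  if (rotate) offsets <- as.integer(floor((0:11) * L / 12))
  found <- NULL
  for (off in offsets) {
    s <- rotate_seq(seq, off)
    pair <- find_best_ir_pair(s, min_ir_length)
    if (!is.null(pair) && (is.null(found) || pair$len > found$pair$len)) {
      found <- list(off = off, seq = s, pair = pair)
    }
  }
  if (is.null(found)) {
    abort(sprintf("no inverted repeat >= %d bp found in '%s'",
                  min_ir_length, id),
          class = "plastocmp_structure_not_found")
  }
  p <- found$pair
  s <- found$seq
  # two arcs between the repeats on the circle: (a2, b1) and (b2, a1 + L)
  arc1 <- p$b1 - p$a2 - 1L                 # between IR pair, inside
  arc2 <- L - (p$b2 - p$a1 + 1L)           # around the origin
  if (arc1 == arc2 && arc1 > 0L) {
    abort(sprintf("ambiguous quadripartite structure in '%s': arcs of equal length", id),
          class = "plastocmp_structure_ambiguous")
  }
  if (arc1 > arc2) {
    # LSC between the repeats: rotate so it starts at 1
    extra <- p$a2                            # bases before LSC start
    lsc_len <- arc1; ssc_len <- arc2
  } else {
    extra <- if (p$b2 < L) p$b2 else 0L      # LSC wraps the origin
    lsc_len <- arc2; ssc_len <- arc1
  }
  total_off <- (found$off + extra) %% L
  ir <- p$len
  tibble(
    id = id,
    lsc_start = 1L, lsc_end = lsc_len,
    ira_start = lsc_len + 1L, ira_end = lsc_len + ir,
    ssc_start = lsc_len + ir + 1L, ssc_end = lsc_len + ir + ssc_len,
    irb_start = lsc_len + ir + ssc_len + 1L, irb_end = L,
    ir_length = ir, offset = as.integer(total_off)
  )
}

check_quad <- function(plastome, quad) {
  if (quad$irb_end != plastome$length) {
    abort("quadripartite structure does not match the record length")
  }
  seq <- rotate_seq(plastome$sequence, quad$offset)
  ira <- substr(seq, quad$ira_start, quad$ira_end)
  irb <- substr(seq, quad$irb_start, quad$irb_end)
  if (!identical(revcomp(ira), irb)) {
    abort("quadripartite structure does not match the record: IRs are not reverse complements")
  }
  seq
}

#' Remove one inverted-repeat copy
#'
#' Deletes the IR\eqn{_B} copy from each genome so that repeated sites are
#' represented once in downstream alignment, distance and parsimony
#' analyses. Sequences are first rotated to the LSC-first linearisation the
#' structure table refers to.
#'
#' @param plastomes plastome tibble.
#' @param quad structure tibble from [detect_quadripartite()] (matched to
#'   `plastomes` by `id`).
#' @return a plastome tibble with `sequence` of length
#'   `length - ir_length` per taxon.
#' @export
reduce_single_ir <- function(plastomes, quad) {
  check_plastomes(plastomes)
  out <- lapply(seq_len(nrow(plastomes)), function(r) {
    rec <- plastomes[r, , drop = FALSE]
    q <- quad[quad$id == rec$id, , drop = FALSE]
    if (nrow(q) != 1L) abort(sprintf("no structure row for taxon '%s'", rec$id))
    seq <- check_quad(rec, q)
    reduced <- substr(seq, 1L, q$irb_start - 1L)
    tibble(id = rec$id, sequence = reduced, length = nchar(reduced),
           circular = FALSE)
  })
  dplyr::bind_rows(out)
}

## per-base region labels over the genome: intergenic / intron / one of the
## coding categories. Exons win over introns (plastomes nest genes inside
## other genes' introns); exon-exon overlap between different gene copies is
## an annotation conflict and errors.
region_labels <- function(features, genome_length) {
  check_features(features)
  lab <- rep("intergenic", genome_length)
  if (nrow(features) == 0L) return(lab)
  if (any(features$start < 1L | features$end > genome_length |
          features$start > features$end)) {
    abort("feature interval outside genome bounds")
  }
  # introns first (spans between a gene copy's exons)
  for (gid in unique(features$gene_id)) {
    fx <- features[features$gene_id == gid, , drop = FALSE]
    if (nrow(fx) > 1L) {
      span <- min(fx$start):max(fx$end)
      lab[span] <- "intron"
    }
  }
  owner <- rep(NA_character_, genome_length)
  for (r in seq_len(nrow(features))) {
    span <- features$start[r]:features$end[r]
    clash <- !is.na(owner[span]) & owner[span] != features$gene_id[r]
    if (any(clash)) {
      abort(paste0("overlapping conflicting features: ",
                   paste(unique(c(features$gene_id[r],
                                  owner[span][clash])), collapse = ", ")),
            class = "plastocmp_feature_overlap")
    }
    owner[span] <- features$gene_id[r]
    lab[span] <- features$category[r]
  }
  lab
}

#' Composition summary of a plastome
#'
#' AT content and the partition of the genome into protein-coding, rRNA,
#' tRNA, intron and intergenic fractions, all as percentages of the full
#' genome (both IR copies included). Values are kept at full precision;
#' round only when reporting.
#'
#' @param plastome one-row plastome tibble.
#' @param features feature tibble for that genome.
#' @return a one-row tibble: `id`, `at_percent`, `coding_percent`,
#'   `protein_percent`, `rrna_percent`, `trna_percent`,
#'   `intergenic_percent`, `intron_percent`.
#' @export
composition_summary <- function(plastome, features) {
  if (nrow(plastome) != 1L) abort("`plastome` must be a single record")
  L <- nchar(plastome$sequence)
  ch <- seq_chars(plastome$sequence)
  at <- 100 * sum(ch %in% c("A", "T")) / L
  lab <- region_labels(features, L)
  pct <- function(x) 100 * sum(lab == x) / L
  protein <- pct("protein_coding"); rrna <- pct("rRNA"); trna <- pct("tRNA")
  tibble(id = plastome$id,
         at_percent = at,
         coding_percent = protein + rrna + trna,
         protein_percent = protein,
         rrna_percent = rrna,
         trna_percent = trna,
         intergenic_percent = pct("intergenic"),
         intron_percent = pct("intron"))
}

#' Gene inventory
#'
#' Counts gene entries by category, IR duplication and intron content.
#' Every annotated copy counts as an entry, so a gene duplicated in the
#' inverted repeats contributes two.
#'
#' @param features feature tibble.
#' @return a one-row tibble: `n_genes`, `n_protein_coding`, `n_trna`,
#'   `n_rrna`, `n_ir_duplicated` (entries), `n_duplicated_pairs`,
#'   `n_single_copy`, `n_one_intron` (gene copies with exactly one intron).
#' @export
gene_inventory <- function(features) {
  check_features(features)
  if (nrow(features) == 0L) abort("`features` is empty")
  per_gene <- features |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(category = dplyr::first(.data$category),
                     copy = dplyr::first(.data$copy),
                     n_exons = dplyr::n(), .groups = "drop")
  n_dup <- sum(per_gene$copy == "IR-duplicated")
  tibble(
    n_genes = nrow(per_gene),
    n_protein_coding = sum(per_gene$category == "protein_coding"),
    n_trna = sum(per_gene$category == "tRNA"),
    n_rrna = sum(per_gene$category == "rRNA"),
    n_ir_duplicated = n_dup,
    n_duplicated_pairs = n_dup %/% 2L,
    n_single_copy = sum(per_gene$copy == "single"),
    n_one_intron = sum(per_gene$n_exons == 2L)
  )
}

#' Write a structure report as TSV
#'
#' @param quad structure tibble from [detect_quadripartite()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_report <- function(quad, path) {
  utils::write.table(quad, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
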