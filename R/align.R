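## Pairwise whole-plastome alignment. Near-identical, collinear genomes are
## aligned by chaining unique shared k-mer anchors (longest increasing
## subsequence) and closing the inter-anchor gaps with affine-gap dynamic
## programming; small or anchorless inputs fall back to full dynamic
## programming. Gap runs are normalised by left-shifting within
## equal-letter runs so placement is deterministic.

#' Default alignment scoring
#'
#' Match +1, mismatch -1, gap open -4, gap extend -1; a gap of length L
#' costs `gap_open + L * gap_ext`.
#'
#' @return a named list with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @export
default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = 4, gap_ext = 1)
}

FULL_DP_MAX_CELLS <- 4e7

## anchors: unique shared k-mers chained by longest (strictly) increasing
## subsequence on the query coordinate.
find_anchors <- function(ref, qry, k) {
  kr <- kmer_starts(ref, k)
  kq <- kmer_starts(qry, k)
  uR <- !(duplicated(kr) | duplicated(kr, fromLast = TRUE))
  uQ <- !(duplicated(kq) | duplicated(kq, fromLast = TRUE))
  pr <- which(uR)
  pq <- which(uQ)
  hit <- match(kr[pr], kq[pq])
  ok <- !is.na(hit)
  if (!any(ok)) return(NULL)
  i <- pr[ok]; j <- pq[hit[ok]]
  o <- order(i)
  i <- i[o]; j <- j[o]
  # LIS (patience) on j, strictly increasing; preallocated tails with
  # manual binary search (findInterval revalidates sortedness per call)
  n <- length(j)
  tails <- integer(n)        # indices into j of tail elements
  tvals <- integer(n)        # j values at those tails
  ntail <- 0L
  prev <- integer(n)
  for (t in seq_len(n)) {
    x <- j[t]
    lo <- 1L; hi <- ntail
    while (lo <= hi) {       # first position with tvals[pos] >= x
      mid <- (lo + hi) %/% 2L
      if (tvals[mid] >= x) hi <- mid - 1L else lo <- mid + 1L
    }
    pos <- lo
    prev[t] <- if (pos > 1L) tails[pos - 1L] else 0L
    tails[pos] <- t
    tvals[pos] <- x
    if (pos > ntail) ntail <- pos
  }
  sel <- integer(ntail)
  t <- tails[ntail]
  s <- ntail
  while (t > 0L) { sel[s] <- t; s <- s - 1L; t <- prev[t] }
  list(i = i[sel], j = j[sel], k = k)
}

## merge chained anchors into non-overlapping exact blocks
anchor_blocks <- function(anc) {
  i <- anc$i; j <- anc$j; k <- anc$k
  d <- j - i
  n <- length(i)
  run_id <- cumsum(c(TRUE, d[-1] != d[-n] | i[-1] != i[-n] + 1L))
  bi <- tapply(i, run_id, min); bj <- tapply(j, run_id, min)
  be <- tapply(i, run_id, max) + k - 1L
  blocks <- data.frame(ri = as.integer(bi), rj = as.integer(bj),
                       len = as.integer(be - bi + 1L))
  # trim overlaps between consecutive blocks (in either coordinate)
  if (nrow(blocks) > 1L) {
    for (t in 2:nrow(blocks)) {
      ov <- max(blocks$ri[t - 1] + blocks$len[t - 1] - blocks$ri[t],
                blocks$rj[t - 1] + blocks$len[t - 1] - blocks$rj[t], 0L)
      if (ov > 0L) {
        blocks$ri[t] <- blocks$ri[t] + ov
        blocks$rj[t] <- blocks$rj[t] + ov
        blocks$len[t] <- blocks$len[t] - ov
      }
    }
    blocks <- blocks[blocks$len > 0L, , drop = FALSE]
  }
  blocks
}

gotoh_pair <- function(a, b, sc) {
  .gotoh_align_cpp(a, b, sc$match, sc$mismatch, sc$gap_open, sc$gap_ext)
}

## left-shift every gap run while the flanking genome letters allow it,
## preserving the alignment score (deterministic tie-breaking).
normalize_gaps <- function(a, b) {
  av <- seq_chars(a); bv <- seq_chars(b)
  shift_row <- function(g, o) {  # g carries the gaps, o the letters
    r <- rle(g == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (t in which(r$values)) {
      s <- starts[t]; e <- ends[t]
      while (s > 1L && g[s - 1L] != "-" &&
             g[s - 1L] == o[e] && o[s - 1L] == o[e]) {
        g[e] <- g[s - 1L]; g[s - 1L] <- "-"
        s <- s - 1L; e <- e - 1L
      }
    }
    g
  }
  av <- shift_row(av, bv)
  bv <- shift_row(bv, av)
  list(a = paste0(av, collapse = ""), b = paste0(bv, collapse = ""))
}

score_alignment <- function(a, b, sc) {
  av <- seq_chars(a); bv <- seq_chars(b)
  ga <- av == "-"; gb <- bv == "-"
  nm <- sum(!ga & !gb & av == bv)
  mm <- sum(!ga & !gb & av != bv)
  runs <- function(g) {
    r <- rle(g)
    list(n = sum(r$values), len = sum(r$lengths[r$values]))
  }
  rga <- runs(ga); rgb <- runs(gb)
  nm * sc$match + mm * sc$mismatch -
    (rga$n + rgb$n) * sc$gap_open - (rga$len + rgb$len) * sc$gap_ext
}

#' Align two plastomes
#'
#' Global alignment of two near-identical genome sequences. The default
#' `"auto"` method uses full affine-gap dynamic programming when the
#' problem is small enough and anchor chaining with dynamic-programming
#' gap closing otherwise. For collinear inputs the anchored path returns
#' the full-DP-optimal score.
#'
#' @param plastomes plastome tibble containing both taxa.
#' @param ref_id,qry_id taxon ids of the reference and query rows.
#' @param scoring scoring list, see [default_scoring()].
#' @param method `"auto"`, `"anchored"` or `"full"`.
#' @param k anchor k-mer size; anchors must be unique in both sequences.
#' @return a one-row tibble of class `pair_alignment`: `ref_id`, `qry_id`,
#'   `ref_aln`, `qry_aln` (equal-length gapped strings), `score`.
#' @export
align_pair <- function(plastomes, ref_id, qry_id,
                       scoring = default_scoring(),
                       method = c("auto", "anchored", "full"), k = 21L) {
  method <- match.arg(method)
  check_plastomes(plastomes)
  ref <- plastome_record(plastomes, ref_id)$sequence
  qry <- plastome_record(plastomes, qry_id)$sequence
  if (nchar(ref) == 0L || nchar(qry) == 0L) abort("empty sequence")
  cells <- (nchar(ref) + 1) * (nchar(qry) + 1)
  use_full <- switch(method,
                     full = TRUE,
                     anchored = FALSE,
                     auto = cells <= FULL_DP_MAX_CELLS)
  if (use_full) {
    al <- gotoh_pair(ref, qry, scoring)
  } else {
    al <- align_anchored(ref, qry, scoring, k)
  }
  nz <- normalize_gaps(al$a, al$b)
  structure(
    tibble(ref_id = ref_id, qry_id = qry_id,
           ref_aln = nz$a, qry_aln = nz$b, score = al$score),
    class = c("pair_alignment", "tbl_df", "tbl", "data.frame"))
}

align_anchored <- function(ref, qry, sc, k) {
  anc <- find_anchors(ref, qry, k)
  if (is.null(anc)) {
    cells <- (nchar(ref) + 1) * (nchar(qry) + 1)
    if (cells <= FULL_DP_MAX_CELLS) return(gotoh_pair(ref, qry, sc))
    abort("no alignment anchors found and inputs exceed the full-DP size cap",
          class = "plastocmp_no_anchors")
  }
  blocks <- anchor_blocks(anc)
  pa <- character(0); pb <- character(0)
  score <- 0
  ri <- 1L; rj <- 1L
  seg_align <- function(a, b) {
    if (nchar(a) == 0L && nchar(b) == 0L) {
      return(list(a = "", b = "", score = 0))
    }
    gotoh_pair(a, b, sc)
  }
  for (t in seq_len(nrow(blocks))) {
    g <- seg_align(substr(ref, ri, blocks$ri[t] - 1L),
                   substr(qry, rj, blocks$rj[t] - 1L))
    blk <- substr(ref, blocks$ri[t], blocks$ri[t] + blocks$len[t] - 1L)
    pa <- c(pa, g$a, blk)
    pb <- c(pb, g$b, blk)
    score <- score + g$score + blocks$len[t] * sc$match
    ri <- blocks$ri[t] + blocks$len[t]
    rj <- blocks$rj[t] + blocks$len[t]
  }
  g <- seg_align(substr(ref, ri, nchar(ref)), substr(qry, rj, nchar(qry)))
  pa <- c(pa, g$a); pb <- c(pb, g$b)
  score <- score + g$score
  list(a = paste0(pa, collapse = ""), b = paste0(pb, collapse = ""),
       score = score)
}

check_pair_alignment <- function(pair) {
  need <- c("ref_id", "qry_id", "ref_aln", "qry_aln")
  if (!is.data.frame(pair) || !all(need %in% names(pair))) {
    abort("`pair` must be a pair_alignment tibble from align_pair()")
  }
  if (any(nchar(pair$ref_aln) != nchar(pair$qry_aln))) {
    abort("alignment rows differ in length")
  }
  invisible(pair)
}

#' Project pairwise alignments onto a common reference
#'
#' Builds a multiple alignment from pairwise alignments that share a
#' reference: insertion columns relative to the reference are unioned
#' (maximum insertion length per reference position across pairs) and each
#' query row is placed in those coordinates. Degapping any row reproduces
#' the input sequence exactly.
#'
#' @param pairs pair_alignment tibble (rows from [align_pair()], all with
#'   the same `ref_id`).
#' @param ref_id the shared reference taxon id.
#' @return a tibble of class `plastome_alignment` with columns `id`, `aln`
#'   (equal-length gapped strings); the reference row comes first. The
#'   reference id is kept in attribute `ref_id`.
#' @export
project_to_reference <- function(pairs, ref_id) {
  check_pair_alignment(pairs)
  if (!all(pairs$ref_id == ref_id)) {
    abort("all pairs must share `ref_id`", class = "plastocmp_ref_mismatch")
  }
  refs <- unique(degap(pairs$ref_aln))
  if (length(refs) != 1L) {
    abort("degapped reference differs between pairs",
          class = "plastocmp_ref_mismatch")
  }
  refseq <- refs
  L <- nchar(refseq)
  # per pair: insertion lengths keyed by reference position (0..L = number
  # of reference bases before the insertion)
  parse_pair <- function(raln, qaln) {
    rv <- seq_chars(raln); qv <- seq_chars(qaln)
    idx <- cumsum(rv != "-")           # ref base index per column
    ins <- rv == "-"
    list(rv = rv, qv = qv, idx = idx, ins = ins)
  }
  parsed <- lapply(seq_len(nrow(pairs)), function(r) {
    parse_pair(pairs$ref_aln[r], pairs$qry_aln[r])
  })
  ins_len <- integer(L + 1L)           # index = pos + 1
  for (p in parsed) {
    if (any(p$ins)) {
      tab <- table(p$idx[p$ins])
      at <- as.integer(names(tab)) + 1L
      ins_len[at] <- pmax(ins_len[at], as.integer(tab))
    }
  }
  pad <- function(x, n) paste0(x, strrep("-", n - nchar(x)))
  build_row <- function(p) {
    # query letters at reference columns, by ref position
    base <- character(L)
    base[p$idx[!p$ins]] <- p$qv[!p$ins]
    chunks <- character(L + 1L)
    if (any(p$ins)) {
      sp <- split(p$qv[p$ins], p$idx[p$ins])
      chunks[as.integer(names(sp)) + 1L] <-
        vapply(sp, paste0, character(1), collapse = "")
    }
    need <- ins_len > 0L
    chunks[need] <- pad(chunks[need], ins_len[need])
    paste0(chunks[1L], paste0(base, chunks[-1L], collapse = ""))
  }
  ref_chunks <- strrep("-", ins_len)
  ref_row <- paste0(ref_chunks[1L],
                    paste0(seq_chars(refseq), ref_chunks[-1L],
                           collapse = ""))
  rows <- vapply(parsed, build_row, character(1))
  out <- tibble(id = c(ref_id, pairs$qry_id), aln = c(ref_row, rows))
  attr(out, "ref_id") <- ref_id
  class(out) <- c("plastome_alignment", class(tibble()))
  out
}

#' Align many plastomes against one reference
#'
#' Convenience wrapper: aligns every non-reference taxon to `ref_id` with
#' [align_pair()] and projects the result with [project_to_reference()].
#'
#' @inheritParams align_pair
#' @return a `plastome_alignment` tibble.
#' @export
multi_align <- function(plastomes, ref_id, scoring = default_scoring(),
                        method = c("auto", "anchored", "full"), k = 21L) {
  method <- match.arg(method)
  others <- setdiff(plastomes$id, ref_id)
  pairs <- dplyr::bind_rows(lapply(others, function(q) {
    align_pair(plastomes, ref_id, q, scoring, method, k)
  }))
  project_to_reference(pairs, ref_id)
}

#' Write a multiple alignment as FASTA
#'
#' @param aln `plastome_alignment` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(setNames(aln$aln, aln$id))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
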