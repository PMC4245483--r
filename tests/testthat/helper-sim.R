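## Shared fixtures, all built in code. Expensive simulations are cached in
## an environment so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## a small quadripartite layout (a few kb) that keeps tests fast
small_layout <- function() {
  list(protein = list(n_lsc = 4L, n_ssc = 1L, n_ir = 1L,
                      aa_mean = 120, aa_sd = 20, aa_min = 50L),
       trna = list(n_lsc = 2L, n_ssc = 1L, n_ir = 1L,
                   len_mean = 75, len_sd = 8, len_min = 60L),
       rrna = list(ir_lengths = 300L),
       introns = list(n_protein = 1L, n_trna = 1L,
                      len_mean = 200, len_sd = 30, len_min = 100L))
}

small_params <- function(tree = "((A:0.002,B:0.003):0.002,(C:0.002,D:0.001):0.002,E:0.02);",
                         ...) {
  sim_params(lsc = 6000L, ir = 1500L, ssc = 900L, genes = small_layout(),
             tree = tree, ...)
}

small_sim <- function() {
  cached("small_sim", simulate_plastomes(small_params(), seed = 4L))
}

## one-branch simulation: REF is a zero-length branch, so its sequence is
## the ancestor and truth positions are directly comparable to calls
branch_sim <- function(seed = 1L, ...) {
  simulate_plastomes(small_params(tree = "(REF:0.0,Q:0.003);", ...),
                     seed = seed)
}

full_sim <- function() {
  cached("full_sim", simulate_plastomes(sim_params(), seed = 1L))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

plastome_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = names(seqs), sequence = unname(seqs),
                 length = nchar(seqs), circular = FALSE)
}

pair_tbl <- function(ref, qry, ref_id = "ref", qry_id = "qry") {
  tibble::tibble(ref_id = ref_id, qry_id = qry_id,
                 ref_aln = ref, qry_aln = qry, score = NA_real_)
}

## mutate one base of a sequence at `pos` to a different base
substitute_base <- function(seq, pos, alt) {
  paste0(substr(seq, 1, pos - 1), alt, substr(seq, pos + 1, nchar(seq)))
}

## independent brute-force Fitch oracle: minimise changes over every
## assignment of internal-node states (tips with missing data may take
## any state in their bitmask)
bf_fitch <- function(edge, n_tip, tip_masks) {
  nodes <- sort(unique(as.vector(edge)))
  internals <- nodes[nodes > n_tip]
  bits <- c(1L, 2L, 4L, 8L)
  tip_choices <- lapply(seq_len(n_tip), function(t) {
    bits[bitwAnd(tip_masks[t], bits) > 0]
  })
  best <- Inf
  grid <- expand.grid(rep(list(bits), length(internals)))
  for (g in seq_len(nrow(grid))) {
    assign_ <- integer(max(nodes))
    assign_[internals] <- as.integer(grid[g, ])
    # tips choose their best compatible state given neighbours: since a
    # tip has one neighbour, its optimal state matches the neighbour when
    # allowed
    cost <- 0L
    for (r in seq_len(nrow(edge))) {
      u <- edge[r, 1]; v <- edge[r, 2]
      su <- if (u <= n_tip) tip_choices[[u]] else assign_[u]
      sv <- if (v <= n_tip) tip_choices[[v]] else assign_[v]
      if (length(intersect(su, sv)) == 0L) cost <- cost + 1L
    }
    best <- min(best, cost)
  }
  best
}

## alignment tibble from explicit rows
aln_tbl <- function(rows) {
  tibble::tibble(id = names(rows), aln = unname(rows))
}

## homoplasy-free character matrix: each variable site changes exactly
## once, on one branch of the given tree; every edge carries at least one
## mutation when n_var allows, so the generating topology is recoverable
hf_alignment <- function(phy, n_sites = 60L, n_var = 12L) {
  n <- length(phy$tip.label)
  base <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  rows <- matrix(rep(base, n), nrow = n, byrow = TRUE)
  ut <- plastocmp:::phylo_to_utree(phy, phy$tip.label)
  edge_for_site <- c(seq_len(min(n_var, nrow(ut$edge))),
                     sample(nrow(ut$edge),
                            max(0L, n_var - nrow(ut$edge)),
                            replace = TRUE))
  for (s in seq_len(n_var)) {
    e <- edge_for_site[s]
    u <- ut$edge[e, 1]; v <- ut$edge[e, 2]
    rest <- ut$edge[-e, , drop = FALSE]
    comp <- plastocmp:::utree_component(rest, v)
    tips <- comp[comp <= n]
    if (length(tips) == 0 || length(tips) == n) next
    alt <- setdiff(c("A", "C", "G", "T"), base[s])[1]
    rows[tips, s] <- alt
  }
  aln_tbl(setNames(apply(rows, 1, paste0, collapse = ""),
                   phy$tip.label))
}
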