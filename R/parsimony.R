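## Maximum-parsimony phylogenetics: character-matrix construction from the
## multiple alignment (gaps and N as missing data, all characters unordered
## and equally weighted), Fitch tree length, exhaustive and heuristic
## searches (random-addition starting trees, TBR branch swapping),
## consistency/retention indices, bootstrap support, plus a
## neighbor-joining cross-check and outgroup rooting.

STATE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, `-` = 15L)

#' Build a parsimony character matrix from a multiple alignment
#'
#' Converts alignment columns to unordered nucleotide characters; gaps and
#' N are treated as missing data. Sites are classified `constant` (at most
#' one observed state), `parsimony_informative` (at least two states each
#' present in at least two taxa) or `variable_uninformative`, and
#' identical columns are compressed to weighted patterns.
#'
#' @param aln `plastome_alignment` tibble (or any tibble with `id`, `aln`).
#' @return an object of class `character_matrix`: taxa, pattern state
#'   matrix (bitmasks), pattern weights, per-site classes and per-pattern
#'   minimum/maximum step counts.
#' @export
build_character_matrix <- function(aln) {
  if (nrow(aln) < 3L) abort("need at least 3 taxa",
                            class = "plastocmp_too_few_taxa")
  rows <- strsplit(aln$aln, "", fixed = TRUE)
  n_sites <- unique(lengths(rows))
  if (length(n_sites) != 1L) abort("alignment rows differ in length")
  M <- matrix(unlist(rows, use.names = FALSE), nrow = n_sites,
              ncol = nrow(aln))
  bits <- STATE_BITS[M]
  if (anyNA(bits)) abort("alignment contains characters outside {A,C,G,T,N,-}")
  B <- matrix(as.integer(bits), nrow = n_sites)
  # per-site state counts
  cnt <- vapply(c(1L, 2L, 4L, 8L), function(b) {
    rowSums(B == b)
  }, numeric(n_sites))
  n_states <- rowSums(cnt > 0)
  n_doubles <- rowSums(cnt >= 2)
  site_class <- ifelse(n_states <= 1, "constant",
                       ifelse(n_doubles >= 2, "parsimony_informative",
                              "variable_uninformative"))
  min_steps <- pmax(n_states - 1, 0)
  max_steps <- rowSums(cnt) - apply(cnt, 1, max)
  key <- do.call(paste, c(lapply(seq_len(ncol(B)), function(j) B[, j]),
                          sep = ","))
  upat <- !duplicated(key)
  pattern_of_site <- match(key, key[upat])
  states <- B[upat, , drop = FALSE]
  weights <- as.integer(tabulate(pattern_of_site, nbins = sum(upat)))
  structure(list(
    taxa = aln$id,
    states = states,
    weights = weights,
    pattern_of_site = pattern_of_site,
    site_class = site_class,
    pattern_class = site_class[upat],
    pattern_min_steps = min_steps[upat],
    pattern_max_steps = max_steps[upat],
    n_sites = n_sites
  ), class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa, %d sites (%d patterns)\n",
              length(x$taxa), x$n_sites, nrow(x$states)))
  print(table(x$site_class))
  invisible(x)
}

#' @rdname build_character_matrix
#' @param x a `character_matrix`.
#' @param ... unused.
#' @export
glance.character_matrix <- function(x, ...) {
  tibble(n_taxa = length(x$taxa), n_sites = x$n_sites,
         n_patterns = nrow(x$states),
         n_constant = sum(x$site_class == "constant"),
         n_variable_uninformative =
           sum(x$site_class == "variable_uninformative"),
         n_parsimony_informative =
           sum(x$site_class == "parsimony_informative"))
}

#' @rdname build_character_matrix
#' @export
tidy.character_matrix <- function(x, ...) {
  tibble(site = seq_len(x$n_sites), class = x$site_class,
         pattern = x$pattern_of_site)
}

check_cm <- function(cm) {
  if (!inherits(cm, "character_matrix")) {
    abort("`matrix` must be a character_matrix from build_character_matrix()")
  }
  invisible(cm)
}

#' Fitch parsimony length of a tree
#'
#' Number of state changes required by the matrix on the given unrooted
#' binary topology, by the Fitch intersection/union pass; missing states
#' contribute the full state set.
#'
#' @param tree an `ape` phylo object whose tips match the matrix taxa.
#' @param matrix a `character_matrix`.
#' @return tree length in steps.
#' @export
fitch_length <- function(tree, matrix) {
  check_cm(matrix)
  tr <- phylo_to_utree(tree, matrix$taxa)
  utree_score(tr, matrix$states, matrix$weights)
}

make_parsimony_fit <- function(best_trees, best_len, cm, method,
                               n_evaluated) {
  # deterministic representative order: sorted canonical strings
  keys <- vapply(best_trees, utree_canonical, character(1))
  o <- order(keys)
  best_trees <- best_trees[o]
  idx <- cm$pattern_class != "constant"
  ci <- consistency_from_tree(best_trees[[1]], cm)
  structure(list(
    trees = lapply(best_trees, utree_to_phylo, labels = cm$taxa),
    utrees = best_trees,
    length = best_len,
    CI = ci$CI, RI = ci$RI, CI_excluding_uninformative = ci$CI_excl,
    taxa = cm$taxa,
    method = method,
    n_evaluated = n_evaluated
  ), class = "parsimony_fit")
}

consistency_from_tree <- function(utr, cm) {
  per <- .fitch_score_cpp(utr$edge, utr$n_tip, cm$states, cm$weights,
                          TRUE)$per_site
  w <- cm$weights
  s <- sum(per * w)
  m <- sum(cm$pattern_min_steps * w)
  g <- sum(cm$pattern_max_steps * w)
  ci <- if (s == 0) 1 else m / s
  if (g == m) {
    warn("all sites reach their minimum on a star tree; RI set to 1")
    ri <- 1
  } else {
    ri <- (g - s) / (g - m)
  }
  keep <- cm$pattern_class == "parsimony_informative"
  s_e <- sum((per * w)[keep]); m_e <- sum((cm$pattern_min_steps * w)[keep])
  ci_e <- if (s_e == 0) 1 else m_e / s_e
  list(CI = ci, RI = ri, CI_excl = ci_e)
}

#' Consistency and retention indices
#'
#' CI = sum(m)/sum(s), RI = (sum(g)-sum(s))/(sum(g)-sum(m)) where m, s
#' and g are per-site minimum, observed and maximum (star-tree) step
#' counts; the CI excluding uninformative characters restricts the sums
#' to parsimony-informative sites.
#'
#' @inheritParams fitch_length
#' @return a one-row tibble: `tree_length`, `CI`, `RI`,
#'   `CI_excluding_uninformative`.
#' @export
consistency_indices <- function(tree, matrix) {
  check_cm(matrix)
  utr <- phylo_to_utree(tree, matrix$taxa)
  ci <- consistency_from_tree(utr, matrix)
  tibble(tree_length = utree_score(utr, matrix$states, matrix$weights),
         CI = ci$CI, RI = ci$RI,
         CI_excluding_uninformative = ci$CI_excl)
}

#' Exhaustive maximum-parsimony search
#'
#' Evaluates every unrooted binary topology — (2n-5)!! of them — and
#' returns all minimum-length trees. Refuses more than 9 taxa; use
#' [heuristic_search()] beyond that.
#'
#' @param matrix a `character_matrix`.
#' @return a `parsimony_fit` object.
#' @export
exhaustive_search <- function(matrix) {
  check_cm(matrix)
  n <- length(matrix$taxa)
  if (n > 9L) {
    abort("exhaustive search is limited to 9 taxa; use heuristic_search()",
          class = "plastocmp_too_many_taxa")
  }
  trees <- utree_enumerate(n)
  scores <- vapply(trees, utree_score, numeric(1),
                   states = matrix$states, weights = matrix$weights)
  best <- min(scores)
  make_parsimony_fit(trees[scores == best], best, matrix, "exhaustive",
                     length(trees))
}

## one stepwise-addition + TBR replicate
search_replicate <- function(cm, order_tips) {
  states <- cm$states; weights <- cm$weights
  tr <- utree_cherry(order_tips[1], order_tips[2], order_tips[3],
                     length(cm$taxa))
  n_eval <- 0L
  for (tip in order_tips[-(1:3)]) {
    cand_scores <- vapply(seq_len(nrow(tr$edge)), function(e) {
      utree_score(utree_insert_tip(tr, tip, e), states, weights)
    }, numeric(1))
    n_eval <- n_eval + length(cand_scores)
    tr <- utree_insert_tip(tr, tip, which.min(cand_scores))
  }
  score <- utree_score(tr, states, weights)
  repeat {
    nb <- utree_tbr_neighbors(tr)
    sc <- vapply(nb, utree_score, numeric(1),
                 states = states, weights = weights)
    n_eval <- n_eval + length(sc)
    if (length(sc) == 0L || min(sc) >= score) break
    tr <- nb[[which.min(sc)]]
    score <- min(sc)
  }
  list(tree = tr, score = score, n_eval = n_eval)
}

#' Heuristic maximum-parsimony search
#'
#' Random stepwise addition builds a starting tree for each replicate and
#' tree-bisection-reconnection (TBR) branch swapping descends to a local
#' optimum; the best tree(s) over all replicates are returned.
#' Deterministic given `seed`.
#'
#' @param matrix a `character_matrix`.
#' @param n_additions number of random-addition replicates.
#' @param seed optional integer seed.
#' @param max_trees cap on the number of tied optimal trees retained.
#' @return a `parsimony_fit` object.
#' @export
heuristic_search <- function(matrix, n_additions = 200L, seed = NULL,
                             max_trees = 100L) {
  check_cm(matrix)
  if (n_additions < 1L) abort("n_additions must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(matrix$taxa)
  best <- NULL; best_score <- Inf; n_eval <- 0L
  seen <- character(0)
  for (rep in seq_len(n_additions)) {
    ord <- sample.int(n)
    res <- search_replicate(matrix, ord)
    n_eval <- n_eval + res$n_eval
    if (res$score < best_score - 1e-9) {
      best_score <- res$score
      best <- list(res$tree)
      seen <- utree_canonical(res$tree)
    } else if (abs(res$score - best_score) < 1e-9 &&
               length(best) < max_trees) {
      key <- utree_canonical(res$tree)
      if (!key %in% seen) {
        best <- c(best, list(res$tree))
        seen <- c(seen, key)
      }
    }
  }
  make_parsimony_fit(best, best_score, matrix, "heuristic", n_eval)
}

#' Bootstrap support for the best parsimony tree
#'
#' Resamples alignment columns with replacement to the original length,
#' reruns the search per pseudoreplicate, and reports for every
#' bipartition of the full-data best tree the percentage of replicates
#' whose best tree contains it. Deterministic given `seed`.
#'
#' @param matrix a `character_matrix`.
#' @param n_reps number of bootstrap pseudoreplicates.
#' @param seed optional integer seed.
#' @param n_additions random-addition replicates per pseudoreplicate.
#' @param fit optional `parsimony_fit` for the full data (computed with
#'   `n_additions` replicates when missing).
#' @return a list of class `bootstrap_support`: `tree` (phylo with node
#'   labels = support), `supports` (tibble: `bipartition`, `support`),
#'   `fit`.
#' @export
bootstrap_support <- function(matrix, n_reps = 2000L, seed = NULL,
                              n_additions = 1L, fit = NULL) {
  check_cm(matrix)
  if (n_reps < 1L) abort("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit)) {
    fit <- heuristic_search(matrix, n_additions = max(10L, n_additions))
  }
  best <- fit$utrees[[1]]
  target <- utree_bipartitions(best)
  hits <- setNames(numeric(length(target)), target)
  prob <- matrix$weights / sum(matrix$weights)
  cm_b <- matrix
  for (b in seq_len(n_reps)) {
    cm_b$weights <- as.integer(rmultinom(1L, matrix$n_sites, prob))
    res <- search_replicate(cm_b, sample.int(length(matrix$taxa)))
    found <- utree_bipartitions(res$tree)
    hit <- target %in% found
    hits[hit] <- hits[hit] + 1
  }
  supports <- tibble(bipartition = target,
                     support = 100 * unname(hits) / n_reps)
  tree <- annotate_supports(best, matrix$taxa, supports)
  structure(list(tree = tree, supports = supports, fit = fit),
            class = "bootstrap_support")
}

## attach support values as node labels on the exported phylo
annotate_supports <- function(utr, taxa, supports) {
  phy <- utree_to_phylo(utr, taxa)
  n <- length(taxa)
  pp <- ape::prop.part(phy)
  labs <- character(phy$Nnode)
  for (i in seq_len(phy$Nnode)) {
    tips <- match(attr(pp, "labels")[pp[[i]]], taxa)
    if (1L %in% tips) tips <- setdiff(seq_len(n), tips)
    key <- paste(sort(tips), collapse = "|")
    j <- match(key, supports$bipartition)
    labs[i] <- if (is.na(j)) "" else
      formatC(supports$support[j], format = "f", digits = 1)
  }
  phy$node.label <- labs
  phy
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration (Q-criterion); a cross-check on the
#' parsimony topology from the variant-count distances. Negative branch
#' lengths are clamped to zero with a warning.
#'
#' @param distances symmetric numeric matrix with zero diagonal, or a
#'   distance tibble from [distance_matrices()].
#' @param metric metric column when `distances` is a tibble.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(distances,
                             metric = c("variants",
                                        "nucleotide_differences")) {
  metric <- match.arg(metric)
  if (is.data.frame(distances)) {
    distances <- as_dist_matrix(distances, metric)
  }
  if (!isSymmetric(unname(distances)) || any(diag(distances) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal",
          class = "plastocmp_bad_distances")
  }
  tr <- ape::nj(distances)
  if (any(tr$edge.length < 0)) {
    warn("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Root a tree on an outgroup
#'
#' Places the root on the outgroup's pendant edge; ingroup bipartitions
#' are unchanged.
#'
#' @param tree a `phylo` tree.
#' @param outgroup tip label of the outgroup.
#' @return a rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    abort(sprintf("outgroup '%s' is not a leaf of the tree", outgroup),
          class = "plastocmp_label_mismatch")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat(sprintf("parsimony_fit (%s): length %g, CI %.4f, RI %.4f, CI(excl) %.4f\n",
              x$method, x$length, x$CI, x$RI,
              x$CI_excluding_uninformative))
  cat(sprintf("%d optimal tree(s); %d topologies evaluated\n",
              length(x$trees), x$n_evaluated))
  invisible(x)
}

#' @rdname heuristic_search
#' @param x a `parsimony_fit`.
#' @param ... unused.
#' @export
glance.parsimony_fit <- function(x, ...) {
  tibble(tree_length = x$length, CI = x$CI, RI = x$RI,
         CI_excluding_uninformative = x$CI_excluding_uninformative,
         n_trees = length(x$trees), method = x$method,
         n_evaluated = x$n_evaluated)
}

#' @rdname heuristic_search
#' @export
tidy.parsimony_fit <- function(x, ...) {
  tibble(tree = seq_along(x$trees),
         newick = vapply(x$trees, function(t) ape::write.tree(t),
                         character(1)),
         tree_length = x$length)
}

#' Export a character matrix in relaxed PHYLIP format
#'
#' @param aln `plastome_alignment` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  lines <- c(sprintf("%d %d", nrow(aln), nchar(aln$aln[1])),
             sprintf("%s  %s", format(aln$id), aln$aln))
  writeLines(lines, path)
  invisible(path)
}

#' Export a character matrix as a NEXUS data block
#'
#' @inheritParams write_phylip
#' @export
write_nexus <- function(aln, path) {
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(aln),
                     nchar(aln$aln[1])),
             "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
             "  MATRIX",
             sprintf("    %s  %s", format(aln$id), aln$aln),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
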