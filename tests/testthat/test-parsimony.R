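test_that("site classification follows the parsimony definitions", {
  aln <- aln_tbl(c(t1 = "AAAGA", t2 = "AAAGA", t3 = "AGAG-", t4 = "AGGG-"))
  cm <- build_character_matrix(aln)
  expect_equal(cm$site_class,
               c("constant", "parsimony_informative",
                 "variable_uninformative", "constant", "constant"))
  g <- glance(cm)
  expect_equal(g$n_constant + g$n_variable_uninformative +
                 g$n_parsimony_informative, g$n_sites)
  expect_error(build_character_matrix(aln[1:2, ]),
               class = "plastocmp_too_few_taxa")
})

test_that("Fitch length matches brute-force enumeration of internal labelings", {
  set.seed(51)
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, `-` = 15L)
  for (trial in 1:20) {
    n <- sample(4:5, 1)
    n_sites <- 8L
    chars <- matrix(sample(c("A", "C", "G", "T", "-"), n * n_sites,
                           replace = TRUE, prob = c(rep(0.23, 4), 0.08)),
                    nrow = n)
    aln <- aln_tbl(setNames(apply(chars, 1, paste0, collapse = ""),
                            paste0("t", 1:n)))
    cm <- build_character_matrix(aln)
    trees <- plastocmp:::utree_enumerate(n)
    tr <- trees[[sample(length(trees), 1)]]
    mine <- plastocmp:::utree_score(tr, cm$states, cm$weights)
    oracle <- sum(vapply(seq_len(n_sites), function(s) {
      masks <- unname(bits[chars[, s]])
      bf_fitch(tr$edge, n, masks)
    }, numeric(1)))
    expect_equal(mine, oracle)
  }
})

test_that("Fitch length agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(52)
  for (trial in 1:8) {
    n <- sample(5:9, 1)
    chars <- matrix(sample(c("A", "C", "G", "T", "-"), n * 40,
                           replace = TRUE), nrow = n,
                    dimnames = list(paste0("t", 1:n), NULL))
    aln <- aln_tbl(setNames(apply(chars, 1, paste0, collapse = ""),
                            rownames(chars)))
    cm <- build_character_matrix(aln)
    tr <- ape::unroot(ape::rtree(n, tip.label = sample(rownames(chars))))
    pd <- phangorn::phyDat(chars, type = "DNA")
    expect_equal(fitch_length(tr, cm),
                 phangorn::parsimony(tr, pd, method = "fitch"))
  }
})

test_that("Fitch length is invariant to rerooting and taxon order", {
  sim <- small_sim()
  quad <- detect_quadripartite(sim$leaves, min_ir_length = 500)
  aln <- multi_align(reduce_single_ir(sim$leaves, quad), "A")
  cm <- build_character_matrix(aln)
  tr <- ape::unroot(ape::rtree(nrow(aln), tip.label = sample(aln$id)))
  len0 <- fitch_length(tr, cm)
  rooted <- root_with_outgroup(tr, "E")
  expect_equal(fitch_length(rooted, cm), len0)
  perm <- sample(nrow(aln))
  cm2 <- build_character_matrix(aln[perm, ])
  expect_equal(fitch_length(tr, cm2), len0)
})

test_that("identical sequences give zero steps on any topology", {
  aln <- aln_tbl(setNames(rep(strrep("ACGT", 10), 5), paste0("t", 1:5)))
  cm <- build_character_matrix(aln)
  for (tr in plastocmp:::utree_enumerate(5)[c(1, 7, 15)]) {
    expect_equal(plastocmp:::utree_score(tr, cm$states, cm$weights), 0)
  }
})

test_that("exhaustive search enumerates (2n-5)!! topologies and finds the grouping", {
  expect_equal(length(plastocmp:::utree_enumerate(8)), 10395L)
  expect_error(exhaustive_search(
    build_character_matrix(aln_tbl(setNames(rep("ACGT", 10),
                                            paste0("t", 1:10))))),
    class = "plastocmp_too_many_taxa")
  # one informative site: the topology grouping the shared states wins by 1
  aln <- aln_tbl(c(t1 = "AAAA", t2 = "AAAA", t3 = "AGAA", t4 = "AGAA"))
  fit <- exhaustive_search(build_character_matrix(aln))
  expect_equal(fit$length, 1)
  expect_equal(length(fit$trees), 1)
  expect_true("2" %in% plastocmp:::utree_bipartitions(fit$utrees[[1]]) ||
              "3|4" %in% plastocmp:::utree_bipartitions(fit$utrees[[1]]))
  expect_equal(fit$n_evaluated, 3L)
})

test_that("heuristic search matches the exhaustive optimum", {
  set.seed(53)
  for (trial in 1:4) {
    n <- sample(6:7, 1)
    chars <- matrix(sample(c("A", "C", "G", "T"), n * 60, replace = TRUE,
                           prob = c(0.4, 0.3, 0.2, 0.1)), nrow = n)
    aln <- aln_tbl(setNames(apply(chars, 1, paste0, collapse = ""),
                            paste0("t", 1:n)))
    cm <- build_character_matrix(aln)
    ex <- exhaustive_search(cm)
    he <- heuristic_search(cm, n_additions = 5, seed = trial)
    expect_equal(he$length, ex$length)
  }
})

test_that("homoplasy-free data give CI = 1 and recover the true topology", {
  set.seed(54)
  phy <- ape::unroot(ape::rtree(7, tip.label = paste0("t", 1:7)))
  aln <- hf_alignment(phy, n_sites = 80, n_var = 15)
  cm <- build_character_matrix(aln)
  fit <- heuristic_search(cm, n_additions = 10, seed = 1)
  expect_equal(fit$CI, 1)
  true_len <- fitch_length(phy, cm)
  expect_equal(fit$length, true_len)
  best_bip <- plastocmp:::utree_bipartitions(fit$utrees[[1]])
  true_bip <- plastocmp:::utree_bipartitions(
    plastocmp:::phylo_to_utree(phy, cm$taxa))
  expect_true(all(true_bip %in% best_bip))
})

test_that("consistency indices match a hand-computed toy and phangorn", {
  # five taxa, one clean site and one convergent site
  aln <- aln_tbl(c(t1 = "GA", t2 = "GG", t3 = "AA", t4 = "AG", t5 = "AA"))
  cm <- build_character_matrix(aln)
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4),t5);")
  ci <- consistency_indices(tr, cm)
  # site 1: m=1, s=1, g=2; site 2: m=1, s=2, g=2
  expect_equal(ci$tree_length, 3)
  expect_equal(ci$CI, 2 / 3)
  expect_equal(ci$RI, (4 - 3) / (4 - 2))
  skip_if_not_installed("phangorn")
  chars <- do.call(rbind, strsplit(aln$aln, ""))
  rownames(chars) <- aln$id
  pd <- phangorn::phyDat(chars, type = "DNA")
  expect_equal(ci$CI, phangorn::CI(tr, pd))
  expect_equal(ci$RI, phangorn::RI(tr, pd))
})

test_that("an overwhelming repeated pattern reaches 100% bootstrap support", {
  block <- function(x) strrep(x, 50)
  # trailing columns are autapomorphies: uninformative noise only
  aln <- aln_tbl(c(t1 = paste0(block("A"), "CAAAAAAAAA"),
                   t2 = paste0(block("A"), "ACAAAAAAAA"),
                   t3 = paste0(block("G"), "AACAAAAAAA"),
                   t4 = paste0(block("G"), "AAACAAAAAA"),
                   t5 = paste0(block("G"), "AAAACAAAAA")))
  cm <- build_character_matrix(aln)
  boot <- bootstrap_support(cm, n_reps = 60, seed = 2, n_additions = 1)
  key12 <- paste(sort(setdiff(1:5, c(1, 2))), collapse = "|")
  sup <- boot$supports$support[boot$supports$bipartition == key12]
  expect_equal(sup, 100)
  expect_true(all(boot$supports$support >= 0 &
                  boot$supports$support <= 100))
  expect_false(is.null(boot$tree$node.label))
})

test_that("neighbor joining recovers additive distances exactly", {
  tr <- ape::read.tree(text = "((a:3,b:2):1,(c:4,d:1):2);")
  d <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-8)
  # three taxa: the single unrooted topology
  nj3 <- neighbor_joining(d[1:3, 1:3])
  expect_equal(length(nj3$tip.label), 3L)
  bad <- d; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), class = "plastocmp_bad_distances")
})

test_that("outgroup rooting places the outgroup sister to the ingroup", {
  tr <- ape::read.tree(text = "((a,b),(c,o));")
  rooted <- root_with_outgroup(ape::unroot(tr), "o")
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  expect_true(which(rooted$tip.label == "o") %in% kids)
  # round trip preserves the bipartitions
  back <- ape::unroot(rooted)
  expect_equal(ape::dist.topo(back, ape::unroot(tr)),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  expect_error(root_with_outgroup(tr, "nope"),
               class = "plastocmp_label_mismatch")
})

test_that("matrix exports are readable PHYLIP and NEXUS", {
  aln <- aln_tbl(c(t1 = "ACGT-", t2 = "ACGTA", t3 = "AGGTA"))
  f1 <- withr::local_tempfile(fileext = ".phy")
  write_phylip(aln, f1)
  first <- strsplit(readLines(f1)[1], " ")[[1]]
  expect_equal(as.integer(first), c(3L, 5L))
  f2 <- withr::local_tempfile(fileext = ".nex")
  write_nexus(aln, f2)
  expect_true(any(grepl("NTAX=3", readLines(f2))))
})
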