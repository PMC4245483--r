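test_that("the default ancestor has the quadripartite geometry and passes round-trip detection", {
  anc <- full_sim()$ancestor
  p <- anc$params
  expect_equal(anc$plastome$length, p$lsc + 2L * p$ir + p$ssc)
  expect_equal(anc$plastome$length, 134557L)
  q <- detect_quadripartite(anc$plastome)
  expect_equal(q$ir_length, p$ir)
  expect_equal(q$lsc_end, p$lsc)
  expect_equal(q$ssc_end - q$ssc_start + 1L, p$ssc)
  red <- reduce_single_ir(anc$plastome, q)
  expect_equal(red$length, 113754L)
  inv <- gene_inventory(anc$features)
  expect_equal(inv$n_genes, 162L)
  expect_equal(inv$n_protein_coding, 114L)
  expect_equal(inv$n_trna, 40L)
  expect_equal(inv$n_rrna, 8L)
  expect_equal(inv$n_one_intron, 11L)
})

test_that("a zero-gene layout yields an empty annotation and zero coding share", {
  p <- sim_params(lsc = 3000L, ir = 1000L, ssc = 500L,
                  genes = list(protein = list(n_lsc = 0L, n_ssc = 0L,
                                              n_ir = 0L, aa_mean = 100,
                                              aa_sd = 10, aa_min = 50L),
                               trna = list(n_lsc = 0L, n_ssc = 0L,
                                           n_ir = 0L, len_mean = 75,
                                           len_sd = 8, len_min = 60L),
                               rrna = list(ir_lengths = integer(0)),
                               introns = list(n_protein = 0L, n_trna = 0L,
                                              len_mean = 200, len_sd = 30,
                                              len_min = 100L)))
  anc <- generate_ancestor(p, seed = 2)
  expect_equal(nrow(anc$features), 0L)
  cs <- composition_summary(anc$plastome, anc$features)
  expect_equal(cs$coding_percent, 0)
  expect_equal(cs$intergenic_percent, 100)
})

test_that("an infeasible gene layout errors", {
  p <- small_params()
  p$lsc <- 1000L
  expect_error(generate_ancestor(p, seed = 1),
               class = "plastocmp_layout_infeasible")
})

test_that("zero-length branches copy the ancestor and leave no truth", {
  sim <- simulate_plastomes(small_params(tree = "(X:0.0,Y:0.0);"),
                            seed = 3)
  expect_identical(sim$leaves$sequence[1], sim$ancestor$plastome$sequence)
  expect_identical(sim$leaves$sequence[2], sim$ancestor$plastome$sequence)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("the same seed reproduces byte-identical simulations", {
  s1 <- simulate_plastomes(small_params(), seed = 5)
  s2 <- simulate_plastomes(small_params(), seed = 5)
  expect_identical(s1$leaves, s2$leaves)
  expect_identical(s1$truth, s2$truth)
})

test_that("replaying the truth reproduces every node sequence exactly", {
  sim <- small_sim()
  phy <- sim$tree
  n <- length(phy$tip.label)
  states <- list()
  states[[n + 1L]] <- sim$ancestor$plastome$sequence
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (r in seq_len(nrow(ord$edge))) {
    par <- ord$edge[r, 1]; child <- ord$edge[r, 2]
    nm <- if (child <= n) phy$tip.label[child] else paste0("node", child)
    bt <- sim$truth[sim$truth$branch == nm, ]
    states[[child]] <- replay_truth(states[[par]], bt)
  }
  for (v in seq_len(n)) {
    expect_identical(states[[v]], sim$leaves$sequence[v])
  }
})

test_that("inverted repeats stay exact reverse complements in every leaf", {
  for (sim in list(small_sim(), full_sim())) {
    for (id in sim$leaves$id) {
      q <- sim$quads[[id]]
      s <- sim$leaves$sequence[sim$leaves$id == id]
      ira <- substr(s, q$ira_start, q$ira_end)
      irb <- substr(s, q$irb_start, q$irb_end)
      expect_identical(revcomp(ira), irb)
      expect_equal(nchar(ira), q$ir_length)
    }
  }
})

test_that("annotation lift-over keeps reading frames intact through indels", {
  sim <- small_sim()
  gc11 <- plastocmp:::genetic_code_table("11")
  # a leaf gene without new internal stops must still start with M and
  # keep length divisible by 3 unless a frameshift truth event hit it
  fs_genes <- character(0)
  for (id in c("A", "E")) {
    feats <- sim$features[[id]]
    s <- sim$leaves$sequence[sim$leaves$id == id]
    for (gid in unique(feats$gene_id[feats$category == "protein_coding"])) {
      fx <- feats[feats$gene_id == gid, ]
      cds <- plastocmp:::cds_sequence(fx, s)
      if (nchar(cds) %% 3L != 0L) fs_genes <- c(fs_genes, gid)
    }
  }
  # every frame break must be explained by a frameshift-length truth indel
  tru <- sim$truth
  indels <- tru[tru$type %in% c("insertion", "deletion") &
                  tru$region == "coding" & tru$length %% 3L != 0L, ]
  expect_lte(length(fs_genes), nrow(indels) * 2L)
})

test_that("transition bias is recovered from calls at scale", {
  p <- small_params(tree = "(A:0.0,B:0.02);", kappa = 2,
                    mnv_rate = 0, indel_rate = 0)
  p$lsc <- 60000L; p$ir <- 8000L; p$ssc <- 4000L
  sim <- simulate_plastomes(p, seed = 8)
  quad <- detect_quadripartite(sim$leaves)
  red <- reduce_single_ir(sim$leaves, quad)
  pa <- align_pair(red, "A", "B")
  rp <- recover_parameters(call_variants(pa))
  expect_gte(rp$n_snp, 1000L)
  expect_lt(abs(rp$kappa_hat - 2) / 2, 0.15)
})

test_that("region enrichment follows the configured multipliers", {
  base <- small_params(tree = "(A:0.0,B:0.01);",
                       region_multipliers = c(coding = 1, intron = 1,
                                              intergenic = 1))
  sim <- simulate_plastomes(base, seed = 9)
  anc_len <- sim$ancestor$plastome$length
  pa <- align_pair(sim$leaves, "A", "B", method = "anchored")
  rp <- recover_parameters(call_variants(pa), sim$ancestor$features,
                           anc_len)
  # uniform multipliers: enrichment near 1 for the large regions
  expect_lt(abs(rp$enrichment_intergenic - 1), 0.35)
  expect_lt(abs(rp$enrichment_coding - 1), 0.35)

  biased <- small_params(tree = "(A:0.0,B:0.01);",
                         region_multipliers = c(coding = 1, intron = 1,
                                                intergenic = 3))
  sim2 <- simulate_plastomes(biased, seed = 9)
  pa2 <- align_pair(sim2$leaves, "A", "B", method = "anchored")
  rp2 <- recover_parameters(call_variants(pa2), sim2$ancestor$features,
                            sim2$ancestor$plastome$length)
  expect_gt(rp2$enrichment_intergenic, rp2$enrichment_coding * 1.5)
})

test_that("recovering parameters without SNPs warns and flags kappa", {
  v <- tibble::tibble(ref_id = "a", qry_id = "b", type = "deletion",
                      ref_position = 5L, ref_allele = "AA",
                      alt_allele = "", length = 2L)
  expect_warning(rp <- recover_parameters(v), "kappa")
  expect_true(is.na(rp$kappa_hat))
})
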