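test_that("adjacent mismatches merge into one MNV", {
  v <- call_variants(pair_tbl("AACCTT", "AAGGTT"))
  expect_equal(nrow(v), 1)
  expect_equal(v$type, "MNV")
  expect_equal(v$ref_position, 3L)
  expect_equal(v$ref_allele, "CC")
  expect_equal(v$alt_allele, "GG")
})

test_that("an indel abutting a mismatch stays two separate events", {
  # 5-column deletion directly followed by a mismatch column
  v <- call_variants(pair_tbl("AAACGTGACT", "AAA-----TT"))
  expect_equal(nrow(v), 2)
  expect_setequal(v$type, c("deletion", "SNP"))
  del <- v[v$type == "deletion", ]
  expect_equal(del$ref_position, 4L)
  expect_equal(del$length, 5L)
  snp <- v[v$type == "SNP", ]
  expect_equal(snp$ref_position, 9L)
})

test_that("transition/transversion typing follows the purine/pyrimidine classes", {
  expect_equal(classify_ts_tv("A", "G"), "transition")
  expect_equal(classify_ts_tv("C", "T"), "transition")
  expect_equal(classify_ts_tv("A", "C"), "transversion")
  expect_equal(classify_ts_tv(c("G", "T"), c("A", "A")),
               c("transition", "transversion"))
  expect_error(classify_ts_tv("AC", "GT"), class = "plastocmp_not_snp")
  expect_error(classify_ts_tv("A", "A"), class = "plastocmp_not_snp")
})

test_that("nucleotide differences count non-identical columns, gaps included", {
  expect_equal(nucleotide_differences(pair_tbl("ACGT", "ACGT")), 0L)
  p <- pair_tbl("AAACGTGAAA", "AAA-----AA")
  v <- call_variants(p)
  expect_equal(nrow(v), 1)
  expect_equal(nucleotide_differences(p), 5L)
  set.seed(21)
  a <- random_seq(1000); b <- random_seq(1000)
  expect_equal(nucleotide_differences(pair_tbl(a, b)),
               sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
})

test_that("N columns never contribute to variants or differences", {
  p <- pair_tbl("AANGT", "AACGT")
  expect_equal(nrow(call_variants(p)), 0)
  expect_equal(nucleotide_differences(p), 0L)
})

test_that("per-pair summary identities hold on simulated data", {
  sim <- small_sim()
  quad <- detect_quadripartite(sim$leaves, min_ir_length = 500)
  red <- reduce_single_ir(sim$leaves, quad)
  prs <- utils::combn(red$id, 2)
  for (k in sample(ncol(prs), 4)) {
    pa <- align_pair(red, prs[1, k], prs[2, k])
    vs <- variant_summary(call_variants(pa))
    if (nrow(vs) == 0) next
    expect_equal(vs$n_variants,
                 vs$n_deletions + vs$n_insertions + vs$n_mnv + vs$n_snp)
    expect_equal(vs$n_snp, vs$n_transitions + vs$n_transversions)
    expect_gte(nucleotide_differences(pa), vs$n_variants)
  }
})

test_that("swapping the pair swaps insertion and deletion labels only", {
  sim <- small_sim()
  quad <- detect_quadripartite(sim$leaves, min_ir_length = 500)
  red <- reduce_single_ir(sim$leaves, quad)
  sa <- variant_summary(call_variants(align_pair(red, "A", "B")))
  sb <- variant_summary(call_variants(align_pair(red, "B", "A")))
  expect_equal(sa$n_variants, sb$n_variants)
  expect_equal(sa$n_snp, sb$n_snp)
  expect_equal(sa$n_mnv, sb$n_mnv)
  expect_equal(sa$n_deletions, sb$n_insertions)
  expect_equal(sa$n_insertions, sb$n_deletions)
})

test_that("one extra SNP adds exactly one variant and one difference", {
  set.seed(22)
  a <- random_seq(3000)
  pos <- 1507
  alt <- setdiff(c("A", "C", "G", "T"),
                 substr(a, pos, pos))[1]
  b <- substitute_base(a, pos, alt)
  p <- plastome_tbl(a = a, b = b)
  al <- align_pair(p, "a", "b")
  expect_equal(nrow(call_variants(al)), 1)
  expect_equal(nucleotide_differences(al), 1L)
  pos2 <- 401
  alt2 <- setdiff(c("A", "C", "G", "T"), substr(b, pos2, pos2))[1]
  b2 <- substitute_base(b, pos2, alt2)
  al2 <- align_pair(plastome_tbl(a = a, b2 = b2), "a", "b2")
  expect_equal(nrow(call_variants(al2)), 2)
  expect_equal(nucleotide_differences(al2), 2L)
})

test_that("distance tables are symmetric with zero diagonal", {
  sim <- small_sim()
  d <- distance_matrices(sim$leaves, min_ir_length = 500)
  for (metric in c("variants", "nucleotide_differences")) {
    m <- as_dist_matrix(d, metric)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
  }
  expect_true(all(d$n_nucleotide_differences >= d$n_variants))
  expect_error(distance_matrices(sim$leaves[1, ]))
})

test_that("variants are assigned to regions by their start position", {
  toy <- plastome_tbl(t = random_seq(300))
  f <- tibble::tibble(gene_id = "g1", gene = "g1",
                      category = "protein_coding", strand = "+",
                      start = 101L, end = 200L, exon = 1L, copy = "single")
  v <- tibble::tibble(ref_id = "t", qry_id = "q", type = "SNP",
                      ref_position = c(120L, 150L), ref_allele = "A",
                      alt_allele = "G", length = 1L)
  rd <- region_distribution(v, f, 300L)
  expect_equal(rd$proportion[rd$region == "coding"], 1)
  expect_equal(sum(rd$proportion), 1)
  v$ref_position[1] <- 400L
  expect_error(region_distribution(v, f, 300L))
})

test_that("region assignment of called variants matches the generator truth", {
  sim <- branch_sim(seed = 2)
  pa <- align_pair(sim$leaves, "REF", "Q", method = "anchored")
  v <- call_variants(pa)
  tru <- sim$truth[sim$truth$branch == "Q", ]
  lab <- plastocmp:::coarse_labels(sim$ancestor$features,
                                   sim$ancestor$plastome$length)
  prim <- v[v$ref_position %in% tru$position, ]
  expect_gt(nrow(prim), 0)
  m <- match(prim$ref_position, tru$position)
  expect_equal(lab[prim$ref_position], tru$region[m])
})

test_that("the VCF writer anchors indels on the previous reference base", {
  ref <- plastome_tbl(r = "ACGTACGTAC")
  v <- tibble::tibble(ref_id = "r", qry_id = "q",
                      type = c("SNP", "deletion", "insertion"),
                      ref_position = c(2L, 4L, 7L),
                      ref_allele = c("C", "TA", ""),
                      alt_allele = c("T", "", "GG"),
                      length = c(1L, 2L, 2L))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, ref, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t")
  expect_equal(sapply(fields, `[`, 2), c("2", "3", "6"))
  expect_equal(sapply(fields, `[`, 4), c("C", "GTA", "C"))
  expect_equal(sapply(fields, `[`, 5), c("T", "G", "CGG"))
})
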