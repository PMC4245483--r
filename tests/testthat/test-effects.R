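## a tiny genome with one plus-strand gene whose CDS we control exactly
mk_gene_genome <- function(cds, flank = 30L, strand = "+") {
  set.seed(33)
  gseq <- if (strand == "+") cds else revcomp(cds)
  genome <- paste0(random_seq(flank), gseq, random_seq(flank))
  feats <- tibble::tibble(gene_id = "g1", gene = "g1",
                          category = "protein_coding", strand = strand,
                          start = flank + 1L, end = flank + nchar(cds),
                          exon = 1L, copy = "single")
  list(genome = plastome_tbl(ref = genome), features = feats)
}

snp_at <- function(pos, ref, alt) {
  tibble::tibble(ref_id = "ref", qry_id = "q", type = "SNP",
                 ref_position = pos, ref_allele = ref, alt_allele = alt,
                 length = 1L)
}

test_that("third-position wobble changes are synonymous", {
  g <- mk_gene_genome("ATGGGTTTAGCTTAA")     # M G L A *
  pos <- g$features$start + 5L               # GGT -> GGC
  eff <- variant_effect(snp_at(pos, "T", "C"), g$features, g$genome)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$aa_position, 2L)
  expect_equal(eff$aa_ref, "G")
  expect_equal(eff$aa_alt, "G")
})

test_that("an Asn-to-Ser style substitution is called non-synonymous", {
  g <- mk_gene_genome("ATGAATTTAGCTTAA")     # M N L A *
  pos <- g$features$start + 4L               # AAT -> AGT
  eff <- variant_effect(snp_at(pos, "A", "G"), g$features, g$genome)
  expect_equal(eff$effect, "nonsynonymous")
  expect_equal(eff$aa_position, 2L)
  expect_equal(eff$aa_ref, "N")
  expect_equal(eff$aa_alt, "S")
})

test_that("minus-strand genes are evaluated on the reverse complement", {
  g <- mk_gene_genome("ATGAATTTAGCTTAA", strand = "-")
  # genome carries revcomp(cds); codon 2 base 2 (A->G on the transcript)
  # sits at genome position end - 4
  pos <- g$features$end - 4L
  eff <- variant_effect(snp_at(pos, "T", "C"), g$features, g$genome)
  expect_equal(eff$effect, "nonsynonymous")
  expect_equal(eff$aa_position, 2L)
  expect_equal(eff$aa_ref, "N")
  expect_equal(eff$aa_alt, "S")
})

test_that("an MNV inside one codon is evaluated as a unit", {
  g <- mk_gene_genome("ATGGGTTTAGCTTAA")
  v <- tibble::tibble(ref_id = "ref", qry_id = "q", type = "MNV",
                      ref_position = g$features$start + 3L,
                      ref_allele = "GG", alt_allele = "TG", length = 2L)
  eff <- variant_effect(v, g$features, g$genome)
  expect_equal(eff$effect, "nonsynonymous")
  expect_equal(eff$aa_position, 2L)
})

test_that("frameshift truncation reproduces the 133 to 101 residue geometry", {
  fs <- synthesize_frameshift_gene(intact_aa = 133L, truncated_aa = 101L)
  gc11 <- plastocmp:::genetic_code_table("11")
  cds <- substr(fs$genome$sequence, fs$features$start, fs$features$end)
  intact <- plastocmp:::translate_cds(cds, gc11)
  expect_equal(nchar(intact) - 1L, 133L)      # stop excluded
  expect_false(grepl("*", substr(intact, 1, nchar(intact) - 1),
                     fixed = TRUE))
  eff <- variant_effect(fs$variant, fs$features, fs$genome)
  expect_equal(eff$effect, "frameshift")
  expect_equal(eff$truncated_length, 101L)
})

test_that("intron and intergenic variants have no protein effect", {
  g <- mk_gene_genome("ATGGGTTTAGCTTAA")
  eff <- variant_effect(snp_at(5L, "A", "G"), g$features, g$genome)
  expect_equal(eff$region, "intergenic")
  expect_equal(eff$effect, "none")
})

test_that("codon-level calls agree with a whole-protein translation oracle", {
  sim <- small_sim()
  quad <- detect_quadripartite(sim$leaves, min_ir_length = 500)
  red <- reduce_single_ir(sim$leaves, quad)
  pa <- align_pair(red, "A", "E")
  v <- call_variants(pa)
  featA <- reduce_features(sim$features$A, quad[quad$id == "A", ])
  refg <- red[red$id == "A", ]
  eff <- variant_effect(v, featA, refg)
  gc11 <- plastocmp:::genetic_code_table("11")
  checked <- 0
  for (r in which(eff$effect %in% c("synonymous", "nonsynonymous"))) {
    fx <- featA[featA$gene_id == eff$gene_id[r], ]
    cds <- plastocmp:::cds_sequence(fx, refg$sequence)
    pos <- plastocmp:::cds_positions(fx)
    span <- eff$ref_position[r]:(eff$ref_position[r] + eff$length[r] - 1L)
    ci <- match(span, pos)
    alt <- strsplit(eff$alt_allele[r], "")[[1]]
    if (fx$strand[1] == "-") alt <- plastocmp:::COMPLEMENT[alt]
    mut <- strsplit(cds, "")[[1]]
    mut[ci] <- alt
    p_ref <- plastocmp:::translate_cds(cds, gc11)
    p_alt <- plastocmp:::translate_cds(paste0(mut, collapse = ""), gc11)
    if (eff$effect[r] == "synonymous") {
      expect_identical(p_ref, p_alt)
    } else {
      d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
      expect_equal(d[1], eff$aa_position[r])
    }
    checked <- checked + 1
  }
  expect_gt(checked, 3)
})

test_that("effect summary counts only coding consequences", {
  g <- mk_gene_genome("ATGGGTTTAGCTTAA")
  v <- dplyr::bind_rows(
    snp_at(g$features$start + 5L, "T", "C"),   # synonymous
    snp_at(g$features$start + 4L, "G", "A"),   # nonsynonymous
    snp_at(5L, "A", "G"))                      # intergenic
  eff <- variant_effect(v, g$features, g$genome)
  es <- effect_summary(eff)
  expect_equal(es$n_synonymous, 1L)
  expect_equal(es$n_nonsynonymous, 1L)
  expect_equal(es$n_frameshift, 0L)
})

test_that("clade partition separates clade-specific and focal-unique keys", {
  taxa <- c("F", "a1", "a2", "b1", "b2")
  mk_at <- function(pos, alleles) {
    tibble::tibble(key = paste0("substitution:", pos, ":R"),
                   position = pos, kind = "substitution",
                   taxon = taxa, allele = alleles)
  }
  at <- dplyr::bind_rows(
    mk_at(10L, c("G", "G", "G", "A", "A")),   # clade-b specific
    mk_at(20L, c("T", "C", "C", "C", "C")),   # focal unique
    mk_at(30L, c("A", "A", "A", "A", "A")),   # invariant: no set
    mk_at(40L, c("C", "C", "A", "A", "A")))   # cladeA not uniform w focal:
  cmap <- tibble::tibble(id = c("a1", "a2", "b1", "b2"),
                         clade = c("cladeA", "cladeA", "cladeB", "cladeB"))
  part <- clade_partition(at, cmap, focal = "F")
  expect_equal(part$set[part$position == 10L], "cladeB_specific")
  expect_equal(part$set[part$position == 20L], "focal_unique")
  expect_false(30L %in% part$position)
  expect_false(40L %in% part$position)
  # reordering taxa does not change the partition
  at2 <- at[order(at$taxon, at$position), ]
  part2 <- clade_partition(at2, cmap[c(3, 1, 4, 2), ], focal = "F")
  expect_setequal(paste(part$position, part$set),
                  paste(part2$position, part2$set))
})

test_that("keys with missing taxa are skipped with a warning", {
  at <- tibble::tibble(key = "substitution:5:A", position = 5L,
                       kind = "substitution",
                       taxon = c("F", "a1", "b1"),
                       allele = c("A", "G", "A"))
  cmap <- tibble::tibble(id = c("a1", "a2", "b1"),
                         clade = c("cladeA", "cladeA", "cladeB"))
  expect_warning(part <- clade_partition(at, cmap, focal = "F"),
                 "skipped")
  expect_equal(nrow(part), 0)
  expect_equal(attr(part, "n_skipped"), 1L)
})

test_that("the allele table covers every taxon at every key", {
  v <- dplyr::bind_rows(
    snp_at(10L, "A", "G") |> dplyr::mutate(qry_id = "x"),
    snp_at(10L, "A", "G") |> dplyr::mutate(qry_id = "y"),
    tibble::tibble(ref_id = "ref", qry_id = "x", type = "deletion",
                   ref_position = 50L, ref_allele = "TTG",
                   alt_allele = "", length = 3L))
  at <- build_allele_table(v, "ref", taxa = c("ref", "x", "y", "z"))
  expect_equal(nrow(at), 2L * 4L)
  expect_equal(at$allele[at$taxon == "z" & at$kind == "substitution"], "A")
  expect_equal(at$allele[at$taxon == "x" & at$kind == "deletion"], "del")
  expect_equal(at$allele[at$taxon == "ref" & at$kind == "deletion"], "TTG")
})
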