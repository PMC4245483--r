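## End-to-end orchestration: structure -> align -> variants -> effects ->
## distances -> trees -> report bundle, with a machine-readable manifest.

#' Drop inverted-repeat-B features after IR reduction
#'
#' @param features full-genome feature tibble.
#' @param quad one-row structure tibble for the same genome.
#' @return features of the IR-reduced genome (IR_B copies removed).
#' @export
reduce_features <- function(features, quad) {
  features[features$end < quad$irb_start, , drop = FALSE]
}

#' Run the full comparative pipeline
#'
#' Executes every stage on a set of plastomes: quadripartite structure
#' detection, IR reduction, reference-pivot multiple alignment, variant
#' calling/classification and summaries, both distance matrices, coding
#' effects, clade partition, maximum-parsimony search with bootstrap,
#' neighbor-joining cross-check and outgroup rooting. Writes TSV/FASTA/
#' newick/VCF outputs plus a JSON manifest when `out_dir` is given.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `fasta` or `plastomes` (input genomes), optional `gff` or
#'   `features` (reference annotation), `ref_id`, `outgroup`,
#'   optional `clades` (named list: clade -> taxon ids, outgroup
#'   excluded), `min_ir_length` (1000), `n_additions` (200),
#'   `bootstrap_reps` (2000), `seed` (1), optional `out_dir`.
#' @return a list with every stage result, invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(name, default = NULL) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  t0 <- proc.time()[["elapsed"]]
  stage_times <- list()
  tick <- function(stage) {
    stage_times[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }
  plastomes <- if (!is.null(config$plastomes)) config$plastomes else
    read_plastomes(cfg("fasta") %||% abort("config needs fasta/plastomes"))
  features <- if (!is.null(config$features)) config$features else
    if (!is.null(config$gff)) read_annotation(config$gff) else NULL
  ref_id <- cfg("ref_id", plastomes$id[1])
  outgroup <- cfg("outgroup")
  seed <- cfg("seed", 1L)
  min_ir <- cfg("min_ir_length", 1000L)
  n_add <- cfg("n_additions", 200L)
  n_boot <- cfg("bootstrap_reps", 2000L)
  out_dir <- cfg("out_dir")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_tsv <- function(x, name) {
    if (!is.null(out_dir)) {
      utils::write.table(x, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  quad <- detect_quadripartite(plastomes, min_ir)
  save_tsv(quad, "structure.tsv")
  tick("structure")

  composition <- inventory <- NULL
  if (!is.null(features)) {
    composition <- composition_summary(plastome_record(plastomes, ref_id),
                                       features)
    inventory <- gene_inventory(features)
    save_tsv(composition, "composition.tsv")
    save_tsv(inventory, "gene_inventory.tsv")
  }
  tick("composition")

  reduced <- reduce_single_ir(plastomes, quad)
  others <- setdiff(reduced$id, ref_id)
  pairs <- dplyr::bind_rows(lapply(others, function(q) {
    align_pair(reduced, ref_id, q)
  }))
  aln <- project_to_reference(pairs, ref_id)
  if (!is.null(out_dir)) {
    write_alignment(aln, file.path(out_dir, "alignment.fasta"))
  }
  tick("align")

  variants <- call_variants(pairs)
  vsum <- variant_summary(variants)
  save_tsv(vsum, "variant_summary.tsv")
  save_tsv(variants, "variants.tsv")
  ref_reduced <- plastome_record(reduced, ref_id)
  if (!is.null(out_dir)) {
    write_vcf(variants, ref_reduced, file.path(out_dir, "variants.vcf"))
  }
  red_features <- NULL
  region_dist <- NULL
  if (!is.null(features)) {
    red_features <- reduce_features(features,
                                    quad[quad$id == ref_id, ])
    region_dist <- region_distribution(variants, red_features,
                                       ref_reduced$length)
    save_tsv(region_dist, "region_distribution.tsv")
  }
  tick("variants")

  distances <- distance_matrices(plastomes, reduce_ir = TRUE,
                                 min_ir_length = min_ir)
  save_tsv(distances, "distances.tsv")
  tick("distances")

  effects <- esum <- partition <- NULL
  if (!is.null(red_features)) {
    effects <- variant_effect(variants, red_features, ref_reduced)
    esum <- effect_summary(effects)
    save_tsv(effects, "effects.tsv")
    save_tsv(esum, "effect_summary.tsv")
    clades <- cfg("clades")
    if (!is.null(clades)) {
      clade_map <- dplyr::bind_rows(lapply(names(clades), function(cl) {
        tibble(id = clades[[cl]], clade = cl)
      }))
      ingroup_variants <- variants[variants$qry_id %in% clade_map$id, ,
                                   drop = FALSE]
      at <- build_allele_table(ingroup_variants, ref_id,
                               taxa = c(ref_id, clade_map$id))
      partition <- clade_partition(at, clade_map, focal = ref_id)
      save_tsv(partition, "clade_partition.tsv")
    }
  }
  tick("effects")

  cm <- build_character_matrix(aln)
  site_classes <- glance(cm)
  save_tsv(site_classes, "site_classes.tsv")
  fit <- heuristic_search(cm, n_additions = n_add, seed = seed + 1L)
  boot <- bootstrap_support(cm, n_reps = n_boot, seed = seed + 2L,
                            fit = fit)
  mp_tree <- boot$tree
  if (!is.null(outgroup)) mp_tree <- root_with_outgroup(mp_tree, outgroup)
  if (!is.null(out_dir)) {
    ape::write.tree(mp_tree, file.path(out_dir, "mp_tree.nwk"))
    write_phylip(aln, file.path(out_dir, "alignment.phy"))
    write_nexus(aln, file.path(out_dir, "alignment.nex"))
  }
  tick("parsimony")

  nj_tree <- neighbor_joining(distances)
  if (!is.null(outgroup)) nj_tree <- root_with_outgroup(nj_tree, outgroup)
  if (!is.null(out_dir)) {
    ape::write.tree(nj_tree, file.path(out_dir, "nj_tree.nwk"))
  }
  tick("nj")

  manifest <- list(
    inputs = list(taxa = plastomes$id, ref_id = ref_id,
                  outgroup = outgroup),
    parameters = list(min_ir_length = min_ir, n_additions = n_add,
                      bootstrap_reps = n_boot, seed = seed),
    versions = list(plastocmp = as.character(utils::packageVersion("plastocmp")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    stage_seconds = stage_times)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(quad = quad, composition = composition,
                 inventory = inventory, alignment = aln, pairs = pairs,
                 variants = variants, variant_summary = vsum,
                 region_distribution = region_dist,
                 distances = distances, effects = effects,
                 effect_summary = esum, clade_partition = partition,
                 character_matrix = cm, site_classes = site_classes,
                 fit = fit, bootstrap = boot, mp_tree = mp_tree,
                 nj_tree = nj_tree, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Download the study accessions (optional helper)
#'
#' Fetches chloroplast genome FASTA records from NCBI efetch into a
#' directory, one file per accession. Requires network access; nothing in
#' the package or its tests depends on it.
#'
#' @param dest_dir destination directory.
#' @param accessions GenBank accession ids.
#' @return paths of the downloaded files, invisibly.
#' @export
fetch_accessions <- function(dest_dir,
                             accessions = c("KF428978", "GU592207",
                                            "AY522329", "JN005831",
                                            "JN005833", "JN005832",
                                            "AP006728", "GU592209")) {
  if (!dir.exists(dest_dir)) dir.create(dest_dir, recursive = TRUE)
  base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                 "efetch.fcgi?db=nuccore&rettype=fasta&retmode=text&id=")
  paths <- vapply(accessions, function(acc) {
    p <- file.path(dest_dir, paste0(acc, ".fasta"))
    download.file(paste0(base, acc), p, quiet = TRUE)
    p
  }, character(1))
  invisible(paths)
}

#' Rerun the published comparative analysis from downloaded genomes
#'
#' Given a directory of the eight study accessions (see
#' [fetch_accessions()]), recomputes the structural lengths, IR-reduced
#' lengths, pairwise variant counts, site classification, parsimony
#' statistics and bootstrap supports, and returns them alongside the
#' published reference values for comparison.
#'
#' @param fasta_dir directory of per-accession FASTA files.
#' @param n_boot bootstrap pseudoreplicates.
#' @param seed integer seed.
#' @return a list: `structure`, `distances`, `site_classes`, `fit`,
#'   `bootstrap`, `checks` (tibble of measured vs reference values).
#' @export
reproduce_study <- function(fasta_dir, n_boot = 2000L, seed = 1L) {
  files <- list.files(fasta_dir, pattern = "\\.fasta$",
                      full.names = TRUE)
  if (length(files) == 0L) abort("no FASTA files in fasta_dir")
  plastomes <- dplyr::bind_rows(lapply(files, read_plastomes))
  quad <- detect_quadripartite(plastomes)
  reduced <- reduce_single_ir(plastomes, quad)
  distances <- distance_matrices(plastomes)
  taxon_a <- plastomes$id[grepl("KF428978", plastomes$id)][1]
  aln <- multi_align(reduced, taxon_a)
  cm <- build_character_matrix(aln)
  fit <- heuristic_search(cm, n_additions = 200L, seed = seed)
  boot <- bootstrap_support(cm, n_reps = n_boot, seed = seed + 1L,
                            fit = fit)
  ka <- quad[quad$id == taxon_a, ]
  checks <- tibble(
    quantity = c("full_length", "ir_length", "lsc_length", "ssc_length",
                 "ir_reduced_length", "n_constant",
                 "n_variable_uninformative", "n_informative",
                 "mp_tree_length", "CI", "RI", "CI_excl"),
    measured = c(plastome_record(plastomes, taxon_a)$length,
                 ka$ir_length, ka$lsc_end - ka$lsc_start + 1,
                 ka$ssc_end - ka$ssc_start + 1,
                 plastome_record(reduced, taxon_a)$length,
                 glance(cm)$n_constant,
                 glance(cm)$n_variable_uninformative,
                 glance(cm)$n_parsimony_informative,
                 fit$length, round(fit$CI, 2), round(fit$RI, 2),
                 round(fit$CI_excluding_uninformative, 2)),
    reference = c(134557, 20803, 80604, 12347, 113754, 112969, 903, 88,
                  1014, 0.98, 0.89, 0.84))
  list(structure = quad, distances = distances,
       site_classes = glance(cm), fit = fit, bootstrap = boot,
       checks = checks)
}
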