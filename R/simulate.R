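## Synthetic plastome evolution. generate_ancestor() builds a circular
## quadripartite genome (LSC + IR_A + SSC + revcomp(IR_A)) with an
## annotated gene layout; evolve() walks a tree and applies SNP, MNV and
## indel events with transition bias and region-dependent rates, mirroring
## every inverted-repeat event to the other copy (concerted evolution, so
## the IRs stay perfect repeats), and emits the full ground truth.

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulation parameters
#'
#' Defaults emulate an A-genome rice plastome: a 134,557 bp quadripartite
#' genome (LSC 80,604, IR 20,803 x 2, SSC 12,347), ~58% coding with 162
#' gene entries (114 protein-coding, 40 tRNA, 8 rRNA; 11 one-intron
#' genes), AT content 61%, and divergence profiles giving tens of events
#' between close taxa and several hundred against an outgroup,
#' SNP-dominated with minority MNV/indel and intergenic-biased placement.
#'
#' @param lsc,ir,ssc region lengths in bases.
#' @param at_content genome-wide AT fraction.
#' @param tree newick string (branch lengths in expected substitutions
#'   per site) along which [evolve()] walks.
#' @param kappa expected transition:transversion event-count ratio
#'   (P(transition | substitution) = kappa/(kappa+1)).
#' @param mnv_rate,indel_rate MNV and indel event rates relative to the
#'   substitution rate (events per site per unit branch length).
#' @param mnv_len_mean,indel_len_mean mean MNV length (>= 2) and mean
#'   indel length (>= 1, geometric).
#' @param region_multipliers named relative rate multipliers for coding,
#'   intron and intergenic sites (intergenic >= intron >= coding).
#' @param min_event_gap minimum spacing in bases between events on one
#'   branch; keeps event classes disjoint.
#' @param genes gene-layout specification (counts and mean lengths per
#'   category and region); see the built default.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(lsc = 80604L, ir = 20803L, ssc = 12347L,
                       at_content = 0.61,
                       tree = default_sim_tree(),
                       kappa = 1.5,
                       mnv_rate = 0.115, indel_rate = 0.315,
                       mnv_len_mean = 2.5, indel_len_mean = 4,
                       region_multipliers = c(coding = 1, intron = 1.8,
                                              intergenic = 5.2),
                       min_event_gap = 2L,
                       genes = default_gene_layout()) {
  stopifnot(lsc > 0, ir > 0, ssc > 0, kappa > 0,
            mnv_rate >= 0, indel_rate >= 0,
            all(region_multipliers > 0))
  if (!(region_multipliers[["intergenic"]] >=
        region_multipliers[["intron"]] &&
        region_multipliers[["intron"]] >=
        region_multipliers[["coding"]])) {
    abort("region multipliers must satisfy intergenic >= intron >= coding")
  }
  structure(list(lsc = as.integer(lsc), ir = as.integer(ir),
                 ssc = as.integer(ssc), at_content = at_content,
                 tree = tree, kappa = kappa, mnv_rate = mnv_rate,
                 indel_rate = indel_rate, mnv_len_mean = mnv_len_mean,
                 indel_len_mean = indel_len_mean,
                 region_multipliers = region_multipliers,
                 min_event_gap = as.integer(min_event_gap),
                 genes = genes),
            class = "sim_params")
}

#' @rdname sim_params
#' @export
default_gene_layout <- function() {
  list(
    protein = list(n_lsc = 82L, n_ssc = 12L, n_ir = 10L,
                   aa_mean = 192, aa_sd = 60, aa_min = 50L),
    trna = list(n_lsc = 26L, n_ssc = 2L, n_ir = 6L,
                len_mean = 75, len_sd = 8, len_min = 60L),
    rrna = list(ir_lengths = c(2900L, 1490L, 120L, 110L)),
    introns = list(n_protein = 5L, n_trna = 6L,
                   len_mean = 1064, len_sd = 150, len_min = 400L)
  )
}

#' @rdname sim_params
#' @export
default_sim_tree <- function() {
  paste0(
    "((TaxonA:0.00011,(TaxonB:0.00013265,",
    "O_meridionalis:0.00004415):0.000033):0.000175,",
    "((O_sativa_indica:0.000148,O_nivara:0.000148):0.00003,",
    "(O_sativa_japonica:0.00034,O_rufipogon:0.000273):0.00003):0.000175,",
    "O_australiensis:0.004189);")
}

random_dna <- function(n, at) {
  if (n == 0L) return("")
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste0(sample(DNA_BASES, n, replace = TRUE, prob = p[DNA_BASES]),
         collapse = "")
}

random_orf <- function(aa, at) {
  gc <- genetic_code_table("11")
  codons <- names(gc)
  ok <- gc != "*" & !grepl("N", codons)
  codons <- codons[ok]
  w <- vapply(strsplit(codons, ""), function(ch) {
    prod(ifelse(ch %in% c("A", "T"), at / 2, (1 - at) / 2))
  }, numeric(1))
  body <- sample(codons, aa - 1L, replace = TRUE, prob = w)
  paste0("ATG", paste0(body, collapse = ""), "TAA")
}

## random integer partition of `total` into n parts (spacers)
random_partition <- function(total, n) {
  if (n == 0L) return(integer(0))
  if (total == 0L) return(integer(n))
  as.integer(rmultinom(1L, total, rep(1 / n, n)))
}

## lay out one region: returns sequence and feature rows (local coords)
layout_region <- function(region_len, gene_specs, at) {
  n <- length(gene_specs)
  span <- sum(vapply(gene_specs, function(g) g$total_len, integer(1)))
  if (span > region_len) {
    abort(sprintf("gene layout infeasible: %d bp of genes in a %d bp region",
                  span, region_len),
          class = "plastocmp_layout_infeasible")
  }
  spacers <- random_partition(region_len - span, n + 1L)
  seqs <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_len(n)) {
    seqs <- c(seqs, random_dna(spacers[i], at))
    pos <- pos + spacers[i]
    g <- gene_specs[[i]]
    gseq <- g$sequence
    strand <- g$strand
    if (strand == "-") gseq <- revcomp(gseq)
    # g$exons are transcript-orientation offsets on g$sequence; on the
    # genome a minus-strand gene is reverse-complemented, so flip them
    ex <- g$exons
    n_ex <- length(ex)
    for (j in seq_len(n_ex)) {
      s <- ex[[j]][1]; e <- ex[[j]][2]
      if (strand == "-") {
        gs <- g$total_len - e + 1L; ge <- g$total_len - s + 1L
      } else {
        gs <- s; ge <- e
      }
      feats[[length(feats) + 1L]] <- tibble(
        gene_id = g$gene_id, gene = g$gene, category = g$category,
        strand = strand, start = pos + gs,
        end = pos + ge, exon = j, copy = g$copy)
    }
    seqs <- c(seqs, gseq)
    pos <- pos + g$total_len
  }
  seqs <- c(seqs, random_dna(spacers[n + 1L], at))
  list(sequence = paste0(seqs, collapse = ""),
       features = dplyr::bind_rows(feats))
}

make_gene_specs <- function(params) {
  g <- params$genes
  at <- params$at_content
  specs <- list(lsc = list(), ssc = list(), ir = list())
  gid <- 0L
  add <- function(region, category, seqlen_fun, label) {
    gid <<- gid + 1L
    list(region = region, category = category, label = label, id = gid)
  }
  draw_aa <- function() {
    as.integer(max(g$protein$aa_min,
                   round(stats::rnorm(1, g$protein$aa_mean,
                                      g$protein$aa_sd))))
  }
  draw_trna <- function() {
    as.integer(max(g$trna$len_min, round(stats::rnorm(1, g$trna$len_mean,
                                                      g$trna$len_sd))))
  }
  draw_intron <- function() {
    as.integer(max(g$introns$len_min,
                   round(stats::rnorm(1, g$introns$len_mean,
                                      g$introns$len_sd))))
  }
  mk_protein <- function(id, region, with_intron) {
    aa <- draw_aa()
    cds <- random_orf(aa, at)
    cdslen <- nchar(cds)
    name <- sprintf("pg%03d", id)
    if (with_intron) {
      ilen <- draw_intron()
      cut <- 3L * sample.int(aa - 2L, 1L)      # interior codon boundary
      list(gene_id = name, gene = name, category = "protein_coding",
           strand = sample(c("+", "-"), 1L), copy = "single",
           sequence = paste0(substr(cds, 1L, cut),
                             random_dna(ilen, at),
                             substr(cds, cut + 1L, cdslen)),
           exons = list(c(1L, cut), c(cut + ilen + 1L, cdslen + ilen)),
           total_len = cdslen + ilen)
    } else {
      list(gene_id = name, gene = name, category = "protein_coding",
           strand = sample(c("+", "-"), 1L), copy = "single",
           sequence = cds, exons = list(c(1L, cdslen)),
           total_len = cdslen)
    }
  }
  mk_trna <- function(id, with_intron) {
    len <- draw_trna()
    name <- sprintf("trn%02d", id)
    if (with_intron) {
      ilen <- draw_intron()
      cut <- sample.int(len - 2L, 1L) + 1L
      s <- random_dna(len, at)
      list(gene_id = name, gene = name, category = "tRNA",
           strand = sample(c("+", "-"), 1L), copy = "single",
           sequence = paste0(substr(s, 1L, cut), random_dna(ilen, at),
                             substr(s, cut + 1L, len)),
           exons = list(c(1L, cut), c(cut + ilen + 1L, len + ilen)),
           total_len = len + ilen)
    } else {
      list(gene_id = name, gene = name, category = "tRNA",
           strand = sample(c("+", "-"), 1L), copy = "single",
           sequence = random_dna(len, at), exons = list(c(1L, len)),
           total_len = len)
    }
  }
  mk_rrna <- function(id, len) {
    name <- sprintf("rrn%02d", id)
    list(gene_id = name, gene = name, category = "rRNA",
         strand = "+", copy = "single",
         sequence = random_dna(len, at), exons = list(c(1L, len)),
         total_len = len)
  }
  p <- g$protein
  lsc <- list(); ssc <- list(); ir <- list()
  for (i in seq_len(p$n_lsc)) {
    lsc[[length(lsc) + 1L]] <- mk_protein(i, "lsc",
                                          i <= g$introns$n_protein)
  }
  for (i in seq_len(p$n_ssc)) {
    ssc[[length(ssc) + 1L]] <- mk_protein(p$n_lsc + i, "ssc", FALSE)
  }
  for (i in seq_len(p$n_ir)) {
    ir[[length(ir) + 1L]] <- mk_protein(p$n_lsc + p$n_ssc + i, "ir",
                                        FALSE)
  }
  t <- g$trna
  for (i in seq_len(t$n_lsc)) {
    lsc[[length(lsc) + 1L]] <- mk_trna(i, i <= g$introns$n_trna)
  }
  for (i in seq_len(t$n_ssc)) {
    ssc[[length(ssc) + 1L]] <- mk_trna(t$n_lsc + i, FALSE)
  }
  for (i in seq_len(t$n_ir)) {
    ir[[length(ir) + 1L]] <- mk_trna(t$n_lsc + t$n_ssc + i, FALSE)
  }
  for (i in seq_along(g$rrna$ir_lengths)) {
    ir[[length(ir) + 1L]] <- mk_rrna(i, g$rrna$ir_lengths[i])
  }
  # IR genes are duplicated by construction
  ir <- lapply(ir, function(x) {
    x$copy <- "IR-duplicated"
    x$gene_id <- paste0(x$gene_id, "_ira")
    x
  })
  list(lsc = sample(lsc), ssc = sample(ssc), ir = sample(ir))
}

#' Generate the ancestral plastome
#'
#' Builds genome = LSC + IR\eqn{_A} + SSC + revcomp(IR\eqn{_A}) with
#' genes placed without overlap (IR genes duplicated with mirrored
#' coordinates and flipped strand) and the matching annotation.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return a list: `plastome` (one-row tibble, id `"ancestor"`),
#'   `features`, `quad` (structure tibble), `params`.
#' @export
generate_ancestor <- function(params = sim_params(), seed = 1L) {
  set.seed(seed)
  specs <- make_gene_specs(params)
  lsc <- layout_region(params$lsc, specs$lsc, params$at_content)
  ira <- layout_region(params$ir, specs$ir, params$at_content)
  ssc <- layout_region(params$ssc, specs$ssc, params$at_content)
  # pin the SSC edges: if its first base complemented its last base the
  # inverted-repeat pair would extend one base past the nominal boundary
  # and detection would (correctly) report a longer IR than configured
  s_len <- nchar(ssc$sequence)
  s_first <- substr(ssc$sequence, 1L, 1L)
  s_last <- substr(ssc$sequence, s_len, s_len)
  edge_in_gene <- nrow(ssc$features) > 0L &&
    (any(ssc$features$start == 1L) | any(ssc$features$end == s_len))
  if (!edge_in_gene && s_first == COMPLEMENT[[s_last]]) {
    repl <- setdiff(DNA_BASES, COMPLEMENT[[s_last]])[1]
    substr(ssc$sequence, 1L, 1L) <- repl
  }
  L <- params$lsc + 2L * params$ir + params$ssc
  astart <- params$lsc + 1L
  aend <- params$lsc + params$ir
  bstart <- params$lsc + params$ir + params$ssc + 1L
  bend <- L
  shift_feats <- function(f, off) {
    if (nrow(f) == 0L) return(f)
    f$start <- f$start + off; f$end <- f$end + off
    f
  }
  fa <- shift_feats(ira$features, params$lsc)
  # mirrored IR_B copies
  fb <- fa
  if (nrow(fb)) {
    s <- bstart + (aend - fa$end)
    e <- bstart + (aend - fa$start)
    fb$start <- s; fb$end <- e
    fb$strand <- ifelse(fa$strand == "+", "-", "+")
    fb$gene_id <- sub("_ira$", "_irb", fb$gene_id)
  }
  features <- dplyr::bind_rows(
    tibble(gene_id = character(0), gene = character(0),
           category = character(0), strand = character(0),
           start = integer(0), end = integer(0), exon = integer(0),
           copy = character(0)),
    lsc$features,
    fa,
    shift_feats(ssc$features, params$lsc + params$ir),
    fb) |>
    dplyr::arrange(.data$start)
  sequence <- paste0(lsc$sequence, ira$sequence, ssc$sequence,
                     revcomp(ira$sequence))
  quad <- tibble(id = "ancestor", lsc_start = 1L, lsc_end = params$lsc,
                 ira_start = astart, ira_end = aend,
                 ssc_start = aend + 1L, ssc_end = bstart - 1L,
                 irb_start = bstart, irb_end = bend,
                 ir_length = params$ir, offset = 0L)
  list(plastome = tibble(id = "ancestor", sequence = sequence,
                         length = L, circular = TRUE),
       features = features, quad = quad, params = params)
}

## ---- evolution along a tree ----

mirror_pos <- function(p, quad) {
  quad$irb_start + (quad$ira_end - p)
}

in_ira <- function(p, quad) p >= quad$ira_start & p <= quad$ira_end
in_irb <- function(p, quad) p >= quad$irb_start & p <= quad$irb_end

## coarse region label vector used for rate multipliers and constraints
coarse_labels <- function(features, L) {
  lab <- region_labels(features, L)
  lab[lab %in% c("protein_coding", "tRNA", "rRNA")] <- "coding"
  lab
}

## run id vector: maximal runs of identical coarse label; events are kept
## within one run so annotation lift-over stays exact
label_runs <- function(lab) {
  cumsum(c(TRUE, lab[-1] != lab[-length(lab)]))
}

draw_alt_base <- function(ref, kappa) {
  if (stats::runif(1) < kappa / (kappa + 1)) {
    TRANSITION_OF[[ref]]
  } else {
    sample(setdiff(DNA_BASES, c(ref, TRANSITION_OF[[ref]])), 1L)
  }
}

## draw the event list for one branch; positions are parent coordinates
draw_branch_events <- function(seq, features, quad, bl, params) {
  L <- nchar(seq)
  ch <- seq_chars(seq)
  lab <- coarse_labels(features, L)
  runs <- label_runs(lab)
  mult <- params$region_multipliers[lab]
  w <- mult / sum(mult)
  n_sub <- rpois(1L, bl * L)
  n_mnv <- rpois(1L, params$mnv_rate * bl * L)
  n_indel <- rpois(1L, params$indel_rate * bl * L)
  n_tot <- n_sub + n_mnv + n_indel
  if (n_tot == 0L) return(list())
  types <- sample(c(rep("sub", n_sub), rep("mnv", n_mnv),
                    rep("indel", n_indel)))
  occupied <- logical(L)
  gap <- params$min_event_gap
  # substitution events need only the configured spacing; indels reserve a
  # wider halo (their length plus the affine gap penalty span) so that no
  # two events can share an equally-scoring alternative alignment — this
  # keeps the emitted truth representation-unique for the caller
  reserve <- function(s, e, margin = gap) {
    s2 <- max(1L, s - margin); e2 <- min(L, e + margin)
    if (any(occupied[s2:e2])) return(FALSE)
    occupied[s2:e2] <<- TRUE
    TRUE
  }
  pool <- sample.int(L, min(L, 20L * n_tot + 50L), replace = TRUE,
                     prob = w)
  pi <- 0L
  next_pos <- function() {
    pi <<- pi + 1L
    if (pi > length(pool)) abort("event position pool exhausted")
    pool[pi]
  }
  events <- list()
  for (ty in types) {
    placed <- FALSE
    for (try in 1:200) {
      p <- next_pos()
      if (ch[p] == "N") next
      if (ty == "sub") {
        span_e <- p
      } else if (ty == "mnv") {
        len <- 2L + rgeom(1L, 1 / (params$mnv_len_mean - 1))
        span_e <- p + len - 1L
      } else {
        len <- 1L + rgeom(1L, 1 / params$indel_len_mean)
        is_del <- stats::runif(1) < 0.5
        span_e <- if (is_del) p + len - 1L else p
      }
      if (span_e > L) next
      # stay inside one region run and one IR context
      if (runs[p] != runs[span_e]) next
      if (ty == "indel" && !is_del) {
        # insertion point strictly interior to a run
        if (p <= 1L || runs[p - 1L] != runs[p]) next
      }
      ira <- in_ira(p, quad); irb <- in_irb(p, quad)
      if (ira && !in_ira(span_e, quad)) next
      if (irb && !in_irb(span_e, quad)) next
      mirrored <- ira || irb
      # draw the event itself; all rejections happen before reserving
      ev <- NULL
      if (ty == "sub") {
        alt <- draw_alt_base(ch[p], params$kappa)
        ev <- list(type = "SNP", position = p, ref = ch[p], alt = alt,
                   length = 1L)
      } else if (ty == "mnv") {
        refs <- ch[p:span_e]
        if (any(refs == "N")) next
        alts <- vapply(refs, draw_alt_base, character(1),
                       kappa = params$kappa)
        ev <- list(type = "MNV", position = p,
                   ref = paste0(refs, collapse = ""),
                   alt = paste0(alts, collapse = ""),
                   length = span_e - p + 1L)
      } else if (is_del) {
        # reject deletions whose aligned representation is not unique
        # (left-shiftable within a repeat), so called positions match
        # the truth exactly; mirrored copies need the mirrored check
        if (p <= 1L || span_e >= L) next
        if (ch[p - 1L] == ch[span_e]) next
        if (mirrored && ch[p] == ch[span_e + 1L]) next
        ev <- list(type = "deletion", position = p,
                   ref = paste0(ch[p:span_e], collapse = ""), alt = "",
                   length = span_e - p + 1L)
      } else {
        ins <- random_dna(len, params$at_content)
        iv <- seq_chars(ins)
        if (iv[len] == ch[p - 1L]) next
        if (mirrored && iv[1L] == ch[p]) next
        ev <- list(type = "insertion", position = p, ref = "",
                   alt = ins, length = len)
      }
      margin <- if (ty == "indel") len + 9L else gap
      if (!reserve(p, span_e, margin)) next
      if (mirrored) {
        ms <- mirror_pos(span_e, quad); me <- mirror_pos(p, quad)
        if (!reserve(ms, me, margin)) next
      }
      ev$in_ir <- mirrored
      ev$mirror_position <- if (mirrored) mirror_pos(span_e, quad) else
        NA_integer_
      ev$region <- lab[p]
      events[[length(events) + 1L]] <- ev
      placed <- TRUE
      break
    }
    if (!placed) {
      warn("could not place an event after 200 tries; branch underfilled")
    }
  }
  events
}

## expand mirrored events into concrete edits (the stored mirror
## position is the start of the twin's span on the parent sequence)
expand_edits <- function(events) {
  edits <- list()
  for (ev in events) {
    edits[[length(edits) + 1L]] <- ev
    if (isTRUE(ev$in_ir)) {
      tw <- ev
      tw$in_ir <- FALSE
      if (ev$type == "insertion") {
        # insertion before p maps to insertion before mirror(p) + 1
        tw$position <- ev$mirror_position + 1L
        tw$alt <- revcomp(ev$alt)
      } else {
        tw$position <- ev$mirror_position
        tw$ref <- revcomp(ev$ref)
        tw$alt <- revcomp(ev$alt)
      }
      edits[[length(edits) + 1L]] <- tw
    }
  }
  edits
}

apply_edits <- function(seq, edits) {
  if (length(edits) == 0L) return(seq)
  pos <- vapply(edits, function(e) e$position, integer(1))
  for (i in order(pos, decreasing = TRUE)) {
    e <- edits[[i]]
    p <- e$position
    if (e$type %in% c("SNP", "MNV")) {
      seq <- paste0(substr(seq, 1L, p - 1L), e$alt,
                    substr(seq, p + e$length, nchar(seq)))
    } else if (e$type == "deletion") {
      seq <- paste0(substr(seq, 1L, p - 1L),
                    substr(seq, p + e$length, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1L, p - 1L), e$alt,
                    substr(seq, p, nchar(seq)))
    }
  }
  seq
}

## shift annotation and structure boundaries through one indel
shift_through <- function(x, p, delta) {
  # x: positions; insertion before p adds delta at >= p; deletion of
  # [p, p+len-1] subtracts len at > span (callers pass span-consistent p)
  ifelse(x >= p, x + delta, x)
}

lift_features <- function(features, edits) {
  f <- features
  pos <- vapply(edits, function(e) e$position, integer(1))
  for (i in order(pos, decreasing = TRUE)) {
    e <- edits[[i]]
    if (e$type == "SNP" || e$type == "MNV") next
    p <- e$position
    if (e$type == "insertion") {
      len <- e$length
      inside <- f$start < p & f$end >= p
      f$end[inside] <- f$end[inside] + len
      after <- f$start >= p
      f$start[after] <- f$start[after] + len
      f$end[after & !inside] <- f$end[after & !inside] + len
    } else {
      len <- e$length
      inside <- f$start <= p & f$end >= p + len - 1L
      f$end[inside] <- f$end[inside] - len
      after <- f$start > p
      f$start[after] <- f$start[after] - len
      f$end[after & !inside] <- f$end[after & !inside] - len
    }
  }
  f
}

lift_quad <- function(quad, edits, L_new) {
  q <- quad
  pos <- vapply(edits, function(e) e$position, integer(1))
  bcols <- c("lsc_end", "ira_start", "ira_end", "ssc_start", "ssc_end",
             "irb_start", "irb_end")
  for (i in order(pos, decreasing = TRUE)) {
    e <- edits[[i]]
    if (e$type %in% c("SNP", "MNV")) next
    delta <- if (e$type == "insertion") e$length else -e$length
    p <- e$position
    for (col in bcols) {
      if (q[[col]] >= p) q[[col]] <- q[[col]] + delta
    }
  }
  q$irb_end <- L_new
  q$ir_length <- q$ira_end - q$ira_start + 1L
  q
}

truth_row <- function(ev, branch) {
  tibble(branch = branch, type = ev$type, position = ev$position,
         ref_allele = ev$ref, alt_allele = ev$alt, length = ev$length,
         in_ir = ev$in_ir, mirror_position = ev$mirror_position,
         region = ev$region)
}

#' Evolve a plastome along a tree
#'
#' Walks the tree from the root (the ancestor), drawing SNP, MNV and
#' indel events per branch with region-dependent rates and transition
#' bias. Events falling in either inverted repeat are mirrored to the
#' other copy, so every genome's IRs remain exact reverse complements.
#' Deterministic given `seed`.
#'
#' @param ancestor list from [generate_ancestor()].
#' @param tree `phylo` or newick string; defaults to the tree in
#'   `ancestor$params`.
#' @param seed integer seed.
#' @return a list: `leaves` (plastome tibble), `features` (named list of
#'   per-leaf feature tibbles), `quads` (named list), `truth` (tibble of
#'   per-branch events in parent coordinates, IR-mirrored events counted
#'   once with their mirror position), `tree` (phylo), `ancestor`.
#' @export
evolve <- function(ancestor, tree = NULL, seed = 1L) {
  params <- ancestor$params
  if (is.null(tree)) tree <- params$tree
  phy <- if (inherits(tree, "phylo")) tree else
    ape::read.tree(text = tree)
  if (is.null(phy$edge.length)) abort("tree must have branch lengths")
  set.seed(seed)
  n <- length(phy$tip.label)
  root <- n + 1L
  node_name <- function(v) {
    if (v <= n) phy$tip.label[v] else paste0("node", v)
  }
  states <- list()
  states[[root]] <- list(seq = ancestor$plastome$sequence,
                         features = ancestor$features,
                         quad = ancestor$quad)
  truth <- list()
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (r in seq_len(nrow(ord$edge))) {
    par <- ord$edge[r, 1]; child <- ord$edge[r, 2]
    bl <- ord$edge.length[r]
    st <- states[[par]]
    events <- draw_branch_events(st$seq, st$features, st$quad, bl,
                                 params)
    edits <- expand_edits(events)
    child_seq <- apply_edits(st$seq, edits)
    child_feats <- lift_features(st$features, edits)
    child_quad <- lift_quad(st$quad, edits, nchar(child_seq))
    states[[child]] <- list(seq = child_seq, features = child_feats,
                            quad = child_quad)
    if (length(events)) {
      truth[[length(truth) + 1L]] <-
        dplyr::bind_rows(lapply(events, truth_row,
                                branch = node_name(child)))
    }
  }
  leaves <- dplyr::bind_rows(lapply(seq_len(n), function(v) {
    tibble(id = phy$tip.label[v], sequence = states[[v]]$seq,
           length = nchar(states[[v]]$seq), circular = TRUE)
  }))
  feats <- setNames(lapply(seq_len(n), function(v) states[[v]]$features),
                    phy$tip.label)
  quads <- setNames(lapply(seq_len(n), function(v) {
    q <- states[[v]]$quad
    q$id <- phy$tip.label[v]
    q
  }), phy$tip.label)
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble(branch = character(0), type = character(0),
           position = integer(0), ref_allele = character(0),
           alt_allele = character(0), length = integer(0),
           in_ir = logical(0), mirror_position = integer(0),
           region = character(0))
  list(leaves = leaves, features = feats, quads = quads, truth = truth,
       tree = phy, ancestor = ancestor)
}

#' Replay truth events onto a parent sequence
#'
#' Applies one branch's ground-truth events (expanding IR mirrors) to the
#' parent sequence; by construction this reproduces the child sequence
#' exactly.
#'
#' @param parent_seq parent nucleotide string.
#' @param branch_truth rows of the truth tibble for one branch.
#' @return the child sequence.
#' @export
replay_truth <- function(parent_seq, branch_truth) {
  events <- lapply(seq_len(nrow(branch_truth)), function(r) {
    as.list(branch_truth[r, c("type", "position", "ref_allele",
                              "alt_allele", "length", "in_ir",
                              "mirror_position")]) |>
      setNames(c("type", "position", "ref", "alt", "length", "in_ir",
                 "mirror_position"))
  })
  apply_edits(parent_seq, expand_edits(events))
}

#' Convenience: generate an ancestor and evolve the default tree
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed (ancestor uses `seed`, evolution `seed + 1`).
#' @return the [evolve()] result.
#' @export
simulate_plastomes <- function(params = sim_params(), seed = 1L) {
  anc <- generate_ancestor(params, seed = seed)
  evolve(anc, seed = seed + 1L)
}

#' Estimate simulation parameters back from variant calls
#'
#' Transition:transversion ratio (the simulator's kappa), event-type
#' fractions, and — when an annotation is supplied — per-region variant
#' enrichment relative to region length share.
#'
#' @param variants tibble from [call_variants()].
#' @param features optional feature tibble for the reference genome.
#' @param genome_length reference genome length (required with
#'   `features`).
#' @return a one-row tibble: `n_events`, `n_snp`, `n_mnv`,
#'   `n_insertion`, `n_deletion`, `snp_fraction`, `indel_fraction`,
#'   `n_transitions`, `n_transversions`, `kappa_hat` and (with
#'   annotation) `enrichment_coding`, `enrichment_intron`,
#'   `enrichment_intergenic`.
#' @export
recover_parameters <- function(variants, features = NULL,
                               genome_length = NULL) {
  snps <- variants[variants$type == "SNP", , drop = FALSE]
  n_snp <- nrow(snps)
  if (n_snp == 0L) {
    warn("no SNPs: kappa is undefined")
    ts <- tv <- 0L
    kappa_hat <- NA_real_
  } else {
    cls <- classify_ts_tv(snps$ref_allele, snps$alt_allele)
    ts <- sum(cls == "transition"); tv <- sum(cls == "transversion")
    kappa_hat <- if (tv == 0L) Inf else ts / tv
  }
  out <- tibble(
    n_events = nrow(variants),
    n_snp = n_snp,
    n_mnv = sum(variants$type == "MNV"),
    n_insertion = sum(variants$type == "insertion"),
    n_deletion = sum(variants$type == "deletion"),
    snp_fraction = n_snp / max(1L, nrow(variants)),
    indel_fraction = sum(variants$type %in% c("insertion", "deletion")) /
      max(1L, nrow(variants)),
    n_transitions = ts, n_transversions = tv,
    kappa_hat = kappa_hat)
  if (!is.null(features)) {
    if (is.null(genome_length)) abort("genome_length required with features")
    rd <- region_distribution(variants, features, genome_length)
    lab <- coarse_labels(features, genome_length)
    share <- table(factor(lab, levels = c("coding", "intron",
                                          "intergenic"))) / genome_length
    enr <- setNames(rd$proportion / as.numeric(share[rd$region]),
                    rd$region)
    out$enrichment_coding <- unname(enr["coding"])
    out$enrichment_intron <- unname(enr["intron"])
    out$enrichment_intergenic <- unname(enr["intergenic"])
  }
  out
}

#' Construct a synthetic frameshift test gene
#'
#' Deterministically (given `seed`) builds a single-exon protein-coding
#' gene whose intact protein has `intact_aa` residues and for which a
#' single-base insertion at the returned position truncates the shifted
#' protein to exactly `truncated_aa` residues — a synthetic
#' reconstruction of the ycf68-style frameshift geometry.
#'
#' @param intact_aa intact protein length (amino acids).
#' @param truncated_aa truncated protein length after the frameshift.
#' @param insert_codon codon index near which the base is inserted.
#' @param seed integer seed for the bounded search.
#' @return a list: `genome` (one-row plastome tibble), `features`,
#'   `variant` (one-row insertion tibble), `intact_aa`, `truncated_aa`.
#' @export
synthesize_frameshift_gene <- function(intact_aa = 133L,
                                       truncated_aa = 101L,
                                       insert_codon = 95L, seed = 101L) {
  set.seed(seed)
  flank <- 50L
  gc <- genetic_code_table("11")
  ins_at <- 3L * (insert_codon - 1L) + 2L   # inside insert_codon
  for (try in seq_len(50000L)) {
    cds <- random_orf(intact_aa, at = 0.61)
    mutated <- paste0(substr(cds, 1L, ins_at - 1L), "A",
                      substr(cds, ins_at, nchar(cds)))
    prot <- translate_cds(mutated, gc)
    stop_at <- regexpr("*", prot, fixed = TRUE)
    if (stop_at > 0L && stop_at - 1L == truncated_aa) {
      genome_seq <- paste0(random_dna(flank, 0.61), cds,
                           random_dna(flank, 0.61))
      features <- tibble(gene_id = "fsgene", gene = "fsgene",
                         category = "protein_coding", strand = "+",
                         start = flank + 1L,
                         end = flank + nchar(cds), exon = 1L,
                         copy = "single")
      variant <- tibble(ref_id = "synthetic_ref", qry_id = "synthetic_alt",
                        type = "insertion",
                        ref_position = flank + ins_at,
                        ref_allele = "", alt_allele = "A", length = 1L)
      return(list(genome = tibble(id = "synthetic_ref",
                                  sequence = genome_seq,
                                  length = nchar(genome_seq),
                                  circular = FALSE),
                  features = features, variant = variant,
                  intact_aa = intact_aa, truncated_aa = truncated_aa))
    }
  }
  abort("no suitable frameshift gene found; adjust parameters")
}
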