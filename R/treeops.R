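## Internal unrooted-binary-tree machinery used by the parsimony searches.
## A tree is a list(edge = integer matrix of undirected edges, n_tip);
## tips are 1..n_tip, internal nodes have larger ids. All surgery
## (stepwise insertion, TBR bisection/reconnection) happens here; scoring
## is delegated to the compiled Fitch kernel.

utree_cherry <- function(i, j, k, n_tip) {
  w <- n_tip + 1L
  list(edge = rbind(c(w, i), c(w, j), c(w, k)), n_tip = n_tip)
}

utree_max_node <- function(tr) max(tr$edge)

utree_insert_tip <- function(tr, tip, edge_row) {
  u <- tr$edge[edge_row, 1]; v <- tr$edge[edge_row, 2]
  w <- utree_max_node(tr) + 1L
  edge <- rbind(tr$edge[-edge_row, , drop = FALSE],
                c(u, w), c(w, v), c(w, tip))
  list(edge = edge, n_tip = tr$n_tip)
}

utree_score <- function(tr, states, weights) {
  .fitch_score_cpp(tr$edge, tr$n_tip, states, weights, FALSE)$steps
}

## connected component containing `node` after removing edge row `drop`
utree_component <- function(edge, node) {
  seen <- node
  frontier <- node
  while (length(frontier)) {
    hit <- edge[, 1] %in% frontier | edge[, 2] %in% frontier
    nxt <- setdiff(unique(as.vector(edge[hit, , drop = FALSE])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

## suppress a degree-2 internal node left behind by edge removal
suppress_node <- function(edge, node, n_tip) {
  if (node <= n_tip) return(list(edge = edge, freed = integer(0)))
  touching <- which(edge[, 1] == node | edge[, 2] == node)
  nb <- setdiff(as.vector(edge[touching, , drop = FALSE]), node)
  edge <- edge[-touching, , drop = FALSE]
  edge <- rbind(edge, nb)
  list(edge = edge, freed = node)
}

## all TBR neighbours of an unrooted binary tree
utree_tbr_neighbors <- function(tr) {
  E <- nrow(tr$edge)
  n_tip <- tr$n_tip
  out <- list()
  for (e in seq_len(E)) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    rest <- tr$edge[-e, , drop = FALSE]
    comp_u <- utree_component(rest, u)
    in_u <- rest[, 1] %in% comp_u          # edges of u's component
    eu <- rest[in_u, , drop = FALSE]
    ev <- rest[!in_u, , drop = FALSE]
    su <- suppress_node(eu, u, n_tip)
    sv <- suppress_node(ev, v, n_tip)
    freed <- c(su$freed, sv$freed)
    attach_points <- function(side_edges, lone) {
      if (nrow(side_edges) == 0L) return(list(list(tip = lone)))
      lapply(seq_len(nrow(side_edges)), function(i) {
        list(row = i)
      })
    }
    ap_u <- attach_points(su$edge, u)
    ap_v <- attach_points(sv$edge, v)
    next_ids <- c(freed, utree_max_node(tr) + seq_len(2L))
    for (au in ap_u) {
      for (av in ap_v) {
        e1 <- su$edge; e2 <- sv$edge
        ids <- next_ids
        if (!is.null(au$tip)) {
          p1 <- au$tip
        } else {
          p1 <- ids[1]; ids <- ids[-1]
          r <- e1[au$row, ]
          e1 <- rbind(e1[-au$row, , drop = FALSE],
                      c(r[1], p1), c(p1, r[2]))
        }
        if (!is.null(av$tip)) {
          p2 <- av$tip
        } else {
          p2 <- ids[1]
          r <- e2[av$row, ]
          e2 <- rbind(e2[-av$row, , drop = FALSE],
                      c(r[1], p2), c(p2, r[2]))
        }
        out[[length(out) + 1L]] <- list(
          edge = rbind(e1, e2, c(p1, p2)), n_tip = n_tip)
      }
    }
  }
  out
}

## canonical string for topology deduplication (labels = tip ids)
utree_canonical <- function(tr) {
  adj <- vector("list", utree_max_node(tr))
  for (r in seq_len(nrow(tr$edge))) {
    a <- tr$edge[r, 1]; b <- tr$edge[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  canon <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0L) return(as.character(node))
    sub <- sort(vapply(kids, canon, character(1), parent = node))
    paste0("(", paste(sub, collapse = ","), ")")
  }
  r <- adj[[1L]][1L]
  paste0("(1,", canon(r, 1L), ");")
}

## newick text rooted at tip 1's internal neighbour (basal trichotomy),
## with real taxon labels; parsed by ape into a standard phylo object
utree_to_phylo <- function(tr, labels) {
  adj <- vector("list", utree_max_node(tr))
  for (r in seq_len(nrow(tr$edge))) {
    a <- tr$edge[r, 1]; b <- tr$edge[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  nwk <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0L) return(labels[node])
    paste0("(", paste(vapply(kids, nwk, character(1), parent = node),
                      collapse = ","), ")")
  }
  if (tr$n_tip == 2L) {
    return(ape::read.tree(text = paste0("(", labels[1], ",", labels[2],
                                        ");")))
  }
  r <- adj[[1L]][1L]
  kids <- setdiff(adj[[r]], 1L)
  txt <- paste0("(", labels[1], ",",
                paste(vapply(kids, nwk, character(1), parent = r),
                      collapse = ","), ");")
  ape::read.tree(text = txt)
}

## ape phylo -> internal representation, tips renumbered to match `taxa`
phylo_to_utree <- function(phy, taxa) {
  phy <- ape::unroot(phy)
  m <- match(phy$tip.label, taxa)
  if (anyNA(m)) {
    abort("tree leaves do not match the matrix taxa",
          class = "plastocmp_label_mismatch")
  }
  n <- length(taxa)
  if (length(m) != n) {
    abort("tree leaves do not match the matrix taxa",
          class = "plastocmp_label_mismatch")
  }
  edge <- phy$edge
  # ape ids: tips 1..n in tip.label order, internals n+1..; remap tips
  remap <- c(m, seq.int(n + 1L, n + phy$Nnode))
  edge[] <- remap[edge]
  list(edge = edge, n_tip = n)
}

## tip set of the smaller side of every internal edge, as canonical keys
## (side not containing tip 1)
utree_bipartitions <- function(tr) {
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    if (u <= tr$n_tip || v <= tr$n_tip) next   # pendant edge: trivial
    rest <- tr$edge[-e, , drop = FALSE]
    comp <- utree_component(rest, u)
    tips <- sort(comp[comp <= tr$n_tip])
    if (1L %in% tips) {
      tips <- sort(setdiff(seq_len(tr$n_tip), tips))
    }
    keys <- c(keys, paste(tips, collapse = "|"))
  }
  keys
}

## enumerate every unrooted binary topology on n tips (recursive stepwise
## insertion); n is capped by the caller
utree_enumerate <- function(n_tip) {
  trees <- list(utree_cherry(1L, 2L, 3L, n_tip))
  if (n_tip < 4L) return(trees)
  for (tip in seq.int(4L, n_tip)) {
    nxt <- vector("list", length(trees) * (2L * tip - 5L))
    pos <- 0L
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        pos <- pos + 1L
        nxt[[pos]] <- utree_insert_tip(tr, tip, e)
      }
    }
    trees <- nxt
  }
  trees
}
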