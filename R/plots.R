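## ggplot2 helpers for the main result types.

#' Heatmap of pairwise plastome distances
#'
#' @param distances tibble from [distance_matrices()].
#' @param metric `"variants"` or `"nucleotide_differences"`.
#' @return a ggplot object.
#' @export
plot_distance_heatmap <- function(distances,
                                  metric = c("variants",
                                             "nucleotide_differences")) {
  metric <- match.arg(metric)
  m <- as_dist_matrix(distances, metric)
  df <- as.data.frame(as.table(m))
  names(df) <- c("taxon_a", "taxon_b", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon_a, y = .data$taxon_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$value), size = 3) +
    ggplot2::scale_fill_gradientn(colours = c("#d73027", "#fdae61",
                                              "#ffffbf", "#1a9850")) +
    ggplot2::labs(x = NULL, y = NULL, fill = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Genome share versus variant share per region
#'
#' Side-by-side bars of how much of the genome each region occupies and
#' what fraction of the variants falls there.
#'
#' @param composition one-row tibble from [composition_summary()].
#' @param region_dist tibble from [region_distribution()].
#' @return a ggplot object.
#' @export
plot_region_distribution <- function(composition, region_dist) {
  genome <- tibble(
    region = c("coding", "intron", "intergenic"),
    share = c(composition$coding_percent, composition$intron_percent,
              composition$intergenic_percent) / 100,
    what = "genome")
  vars <- tibble(region = region_dist$region,
                 share = region_dist$proportion, what = "variants")
  df <- dplyr::bind_rows(genome, vars)
  df$region <- factor(df$region, levels = c("coding", "intron",
                                            "intergenic"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$share,
                                   fill = .data$region)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share", fill = "region") +
    ggplot2::theme_minimal()
}

## simple rectangular layout for a rooted tree
tree_layout <- function(phy) {
  n <- length(phy$tip.label)
  root <- n + 1L
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  depth <- numeric(max(phy$edge))
  ys <- numeric(max(phy$edge))
  tip_counter <- 0
  assign_y <- function(v) {
    ks <- kids[[as.character(v)]]
    if (is.null(ks)) {
      tip_counter <<- tip_counter + 1
      ys[v] <<- tip_counter
    } else {
      for (k in ks) assign_y(k)
      ys[v] <<- mean(ys[ks])
    }
  }
  assign_depth <- function(v, d) {
    depth[v] <<- d
    ks <- kids[[as.character(v)]]
    for (k in ks) assign_depth(k, d + 1)
  }
  assign_y(root)
  assign_depth(root, 0)
  maxd <- max(depth)
  # tips flush right
  for (v in seq_len(n)) depth[v] <- maxd
  list(x = depth, y = ys, kids = kids, root = root, n = n)
}

#' Plot a parsimony fit as a rooted cladogram
#'
#' Draws the first optimal tree (rooted on `outgroup` when given) with
#' bootstrap-style node labels if present.
#'
#' @param object a `parsimony_fit` object.
#' @param outgroup optional tip label to root on.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.parsimony_fit <- function(object, outgroup = NULL, ...) {
  phy <- object$trees[[1]]
  if (!is.null(outgroup)) phy <- root_with_outgroup(phy, outgroup)
  plot_cladogram(phy)
}

#' @rdname autoplot.parsimony_fit
#' @param phy a rooted `phylo` object.
#' @export
plot_cladogram <- function(phy) {
  lay <- tree_layout(phy)
  seg_h <- data.frame(x = lay$x[phy$edge[, 1]],
                      xend = lay$x[phy$edge[, 2]],
                      y = lay$y[phy$edge[, 2]],
                      yend = lay$y[phy$edge[, 2]])
  seg_v <- data.frame(x = lay$x[phy$edge[, 1]],
                      xend = lay$x[phy$edge[, 1]],
                      y = lay$y[phy$edge[, 1]],
                      yend = lay$y[phy$edge[, 2]])
  tips <- data.frame(x = lay$x[seq_len(lay$n)],
                     y = lay$y[seq_len(lay$n)],
                     label = phy$tip.label)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = rbind(seg_h, seg_v),
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.05, size = 3) +
    ggplot2::expand_limits(x = max(lay$x) * 1.4) +
    ggplot2::theme_void()
  if (!is.null(phy$node.label)) {
    nodes <- data.frame(
      x = lay$x[lay$n + seq_along(phy$node.label)],
      y = lay$y[lay$n + seq_along(phy$node.label)],
      label = phy$node.label)
    nodes <- nodes[nzchar(nodes$label), , drop = FALSE]
    if (nrow(nodes)) {
      p <- p + ggplot2::geom_text(
        data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                   label = .data$label),
        hjust = 1.1, vjust = -0.5, size = 2.7, colour = "grey30")
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
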