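# tidy()/glance() methods, autoplot()/plot_* figures, and Newick export.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.chic_hclust <- function(x, ...) {
  cat("Cell-line clustering (average linkage, Euclidean) on",
      x$n_interactions, "interactions\n")
  cat("Cell lines:", paste(x$cell_lines, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a cell-line clustering
#'
#' One row per agglomeration step with its merge height.
#'
#' @param x A `chic_hclust` object.
#' @param ... Unused.
#' @return Tibble: `step`, `height`, `members` (labels merged at the step).
#' @export
tidy.chic_hclust <- function(x, ...) {
  hc <- x$hclust
  members <- lapply(seq_len(nrow(hc$merge)), function(i) {
    leaves <- function(node) {
      if (node < 0) return(hc$labels[-node])
      unlist(lapply(hc$merge[node, ], leaves))
    }
    paste(sort(leaves(i)), collapse = ",")
  })
  tibble::tibble(step = seq_len(nrow(hc$merge)), height = hc$height,
                 members = unlist(members))
}

#' @rdname tidy.chic_hclust
#' @export
glance.chic_hclust <- function(x, ...) {
  tibble::tibble(n_cell_lines = length(x$cell_lines),
                 n_interactions = x$n_interactions,
                 max_height = max(x$hclust$height))
}

#' Cut a cell-line clustering into k groups
#'
#' @param x A `chic_hclust` object.
#' @param k Number of groups.
#' @return Tibble: `cell_line`, `cluster`.
#' @export
cut_cell_lines <- function(x, k = 2) {
  cl <- stats::cutree(x$hclust, k = k)
  tibble::tibble(cell_line = names(cl), cluster = unname(cl))
}

#' Export a cell-line merge tree in Newick format
#'
#' @param x A `chic_hclust` object.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "chic_hclust"))
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

# Dendrogram segment coordinates from an hclust object.
dendro_segments <- function(hc) {
  n <- length(hc$labels)
  xleaf <- numeric(n)
  xleaf[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  segs <- list()
  child_xy <- function(v) {
    if (v < 0) c(xleaf[-v], 0) else c(node_x[v], node_h[v])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- child_xy(hc$merge[i, 1])
    b <- child_xy(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[i]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], node_h[i]), yend = c(node_h[i], node_h[i], node_h[i])
    )
  }
  list(segments = dplyr::bind_rows(segs),
       leaves = tibble::tibble(x = xleaf, label = hc$labels))
}

#' @rdname tidy.chic_hclust
#' @param object A `chic_hclust` object.
#' @export
autoplot.chic_hclust <- function(object, ...) {
  d <- dendro_segments(object$hclust)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = d$segments,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend)
    ) +
    ggplot2::scale_x_continuous(breaks = d$leaves$x,
                                labels = d$leaves$label) +
    ggplot2::labs(x = NULL, y = "Merge height (Euclidean, average linkage)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
}

#' @export
print.chic_pca <- function(x, ...) {
  cat("Cell-line PCA on", x$n_interactions,
      "unit-variance-scaled interactions\n")
  cat("PC1/PC2 variance explained:",
      sprintf("%.1f%% / %.1f%%", 100 * x$var_explained[1],
              100 * x$var_explained[2]), "\n")
  invisible(x)
}

#' Tidy a cell-line PCA
#'
#' @param x A `chic_pca` object.
#' @param ... Unused.
#' @return Component scores, one row per cell line.
#' @export
tidy.chic_pca <- function(x, ...) {
  x$scores
}

#' @rdname tidy.chic_pca
#' @export
glance.chic_pca <- function(x, ...) {
  tibble::tibble(
    n_interactions = x$n_interactions,
    n_components = length(x$var_explained),
    pc1_var_explained = x$var_explained[1],
    pc2_var_explained = if (length(x$var_explained) > 1) {
      x$var_explained[2]
    } else NA_real_
  )
}

#' @rdname tidy.chic_pca
#' @param object A `chic_pca` object.
#' @export
autoplot.chic_pca <- function(object, ...) {
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(x = .data$PC1, y = .data$PC2, label = .data$cell_line)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of feature enrichment z-scores
#'
#' @param enrichment Output of [enrich_features()].
#' @return A ggplot object (features x cell lines, fill = z).
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(
    enrichment,
    ggplot2::aes(x = .data$cell_line, y = .data$feature_name, fill = .data$z)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal()
}

#' Observed vs permutation-null eQTL-loop counts per distance bin
#'
#' @param test Output of [eqtl_enrichment_test()].
#' @return A ggplot object with significance stars above observed bars.
#' @export
plot_eqtl_bins <- function(test) {
  long <- tidyr::pivot_longer(
    dplyr::select(test, "bin_label", "observed", "null_mean"),
    c("observed", "null_mean"),
    names_to = "set", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_label, y = .data$count,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = test,
      ggplot2::aes(x = .data$bin_label, y = .data$observed,
                   label = .data$stars),
      inherit.aes = FALSE, vjust = -0.3
    ) +
    ggplot2::labs(x = "Interaction distance bin",
                  y = "eQTL-supported interactions", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL
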