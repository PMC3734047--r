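#' Hierarchical clustering of samples on log2 expression
#'
#' Agglomerative clustering of the sample columns with average linkage
#' on correlation distance (1 - Pearson r over genes), the metric
#' conventional for expression heatmap dendrograms. A constant input
#' matrix has no correlation structure: all distances are set to zero
#' with a warning and the resulting order is arbitrary but stable.
#'
#' @param log2_mat A [log2_matrix()] tibble (gene_id + >= 3 sample
#'   columns), or a plain numeric matrix with sample columns.
#' @return A `sample_clustering` object: `hclust` (the tree),
#'   `newick` (the same tree as a newick string), `nearest_pair`
#'   (labels of the first two samples to merge, with the merge height),
#'   and `dist` (the distance object).
#' @export
cluster_samples <- function(log2_mat) {
  m <- if (is.data.frame(log2_mat)) {
    as.matrix(log2_mat[setdiff(names(log2_mat), "gene_id")])
  } else as.matrix(log2_mat)
  if (ncol(m) < 3) stop("need >= 3 samples to cluster", call. = FALSE)
  cc <- suppressWarnings(cor(m))
  if (anyNA(cc)) {
    warning("constant expression matrix: all distances zero, ",
            "sample order arbitrary", call. = FALSE)
    cc[is.na(cc)] <- 1
  }
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  first <- hc$merge[1, ]
  pair <- hc$labels[-first]  # first merge always joins two singletons
  phy <- ape::as.phylo(hc)
  structure(
    list(
      hclust = hc,
      newick = ape::write.tree(phy),
      nearest_pair = list(samples = pair, height = hc$height[1]),
      dist = d
    ),
    class = "sample_clustering"
  )
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering>", x$newick, "\n")
  cat(sprintf("  nearest pair: %s (height %.4g)\n",
              paste(x$nearest_pair$samples, collapse = " + "),
              x$nearest_pair$height))
  invisible(x)
}

#' @export
tidy.sample_clustering <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    item1 = ifelse(hc$merge[, 1] < 0, hc$labels[-hc$merge[, 1]],
                   paste0("cluster", hc$merge[, 1])),
    item2 = ifelse(hc$merge[, 2] < 0, hc$labels[-hc$merge[, 2]],
                   paste0("cluster", hc$merge[, 2])),
    height = hc$height
  )
}

#' @export
glance.sample_clustering <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$hclust$labels),
    nearest_pair = paste(x$nearest_pair$samples, collapse = "+"),
    nearest_height = x$nearest_pair$height,
    max_height = max(x$hclust$height)
  )
}

# hclust -> segment table for a ggplot dendrogram
dendrogram_segments <- function(hc) {
  n <- length(hc$labels)
  xpos <- numeric(2 * n - 1)  # leaves negative index, merges positive
  leaf_x <- stats::setNames(seq_len(n), hc$order)
  node_x <- function(i) if (i < 0) leaf_x[[as.character(-i)]] else xpos[i]
  node_h <- function(i) if (i < 0) 0 else hc$height[i]
  segs <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    a <- hc$merge[s, 1]; b <- hc$merge[s, 2]
    xa <- node_x(a); xb <- node_x(b)
    xpos[s] <- (xa + xb) / 2
    segs[[s]] <- tibble::tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(node_h(a), node_h(b), hc$height[s]),
      yend = c(hc$height[s], hc$height[s], hc$height[s])
    )
  }
  list(segments = dplyr::bind_rows(segs),
       labels = tibble::tibble(x = seq_len(n),
                               label = hc$labels[hc$order]))
}

#' Dendrogram plot of a sample clustering
#'
#' @param object A `sample_clustering`.
#' @param ... Unused.
#' @return A ggplot dendrogram.
#' @export
autoplot.sample_clustering <- function(object, ...) {
  dd <- dendrogram_segments(object$hclust)
  ggplot2::ggplot(dd$segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = dd$labels,
                       ggplot2::aes(x = .data$x, y = -0.02 *
                                      max(object$hclust$height),
                                    label = .data$label),
                       vjust = 1) +
    ggplot2::labs(y = "1 - Pearson r (average linkage)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
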