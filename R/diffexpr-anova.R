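#' Per-gene one-way ANOVA across conditions
#'
#' For every gene, tests whether mean RPKM differs between conditions
#' with a fixed-effects one-way ANOVA over the replicate RPKM values:
#' F = (SSB/(k-1)) / (SSW/(N-k)) with k conditions and N samples, and
#' the p value from the F distribution. Genes are gated at raw
#' p < alpha — no multiple-testing correction by default, matching
#' protocols that display all nominally significant genes; set
#' `p_adjust = "BH"` for an FDR-adjusted gate instead.
#'
#' Degenerate genes with zero variance everywhere (all observations
#' equal) get p = 1 — constitutively flat genes are never significant.
#' Zero within-group variance with distinct group means gives F = Inf,
#' p = 0.
#'
#' The sums of squares are computed by vectorized row-wise arithmetic
#' (identical to `stats::aov` gene by gene, which the test suite uses
#' as the cross-check).
#'
#' @param x An `rpkm_set`, or a tibble with `gene_id` + sample columns
#'   (then `design` is required).
#' @param design Tibble `sample_id`, `condition`, `replicate`; taken
#'   from `x` when `x` is an `rpkm_set`.
#' @param alpha Significance level for the gate (default 0.05).
#' @param p_adjust `"none"` (default) or a method name accepted by
#'   [stats::p.adjust()]; when not `"none"`, the `significant` flag is
#'   based on the adjusted p.
#' @return A `gene_anova` tibble: `gene_id`, `F_statistic`, `p_value`,
#'   `significant`, and one `mean_<condition>` column per condition,
#'   with the alpha and degrees of freedom as attributes.
#' @export
anova_per_gene <- function(x, design = NULL, alpha = 0.05,
                           p_adjust = "none") {
  if (inherits(x, "rpkm_set")) {
    design <- x$design
    m <- rpkm_matrix_of(x)
  } else {
    stopifnot(!is.null(design), "gene_id" %in% names(x))
    m <- as.matrix(x[design$sample_id])
    rownames(m) <- x$gene_id
  }
  cond <- factor(condition_of(list(design = design), colnames(m)),
                 levels = unique(design$condition))
  k <- nlevels(cond)
  if (k < 2) stop("need >= 2 conditions", call. = FALSE)
  n_i <- table(cond)
  if (any(n_i < 2)) {
    stop("every condition needs >= 2 replicates; short: ",
         paste(names(n_i)[n_i < 2], collapse = ", "), call. = FALSE)
  }
  N <- ncol(m)

  group_means <- vapply(levels(cond), function(cl) {
    rowMeans(m[, cond == cl, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(group_means))) {
    group_means <- matrix(group_means, nrow = nrow(m),
                          dimnames = list(rownames(m), levels(cond)))
  }
  grand <- rowMeans(m)
  ssb <- as.numeric(group_means^2 %*% as.numeric(n_i)) -
    N * grand^2
  sst <- rowSums(m^2) - N * grand^2
  ssw <- sst - ssb
  # guard tiny negatives from cancellation
  ssb <- pmax(ssb, 0); ssw <- pmax(ssw, 0)

  tol <- 1e-10 * pmax(sst, 1e-300)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(f, k - 1, N - k, lower.tail = FALSE)
  flat <- sst <= 1e-12 * pmax(N * grand^2, 1)
  p[flat] <- 1; f[flat] <- NA_real_
  exact <- !flat & ssw <= tol        # distinct means, no within noise
  p[exact] <- 0; f[exact] <- Inf

  p_used <- if (identical(p_adjust, "none")) p else stats::p.adjust(p, p_adjust)
  out <- tibble::tibble(
    gene_id = rownames(m),
    F_statistic = unname(f),
    p_value = unname(p),
    significant = unname(p_used < alpha)
  )
  if (!identical(p_adjust, "none")) out$p_adjusted <- p_used
  gm <- tibble::as_tibble(group_means)
  names(gm) <- paste0("mean_", levels(cond))
  out <- dplyr::bind_cols(out, gm)
  structure(out, class = c("gene_anova", class(out)),
            alpha = alpha, df = c(k - 1, N - k), p_adjust = p_adjust)
}

#' @export
tidy.gene_anova <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id,
    statistic = x$F_statistic,
    p.value = x$p_value,
    significant = x$significant
  )
}

#' @export
glance.gene_anova <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    df_between = attr(x, "df")[1],
    df_within = attr(x, "df")[2]
  )
}

#' p-value histogram for a per-gene ANOVA
#'
#' A flat histogram with a spike near 0 is the expected shape for a
#' well-calibrated test with true effects; systematic slopes indicate
#' miscalibration.
#'
#' @param object A `gene_anova`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_anova <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey35") +
    ggplot2::geom_vline(xintercept = attr(object, "alpha"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "ANOVA p value", y = "genes") +
    ggplot2::theme_minimal()
}
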