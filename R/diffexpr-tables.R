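#' Classify genes by expression level per condition
#'
#' Labels every gene in every condition from the mean RPKM of its
#' replicates: below `weak_max` (strictly) the gene is silent or weakly
#' expressed; above `high_min` (strictly) it is highly expressed;
#' otherwise moderate. The defaults (250 and 20,000 RPKM) are the
#' conventional cutoffs for bacterial transcriptomes quantified this
#' way; a value exactly at a threshold is moderate.
#'
#' @param x An `rpkm_set` (or tibble + `design`).
#' @param design Design tibble when `x` is a plain table.
#' @param weak_max Upper RPKM bound (exclusive) of the silent/weak
#'   class.
#' @param high_min Lower RPKM bound (exclusive) of the high class.
#' @return An `expression_category` tibble, long over gene x condition:
#'   `gene_id`, `condition`, `mean_rpkm`, `category`, plus a
#'   `high_in_any` logical attribute-free column marking genes high in
#'   at least one condition.
#' @export
classify_expression <- function(x, design = NULL, weak_max = 250,
                                high_min = 20000) {
  stopifnot(weak_max < high_min)
  if (inherits(x, "rpkm_set")) {
    design <- x$design
    m <- rpkm_matrix_of(x)
  } else {
    m <- as.matrix(x[design$sample_id]); rownames(m) <- x$gene_id
  }
  cond <- condition_of(list(design = design), colnames(m))
  out <- purrr::map_dfr(unique(cond), function(cl) {
    tibble::tibble(
      gene_id = rownames(m),
      condition = cl,
      mean_rpkm = unname(rowMeans(m[, cond == cl, drop = FALSE]))
    )
  })
  out$category <- dplyr::case_when(
    out$mean_rpkm < weak_max ~ "silent_or_weak",
    out$mean_rpkm > high_min ~ "high",
    TRUE ~ "moderate"
  )
  high_genes <- unique(out$gene_id[out$category == "high"])
  out <- dplyr::mutate(out, high_in_any = .data$gene_id %in% high_genes)
  structure(out, class = c("expression_category", class(out)),
            thresholds = c(weak_max = weak_max, high_min = high_min))
}

#' Between-condition expression ratio table
#'
#' Ratio of replicate-mean RPKM between two conditions per gene, the
#' statistic behind fold-change statements and up/down-regulation
#' tables. A pseudocount can be added to both means to guard zero
#' denominators; with `pseudo = 0` (default) genes whose denominator
#' mean is zero are skipped rather than reported as infinite.
#'
#' @param x An `rpkm_set` (or tibble + `design`).
#' @param numerator,denominator Condition labels.
#' @param design Design tibble when `x` is a plain table.
#' @param pseudo Nonnegative RPKM offset added to both means.
#' @return Tibble sorted by descending ratio: `gene_id`, `mean_num`,
#'   `mean_den`, `ratio`, `log2_ratio`, `direction` (up/down/flat).
#' @export
expression_ratios <- function(x, numerator, denominator, design = NULL,
                              pseudo = 0) {
  stopifnot(pseudo >= 0)
  if (inherits(x, "rpkm_set")) {
    design <- x$design
    m <- rpkm_matrix_of(x)
  } else {
    m <- as.matrix(x[design$sample_id]); rownames(m) <- x$gene_id
  }
  cond <- condition_of(list(design = design), colnames(m))
  for (cl in c(numerator, denominator)) {
    if (!cl %in% cond) stop("unknown condition: ", cl, call. = FALSE)
  }
  num <- rowMeans(m[, cond == numerator, drop = FALSE]) + pseudo
  den <- rowMeans(m[, cond == denominator, drop = FALSE]) + pseudo
  out <- tibble::tibble(gene_id = rownames(m), mean_num = unname(num),
                        mean_den = unname(den))
  if (pseudo == 0) out <- dplyr::filter(out, .data$mean_den > 0)
  out <- out |>
    dplyr::mutate(
      ratio = .data$mean_num / .data$mean_den,
      log2_ratio = log2(.data$ratio),
      direction = dplyr::case_when(
        .data$log2_ratio > 0 ~ "up",
        .data$log2_ratio < 0 ~ "down",
        TRUE ~ "flat"
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$ratio))
  out
}

#' log2-transformed RPKM matrix
#'
#' `log2(RPKM + pseudo)`, finite everywhere for `pseudo > 0`; the
#' standard input for expression heatmaps and sample clustering.
#' Optionally restricted to genes flagged significant by a
#' [anova_per_gene()] result, mirroring heatmaps that hide
#' non-significant genes.
#'
#' @param x An `rpkm_set` (or tibble of gene_id + sample columns).
#' @param pseudo Positive pseudocount (default 1 RPKM).
#' @param significant Optional `gene_anova`; keeps only its significant
#'   genes.
#' @return Tibble: `gene_id` + one log2 column per sample.
#' @export
log2_matrix <- function(x, pseudo = 1, significant = NULL) {
  stopifnot(pseudo > 0)
  rpkm <- if (inherits(x, "rpkm_set")) x$rpkm else tibble::as_tibble(x)
  out <- dplyr::mutate(rpkm, dplyr::across(-"gene_id", ~ log2(.x + pseudo)))
  if (!is.null(significant)) {
    keep <- significant$gene_id[significant$significant]
    out <- dplyr::filter(out, .data$gene_id %in% keep)
  }
  out
}

#' Expression heatmap of a log2 matrix
#'
#' @param log2_mat Output of [log2_matrix()].
#' @param order_genes Order rows by decreasing row mean.
#' @return A ggplot tile heatmap (samples x genes, rainbow fill as is
#'   conventional for these displays).
#' @export
plot_expression_heatmap <- function(log2_mat, order_genes = TRUE) {
  long <- tidyr::pivot_longer(log2_mat, -"gene_id",
                              names_to = "sample", values_to = "log2_rpkm")
  if (order_genes) {
    ord <- long |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(m = mean(.data$log2_rpkm), .groups = "drop") |>
      dplyr::arrange(.data$m)
    long$gene_id <- factor(long$gene_id, levels = ord$gene_id)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                     fill = .data$log2_rpkm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = rev(grDevices::rainbow(7))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 RPKM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
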