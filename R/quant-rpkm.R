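#' Quantify a set of SAM files into count and RPKM matrices
#'
#' Runs the full per-sample pipeline — group alignments by read, drop
#' mismatched and rRNA-overlapping loci, fractionally count over CDS
#' features, normalize to RPKM — and assembles gene x sample matrices
#' together with the replicate/condition design.
#'
#' @param sam_files Named character vector, `sample_id -> SAM path`.
#'   Names must match `design$sample_id`.
#' @param annotation A `genome_annotation`.
#' @param design Tibble with columns `sample_id`, `condition`,
#'   `replicate`.
#' @param granularity Filtering granularity, see [filter_alignments()].
#' @return An `rpkm_set`: list with tibbles `counts` and `rpkm`
#'   (gene_id + one column per sample), `gene_length`, named
#'   `library_size`, `design`, and per-sample `filter_stats`.
#' @export
quantify_samples <- function(sam_files, annotation, design,
                             granularity = "locus") {
  stopifnot(!is.null(names(sam_files)),
            all(c("sample_id", "condition", "replicate") %in% names(design)))
  miss <- setdiff(design$sample_id, names(sam_files))
  if (length(miss) > 0) {
    stop("no SAM file for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples <- design$sample_id
  counts <- tibble::tibble(gene_id = annotation$cds$gene_id)
  rpkm <- counts
  lib <- stats::setNames(numeric(length(samples)), samples)
  stats_list <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    loci <- group_alignments(sam_files[[s]])
    flt <- filter_alignments(loci, annotation, granularity = granularity)
    cnt <- count_reads(flt, annotation)
    counts[[s]] <- cnt$counts$count
    lib[s] <- cnt$library_size
    rpkm[[s]] <- compute_rpkm(cnt$counts$count, cnt$counts$length,
                              cnt$library_size)
    stats_list[[i]] <- dplyr::mutate(flt$stats, sample_id = s,
                                     .before = 1)
  }
  structure(
    list(
      counts = counts,
      rpkm = rpkm,
      gene_length = tibble::tibble(gene_id = annotation$cds$gene_id,
                                   length = annotation$cds$length),
      library_size = lib,
      design = tibble::as_tibble(design),
      filter_stats = dplyr::bind_rows(stats_list)
    ),
    class = "rpkm_set"
  )
}

#' Assemble an rpkm_set from an existing RPKM table
#'
#' For workflows that start from a precomputed RPKM TSV rather than SAM
#' files (the downstream statistics only need RPKM + design).
#'
#' @param rpkm Tibble/data frame: `gene_id` plus one numeric column per
#'   sample.
#' @param design Tibble with `sample_id`, `condition`, `replicate`.
#' @param counts,gene_length,library_size Optional companion pieces.
#' @return An `rpkm_set`.
#' @export
rpkm_set <- function(rpkm, design, counts = NULL, gene_length = NULL,
                     library_size = NULL) {
  rpkm <- tibble::as_tibble(rpkm)
  stopifnot("gene_id" %in% names(rpkm),
            all(design$sample_id %in% names(rpkm)))
  structure(
    list(counts = counts, rpkm = rpkm, gene_length = gene_length,
         library_size = library_size, design = tibble::as_tibble(design),
         filter_stats = NULL),
    class = "rpkm_set"
  )
}

#' @export
print.rpkm_set <- function(x, ...) {
  cat(sprintf("<rpkm_set> %d genes x %d samples (%s)\n",
              nrow(x$rpkm), nrow(x$design),
              paste(unique(x$design$condition), collapse = ", ")))
  if (!is.null(x$filter_stats)) {
    print(x$filter_stats)
  }
  invisible(x)
}

#' Per-sample summary of an rpkm_set
#'
#' @param x An `rpkm_set`.
#' @param ... Unused.
#' @return Tibble with one row per sample: condition, replicate,
#'   library size and rRNA fraction (when the set was built from SAM
#'   files).
#' @export
glance.rpkm_set <- function(x, ...) {
  out <- x$design
  if (!is.null(x$library_size)) {
    out$library_size <- unname(x$library_size[out$sample_id])
  }
  if (!is.null(x$filter_stats)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$filter_stats, "sample_id", "n_reads_input",
                    "n_reads_rrna", "frac_rrna"),
      by = "sample_id")
  }
  out
}

rpkm_matrix_of <- function(x) {
  m <- as.matrix(x$rpkm[setdiff(names(x$rpkm), "gene_id")])
  rownames(m) <- x$rpkm$gene_id
  m
}

condition_of <- function(x, samples) {
  x$design$condition[match(samples, x$design$sample_id)]
}
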