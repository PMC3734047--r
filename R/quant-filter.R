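#' Filter alignment groups: mismatches and rRNA regions
#'
#' Applies the two exclusion rules of the quantification protocol:
#' alignments with a mismatch (NM > 0) are discarded, and alignments
#' overlapping any rRNA exclusion interval (>= 1 bp) are discarded.
#' Reads left with no surviving locus are removed entirely; a removed
#' read is tallied as an rRNA read if at least one of its loci
#' overlapped an rRNA interval.
#'
#' `granularity` selects what "alignments ... were discarded" removes
#' when a multimapped read has loci both inside and outside rRNA
#' regions: `"locus"` (default) drops only the offending loci and keeps
#' the read on its clean ones; `"read"` drops the whole read as soon as
#' any locus touches an rRNA interval.
#'
#' @param loci Alignment-locus tibble from [group_alignments()].
#' @param annotation A `genome_annotation` with normalized rRNA
#'   intervals.
#' @param granularity `"locus"` or `"read"` (see above).
#' @return A list: `loci` (surviving rows, plus `n_loci` = surviving
#'   loci per read) and `stats`, a one-row `filter_stats` tibble with
#'   `n_reads_input`, `n_reads_rrna`, `n_loci_dropped_mismatch`,
#'   `n_reads_retained`, `frac_rrna`.
#' @export
filter_alignments <- function(loci, annotation,
                              granularity = c("locus", "read")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(annotation, "genome_annotation"))
  rr <- rrna_granges(annotation)
  in_rrna <- if (length(rr) == 0) {
    rep(FALSE, nrow(loci))
  } else {
    gr <- GenomicRanges::GRanges(loci$replicon,
                                 IRanges::IRanges(loci$start, loci$end))
    IRanges::overlapsAny(gr, rr)
  }
  is_mm <- loci$nm > 0

  flags <- tibble::tibble(read_id = loci$read_id,
                          in_rrna = in_rrna, is_mm = is_mm)
  per_read <- flags |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(any_rrna = any(.data$in_rrna), .groups = "drop")

  survive <- !is_mm & !in_rrna
  if (granularity == "read") {
    rrna_reads <- per_read$read_id[per_read$any_rrna]
    survive <- survive & !(loci$read_id %in% rrna_reads)
  }

  kept <- loci[survive, , drop = FALSE]
  kept <- kept |>
    dplyr::add_count(.data$read_id, name = "n_loci")

  surviving_ids <- unique(kept$read_id)
  dropped <- per_read[!per_read$read_id %in% surviving_ids, , drop = FALSE]
  stats <- tibble::tibble(
    n_reads_input = nrow(per_read),
    n_reads_rrna = sum(dropped$any_rrna),
    n_loci_dropped_mismatch = sum(is_mm),
    n_reads_retained = length(surviving_ids)
  )
  stats$frac_rrna <- if (stats$n_reads_input > 0) {
    stats$n_reads_rrna / stats$n_reads_input
  } else NA_real_
  class(stats) <- c("filter_stats", class(stats))
  list(loci = kept, stats = stats)
}

#' Fractional read counting over CDS features
#'
#' A retained read with k surviving loci contributes weight 1/k at each
#' locus; a locus overlapping m >= 1 CDS features (by >= 1 bp) splits
#' its weight equally among them (1/(k m) per gene); loci overlapping
#' no CDS contribute nothing. The library size is the column sum of the
#' counted weights ("reads on CDSs" convention), so with every locus
#' genic the total counted weight equals the number of retained reads
#' exactly.
#'
#' @param filtered Result of [filter_alignments()] (or its `loci`
#'   tibble including the `n_loci` column).
#' @param annotation A `genome_annotation`.
#' @return A list: `counts` — tibble (gene_id, length, count) covering
#'   every annotated gene — and `library_size` (sum of counts).
#' @export
count_reads <- function(filtered, annotation) {
  loci <- if (is.list(filtered) && !is.data.frame(filtered)) filtered$loci
          else filtered
  stopifnot("n_loci" %in% names(loci))
  counts <- tibble::tibble(gene_id = annotation$cds$gene_id,
                           length = annotation$cds$length,
                           count = 0)
  if (nrow(loci) > 0) {
    gr <- GenomicRanges::GRanges(loci$replicon,
                                 IRanges::IRanges(loci$start, loci$end))
    hits <- GenomicRanges::findOverlaps(gr, cds_granges(annotation))
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      m_per_locus <- tabulate(qh, nbins = nrow(loci))
      w <- 1 / (loci$n_loci[qh] * m_per_locus[qh])
      gene <- annotation$cds$gene_id[S4Vectors::subjectHits(hits)]
      agg <- rowsum(w, gene)
      idx <- match(rownames(agg), counts$gene_id)
      counts$count[idx] <- agg[, 1]
    }
  }
  list(counts = counts, library_size = sum(counts$count))
}

#' RPKM from fractional counts
#'
#' RPKM = count / (gene length in kb) / (library size in millions):
#' reads per kilobase of CDS per million counted reads. Genes with zero
#' counts get RPKM 0.
#'
#' @param counts Numeric vector of (possibly fractional) per-gene
#'   counts.
#' @param gene_length Gene lengths in bp (> 0), same order.
#' @param library_size Total counted reads for the sample (> 0).
#' @return Numeric vector of RPKM values.
#' @export
#' @examples
#' compute_rpkm(10, 1000, 1e6)  # 10
compute_rpkm <- function(counts, gene_length, library_size) {
  stopifnot(length(gene_length) == length(counts), all(gene_length > 0))
  if (length(library_size) != 1 || library_size <= 0) {
    stop("degenerate sample: library_size must be a single positive number",
         call. = FALSE)
  }
  counts / (gene_length / 1000) / (library_size / 1e6)
}
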