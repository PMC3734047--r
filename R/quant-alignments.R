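#' Group SAM alignments by read
#'
#' Reads a SAM file (converted through Rsamtools) and collates all
#' mapped alignment records of each read into one group, the unit on
#' which filtering and fractional (1/k) counting operate. Unmapped
#' records contribute no locus. The mismatch count is taken from the
#' `NM` tag; records lacking it are treated as mismatch-free, with a
#' warning giving the count (data are not silently dropped).
#'
#' The result is sorted by read id and coordinates, so it is invariant
#' to the record order of the input file.
#'
#' @param sam_path Path to a SAM file with `@SQ` lines for every
#'   reference used.
#' @return A tibble with one row per alignment locus: `read_id`,
#'   `replicon`, `start`, `end`, `nm`.
#' @export
group_alignments <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth"), tag = "NM")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- bitwAnd(res$flag, 4L) == 0L
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(res$qname))
  n_missing <- sum(is.na(nm[mapped]))
  if (n_missing > 0) {
    warning(n_missing, " mapped record(s) lack an NM tag; ",
            "treated as mismatch-free", call. = FALSE)
    nm[is.na(nm)] <- 0L
  }
  tibble::tibble(
    read_id = res$qname[mapped],
    replicon = as.character(res$rname[mapped]),
    start = res$pos[mapped],
    end = res$pos[mapped] + res$qwidth[mapped] - 1L,
    nm = nm[mapped]
  ) |>
    dplyr::arrange(.data$read_id, .data$replicon, .data$start, .data$nm)
}
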