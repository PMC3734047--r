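#' Read a genome annotation from GFF3 + rRNA interval TSV
#'
#' Parses CDS features (needing an `ID` attribute) with rtracklayer and
#' replicon lengths from `##sequence-region` pragmas, and the rRNA
#' exclusion intervals from a three-column TSV (replicon, start, end).
#' Intervals listed high-to-low — as rrn operons on the reverse strand
#' often are — are normalized to `start <= end`. Features outside
#' replicon bounds or on unknown replicons are errors.
#'
#' @param gff_path GFF3 file with CDS features and sequence-region
#'   pragmas.
#' @param rrna_path TSV of rRNA intervals; an empty table (header only)
#'   yields an empty exclusion set.
#' @return A `genome_annotation` object (see [generate_annotation()]).
#' @export
read_annotation <- function(gff_path, rrna_path) {
  pragmas <- grep("^##sequence-region", readLines(gff_path), value = TRUE)
  if (length(pragmas) == 0) {
    stop("GFF3 lacks ##sequence-region pragmas; replicon lengths unknown",
         call. = FALSE)
  }
  fields <- strsplit(trimws(pragmas), "\\s+")
  replicons <- tibble::tibble(
    name = vapply(fields, `[[`, "", 2),
    length = as.integer(vapply(fields, `[[`, "", 4))
  )

  gr <- rtracklayer::import(gff_path)
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids) || anyNA(ids)) {
    stop("every CDS record must carry an ID attribute", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicated gene IDs in GFF3", call. = FALSE)
  cds <- tibble::tibble(
    gene_id = as.character(ids),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  cds$length <- cds$end - cds$start + 1L

  bad_repl <- setdiff(cds$replicon, replicons$name)
  if (length(bad_repl) > 0) {
    stop("CDS on unknown replicon(s): ", paste(bad_repl, collapse = ", "),
         call. = FALSE)
  }
  repl_len <- replicons$length[match(cds$replicon, replicons$name)]
  if (any(cds$start < 1 | cds$end > repl_len)) {
    stop("CDS outside replicon bounds", call. = FALSE)
  }

  rr_raw <- readr::read_tsv(rrna_path, show_col_types = FALSE,
                            col_types = readr::cols(
                              replicon = readr::col_character(),
                              start = readr::col_integer(),
                              end = readr::col_integer()
                            ))
  if (!all(c("replicon", "start", "end") %in% names(rr_raw))) {
    stop("rRNA TSV must have columns replicon, start, end", call. = FALSE)
  }
  rr <- rr_raw |>
    dplyr::mutate(lo = pmin(.data$start, .data$end),
                  hi = pmax(.data$start, .data$end)) |>
    dplyr::transmute(replicon = .data$replicon, start = .data$lo,
                     end = .data$hi)
  if (nrow(rr) > 0) {
    bad <- setdiff(rr$replicon, replicons$name)
    if (length(bad) > 0) {
      stop("rRNA interval on unknown replicon(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    rlen <- replicons$length[match(rr$replicon, replicons$name)]
    if (any(rr$start < 1 | rr$end > rlen)) {
      stop("rRNA interval outside replicon bounds", call. = FALSE)
    }
  }

  structure(
    list(replicons = replicons, cds = cds, rrna = rr, rrna_raw = rr_raw),
    class = "genome_annotation"
  )
}
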