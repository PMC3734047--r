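#' Generate a toy multi-replicon genome annotation
#'
#' Lays out non-overlapping CDS features round-robin across the
#' configured replicons, then appends rRNA (rrn-operon-like) exclusion
#' intervals. rRNA intervals are ~5.2 kb, the size of a bacterial rrn
#' operon. To exercise downstream coordinate normalization, the first
#' rRNA interval is recorded in the raw interval table
#' (`$rrna_raw`, the table [write_annotation()] exports) with its
#' coordinates in descending order; the normalized table (`$rrna`)
#' always has `start <= end`.
#'
#' @param config A [synth_config()].
#' @return A `genome_annotation` object: a list with tibbles
#'   `replicons` (name, length), `cds` (gene_id, replicon, start, end,
#'   strand, length), `rrna` (normalized intervals) and `rrna_raw`
#'   (as-exported intervals, first one reversed).
#' @export
#' @examples
#' ann <- generate_annotation(synth_config(n_genes = 6, seed = 7))
#' ann$cds
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_genes
  lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                 n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  repl_idx <- rep_len(seq_len(config$n_replicons), n)
  repl_names <- sprintf("chr%d", seq_len(config$n_replicons))

  cds <- vector("list", config$n_replicons)
  cursor <- rep(1L, config$n_replicons)
  gaps <- sample(200:800, n, replace = TRUE)
  starts <- integer(n); ends <- integer(n)
  for (g in seq_len(n)) {
    r <- repl_idx[g]
    starts[g] <- cursor[r] + gaps[g]
    ends[g] <- starts[g] + lens[g] - 1L
    cursor[r] <- ends[g] + 1L
  }
  cds_tbl <- tibble::tibble(
    gene_id = sprintf("gene%03d", seq_len(n)),
    replicon = repl_names[repl_idx],
    start = starts, end = ends, strand = strands, length = as.integer(lens)
  )

  rrna_len <- 5200L
  n_rr <- config$n_rrn_regions
  rr_tbl <- tibble::tibble(replicon = character(0), start = integer(0),
                           end = integer(0))
  if (n_rr > 0) {
    rr_repl <- rep_len(seq_len(config$n_replicons), n_rr)
    rr_start <- integer(n_rr); rr_end <- integer(n_rr)
    rr_gaps <- sample(500:1500, n_rr, replace = TRUE)
    for (i in seq_len(n_rr)) {
      r <- rr_repl[i]
      rr_start[i] <- cursor[r] + rr_gaps[i]
      rr_end[i] <- rr_start[i] + rrna_len - 1L
      cursor[r] <- rr_end[i] + 1L
    }
    rr_tbl <- tibble::tibble(replicon = repl_names[rr_repl],
                             start = rr_start, end = rr_end)
  }

  repl_len <- cursor + 999L
  if (!is.null(config$replicon_length)) {
    if (any(repl_len > config$replicon_length)) {
      stop("features do not fit in replicon_length = ",
           config$replicon_length, " bp; increase it or reduce gene count/size",
           call. = FALSE)
    }
    repl_len <- rep(as.integer(config$replicon_length), config$n_replicons)
  }

  rr_raw <- rr_tbl
  if (nrow(rr_raw) >= 1) {  # first interval deliberately high-to-low
    rr_raw[1, c("start", "end")] <- rr_raw[1, c("end", "start")]
  }

  structure(
    list(
      replicons = tibble::tibble(name = repl_names,
                                 length = as.integer(repl_len)),
      cds = cds_tbl,
      rrna = rr_tbl,
      rrna_raw = rr_raw
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d replicons, %d CDS, %d rRNA intervals\n",
              nrow(x$replicons), nrow(x$cds), nrow(x$rrna)))
  invisible(x)
}

cds_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$cds$replicon,
    ranges = IRanges::IRanges(annotation$cds$start, annotation$cds$end),
    gene_id = annotation$cds$gene_id
  )
}

rrna_granges <- function(annotation) {
  if (nrow(annotation$rrna) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = annotation$rrna$replicon,
    ranges = IRanges::IRanges(annotation$rrna$start, annotation$rrna$end)
  )
}

#' Write an annotation to GFF3 + rRNA interval TSV
#'
#' CDS features go to GFF3 (via rtracklayer) with `##sequence-region`
#' pragmas carrying replicon lengths; rRNA exclusion intervals go to a
#' three-column TSV (replicon, start, end) exactly as generated — i.e.
#' including any interval stored high-to-low.
#'
#' @param annotation A `genome_annotation`.
#' @param gff_path,rrna_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_annotation <- function(annotation, gff_path, rrna_path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$cds$replicon,
    ranges = IRanges::IRanges(annotation$cds$start, annotation$cds$end),
    strand = annotation$cds$strand,
    type = "CDS",
    ID = annotation$cds$gene_id,
    Name = annotation$cds$gene_id
  )
  suppressWarnings(rtracklayer::export.gff3(gr, gff_path))
  # rtracklayer does not write sequence-region pragmas; splice them in so
  # replicon bounds survive the round trip
  lines <- readLines(gff_path)
  pragmas <- sprintf("##sequence-region %s 1 %d",
                     annotation$replicons$name, annotation$replicons$length)
  writeLines(c(lines[1], pragmas, lines[-1]), gff_path)
  readr::write_tsv(annotation$rrna_raw, rrna_path)
  invisible(c(gff = gff_path, rrna = rrna_path))
}
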