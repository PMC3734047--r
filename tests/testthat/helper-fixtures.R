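# hand-built two-replicon annotation with known coordinates
manual_annotation <- function() {
  structure(
    list(
      replicons = tibble::tibble(name = c("chr1", "chr2"),
                                 length = c(10000L, 8000L)),
      cds = tibble::tibble(
        gene_id = c("geneA", "geneB", "geneC"),
        replicon = c("chr1", "chr1", "chr2"),
        start = c(1001L, 3001L, 501L),
        end = c(2500L, 3500L, 1500L),
        strand = c("+", "-", "+"),
        length = c(1500L, 500L, 1000L)
      ),
      rrna = tibble::tibble(replicon = "chr1", start = 5000L, end = 6000L),
      rrna_raw = tibble::tibble(replicon = "chr1", start = 6000L,
                                end = 5000L)
    ),
    class = "genome_annotation"
  )
}

# alignment-locus table builder (36-bp reads)
mk_loci <- function(read_id, replicon, start, nm = 0L) {
  tibble::tibble(read_id = read_id, replicon = replicon,
                 start = as.integer(start),
                 end = as.integer(start) + 35L, nm = as.integer(nm))
}

# design for a conditions x replicates layout
mk_design <- function(conditions, replicates = 2) {
  tidyr::crossing(condition = conditions, replicate = seq_len(replicates)) |>
    dplyr::mutate(sample_id = paste0(condition, "_r", replicate)) |>
    dplyr::select(sample_id, condition, replicate)
}
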