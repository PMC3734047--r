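#' Simulate single-end alignments for one sample, with ground truth
#'
#' Draws `reads_per_sample` reads for one (condition, replicate) cell of
#' the design. Each read is assigned to one of three disjoint classes
#' with probabilities from the config: rRNA-derived (placed uniformly in
#' an rRNA interval, weighted by interval length), mismatched (placed in
#' a gene like a clean read but carrying NM = 1), or clean. Clean reads
#' are placed uniformly within a gene chosen with probability
#' proportional to level x length (level = expected reads per base for
#' this condition); a `multimap_fraction` of them additionally receive
#' k - 1 secondary alignments (k uniform in 2..max_loci_per_read) at
#' uniformly chosen positions in uniformly chosen genes, the SAM dialect
#' being repeated QNAME records (primary + flag-256 secondaries), not an
#' NH tag.
#'
#' The returned truth tables record, per gene, how many reads originated
#' from it (primary locus) in the clean and mismatched classes, and per
#' read its class and locus count, so downstream filtering and counting
#' can be validated exactly.
#'
#' @param annotation A [genome_annotation][generate_annotation].
#' @param profile An [expression_profile()] covering all genes and the
#'   requested condition.
#' @param config A [synth_config()].
#' @param condition Condition label (must be a profile column).
#' @param replicate Replicate index (1-based).
#' @return A `sim_alignments` object: list with `alignments` (tibble:
#'   qname, flag, replicon, pos, end, nm), `truth` (list of `reads` and
#'   `gene_counts` tibbles), `replicons`, `condition`, `replicate`.
#' @export
simulate_alignments <- function(annotation, profile, config,
                                condition, replicate = 1L) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "synth_config"))
  if (!condition %in% names(profile)) {
    stop("unknown condition label: ", condition, call. = FALSE)
  }
  if (!all(annotation$cds$gene_id %in% profile$gene_id)) {
    stop("profile must cover every annotated gene", call. = FALSE)
  }
  cond_idx <- match(condition, setdiff(names(profile), "gene_id"))
  set.seed(sample_seed(config$seed, cond_idx, replicate))

  rl <- config$read_length
  N <- config$reads_per_sample
  genes <- annotation$cds
  level <- profile[[condition]][match(genes$gene_id, profile$gene_id)]
  gene_w <- level * genes$length
  if (all(gene_w == 0)) {
    stop("expression profile is identically zero for condition ", condition,
         call. = FALSE)
  }

  p_rrna <- config$rrna_read_fraction
  if (nrow(annotation$rrna) == 0) p_rrna <- 0
  cls <- sample(c("rrna", "mismatch", "clean"), N, replace = TRUE,
                prob = c(p_rrna, config$mismatch_fraction,
                         1 - p_rrna - config$mismatch_fraction))
  qname <- sprintf("r%07d", seq_len(N))

  place_in_gene <- function(idx) {
    gi <- sample.int(nrow(genes), length(idx), replace = TRUE, prob = gene_w)
    pos <- genes$start[gi] +
      vapply(genes$length[gi] - rl + 1L, function(m) sample.int(m, 1L), 1L) - 1L
    list(gene = gi, replicon = genes$replicon[gi], pos = pos)
  }

  al <- list(); truth_reads <- list()

  genic <- which(cls != "rrna")
  if (length(genic) > 0) {
    pl <- place_in_gene(genic)
    nm <- ifelse(cls[genic] == "mismatch", 1L, 0L)
    al[["primary"]] <- tibble::tibble(
      qname = qname[genic], flag = 0L, replicon = pl$replicon,
      pos = pl$pos, nm = nm
    )
    is_mm <- cls[genic] == "clean" &
      stats::runif(length(genic)) < config$multimap_fraction
    mm_idx <- which(is_mm)
    extra <- integer(0)
    if (length(mm_idx) > 0) {
      k <- sample(2:config$max_loci_per_read, length(mm_idx), replace = TRUE)
      rep_read <- rep(mm_idx, k - 1L)
      gi2 <- sample.int(nrow(genes), length(rep_read), replace = TRUE)
      pos2 <- genes$start[gi2] +
        vapply(genes$length[gi2] - rl + 1L, function(m) sample.int(m, 1L), 1L) - 1L
      al[["secondary"]] <- tibble::tibble(
        qname = qname[genic][rep_read], flag = 256L,
        replicon = genes$replicon[gi2], pos = pos2, nm = 0L
      )
      extra <- stats::setNames(k - 1L, qname[genic][mm_idx])
    }
    n_loci <- rep(1L, length(genic))
    if (length(mm_idx) > 0) n_loci[mm_idx] <- n_loci[mm_idx] + (extra)
    truth_reads[["genic"]] <- tibble::tibble(
      qname = qname[genic], class = cls[genic],
      gene_id = genes$gene_id[pl$gene], n_loci = n_loci
    )
  }

  rr <- which(cls == "rrna")
  if (length(rr) > 0) {
    ri <- sample.int(nrow(annotation$rrna), length(rr), replace = TRUE,
                     prob = annotation$rrna$end - annotation$rrna$start + 1L)
    span <- annotation$rrna$end[ri] - annotation$rrna$start[ri] + 1L - rl + 1L
    pos <- annotation$rrna$start[ri] +
      vapply(span, function(m) sample.int(m, 1L), 1L) - 1L
    al[["rrna"]] <- tibble::tibble(
      qname = qname[rr], flag = 0L, replicon = annotation$rrna$replicon[ri],
      pos = pos, nm = 0L
    )
    truth_reads[["rrna"]] <- tibble::tibble(
      qname = qname[rr], class = "rrna", gene_id = NA_character_, n_loci = 1L
    )
  }

  alignments <- dplyr::arrange(dplyr::bind_rows(al), .data$qname, .data$flag,
                               .data$replicon, .data$pos)
  alignments$end <- alignments$pos + rl - 1L
  reads <- dplyr::arrange(dplyr::bind_rows(truth_reads), .data$qname)
  gene_counts <- reads |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::count(.data$gene_id, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (col in c("clean", "mismatch")) {
    if (!col %in% names(gene_counts)) gene_counts[[col]] <- 0L
  }
  gene_counts <- genes |>
    dplyr::select("gene_id") |>
    dplyr::left_join(gene_counts, by = "gene_id") |>
    dplyr::mutate(dplyr::across(c("clean", "mismatch"),
                                ~ tidyr::replace_na(.x, 0L)))

  structure(
    list(
      alignments = alignments,
      truth = list(reads = reads, gene_counts = gene_counts),
      replicons = annotation$replicons,
      read_length = rl,
      condition = condition,
      replicate = as.integer(replicate)
    ),
    class = "sim_alignments"
  )
}

#' @export
print.sim_alignments <- function(x, ...) {
  cat(sprintf("<sim_alignments> %s rep %d: %d reads, %d alignment records\n",
              x$condition, x$replicate, nrow(x$truth$reads),
              nrow(x$alignments)))
  invisible(x)
}

#' Write simulated alignments as a SAM file
#'
#' Emits a valid SAM 1.6 file: `@SQ` header line per replicon, one record
#' per alignment locus with a 36M-style CIGAR, constant base/quality
#' strings, an `NM:i:` tag, and flag 256 on secondary loci of multimapped
#' reads.
#'
#' @param sim A [simulate_alignments()] result.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path) {
  stopifnot(inherits(sim, "sim_alignments"))
  rl <- sim$read_length
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d",
                      sim$replicons$name, sim$replicons$length))
  a <- sim$alignments
  seq_f <- strrep("A", rl); qual <- strrep("I", rl)
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  a$qname, a$flag, a$replicon, a$pos,
                  ifelse(a$flag == 256L, 0L, 60L), rl,
                  ifelse(a$flag == 256L, "*", seq_f),
                  ifelse(a$flag == 256L, "*", qual), a$nm)
  writeLines(c(header, recs), path)
  invisible(path)
}
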