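#' Configuration for the synthetic RNA-seq experiment generator
#'
#' Bundles the parameters of the toy genome and read simulator: replicon
#' and gene layout, the condition/replicate design, library size, and the
#' fractions of reads falling into the three disjoint read classes
#' (rRNA-derived, mismatched, clean genic).
#'
#' Defaults emulate a small PHA-producing bacterium sequenced through an
#' incompletely rRNA-depleted library: three replicons, an rRNA read
#' fraction of 0.8 (the regime seen when bacterial mRNA enrichment leaves
#' 70-90% of reads on rrn operons), 36-bp single-end reads, and two
#' technical replicates for each of four sampling phases.
#'
#' @param n_replicons Number of circular replicons in the toy genome.
#' @param n_genes Number of CDS features (>= 2), laid out round-robin
#'   across replicons without overlap.
#' @param gene_length_range Length range (bp) genes are drawn from;
#'   minimum must be at least `read_length`.
#' @param n_rrn_regions Number of rRNA exclusion intervals.
#' @param conditions Character vector of condition labels.
#' @param replicates_per_condition Technical replicates per condition.
#' @param reads_per_sample Mapped reads simulated per sample.
#' @param rrna_read_fraction Expected fraction of reads placed in rRNA
#'   intervals.
#' @param multimap_fraction Fraction of clean genic reads that align to
#'   more than one locus.
#' @param max_loci_per_read Maximum loci for a multimapped read (>= 2).
#' @param mismatch_fraction Fraction of reads carrying a mismatch
#'   (NM > 0); disjoint from the rRNA class, so
#'   `rrna_read_fraction + mismatch_fraction <= 1`.
#' @param read_length Read length in bp.
#' @param replicon_length Optional fixed replicon length (bp). `NULL`
#'   sizes each replicon to fit its features; a fixed length that cannot
#'   hold them is a sizing error.
#' @param seed Integer seed; identical seeds reproduce identical outputs
#'   byte for byte.
#'
#' @return A `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 10, reads_per_sample = 500, seed = 42)
synth_config <- function(n_replicons = 3,
                         n_genes = 60,
                         gene_length_range = c(300, 3000),
                         n_rrn_regions = 5,
                         conditions = c("F16", "F26", "F36", "O26"),
                         replicates_per_condition = 2,
                         reads_per_sample = 20000,
                         rrna_read_fraction = 0.8,
                         multimap_fraction = 0.05,
                         max_loci_per_read = 3,
                         mismatch_fraction = 0.05,
                         read_length = 36,
                         replicon_length = NULL,
                         seed = 1L) {
  stopifnot(
    n_replicons >= 1, n_genes >= 2,
    length(gene_length_range) == 2,
    gene_length_range[1] <= gene_length_range[2],
    n_rrn_regions >= 0,
    length(conditions) >= 1,
    replicates_per_condition >= 1,
    reads_per_sample >= 0,
    max_loci_per_read >= 2,
    read_length >= 1
  )
  fracs <- c(rrna_read_fraction, multimap_fraction, mismatch_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (rrna_read_fraction + mismatch_fraction > 1) {
    stop("rrna_read_fraction + mismatch_fraction must not exceed 1 ",
         "(the classes are disjoint)", call. = FALSE)
  }
  if (gene_length_range[1] < read_length) {
    stop("genes must be at least one read long", call. = FALSE)
  }
  structure(
    list(
      n_replicons = as.integer(n_replicons),
      n_genes = as.integer(n_genes),
      gene_length_range = as.integer(gene_length_range),
      n_rrn_regions = as.integer(n_rrn_regions),
      conditions = as.character(conditions),
      replicates_per_condition = as.integer(replicates_per_condition),
      reads_per_sample = as.integer(reads_per_sample),
      rrna_read_fraction = rrna_read_fraction,
      multimap_fraction = multimap_fraction,
      max_loci_per_read = as.integer(max_loci_per_read),
      mismatch_fraction = mismatch_fraction,
      read_length = as.integer(read_length),
      replicon_length = replicon_length,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  genome: %d replicons, %d genes (%d-%d bp), %d rRNA regions\n",
              x$n_replicons, x$n_genes, x$gene_length_range[1],
              x$gene_length_range[2], x$n_rrn_regions))
  cat(sprintf("  design: %s x %d replicates, %d reads/sample (%d bp)\n",
              paste(x$conditions, collapse = "/"),
              x$replicates_per_condition, x$reads_per_sample, x$read_length))
  cat(sprintf("  read classes: rRNA %.2f, mismatch %.2f, multimap %.2f (<= %d loci)\n",
              x$rrna_read_fraction, x$mismatch_fraction,
              x$multimap_fraction, x$max_loci_per_read))
  invisible(x)
}

# deterministic per-sample seed below 2^31, unique per (seed, condition, rep)
sample_seed <- function(seed, condition_index, replicate) {
  as.integer((as.numeric(seed) * 7919 + condition_index * 1299709 +
                replicate * 104729) %% 2147483647L)
}

#' Ground-truth expression profile for the read simulator
#'
#' Assigns each gene a nonnegative expression level per condition,
#' expressed as expected reads per base (arbitrary units; only relative
#' levels matter because each sample draws a fixed number of reads).
#' The default profile always contains the three expression archetypes a
#' recovery test needs: a silent gene (level 0), a weakly expressed gene,
#' and a highly expressed gene; remaining genes draw lognormal levels.
#' Per-gene fold changes between conditions are programmed through
#' `fold_changes`.
#'
#' @param annotation A [genome_annotation][generate_annotation] object.
#' @param conditions Condition labels (columns of the profile).
#' @param base_level Optional named numeric vector of per-gene baseline
#'   levels (reads per base); names must cover all gene ids.
#' @param fold_changes Optional named list: `gene_id -> named numeric` of
#'   per-condition multipliers applied to the baseline (conditions not
#'   named keep multiplier 1).
#' @param seed Seed for the default lognormal baseline draw.
#'
#' @return A tibble with `gene_id` and one level column per condition,
#'   carrying the fold-change map as attribute `fold_changes`.
#' @export
expression_profile <- function(annotation,
                               conditions = c("F16", "F26", "F36", "O26"),
                               base_level = NULL,
                               fold_changes = NULL,
                               seed = 1L) {
  genes <- annotation$cds$gene_id
  if (is.null(base_level)) {
    set.seed(as.integer(seed))
    base_level <- stats::setNames(rlnorm(length(genes), log(0.05), 1.2), genes)
    base_level[genes[1]] <- 0                       # silent
    if (length(genes) >= 3) {
      base_level[genes[2]] <- 0.002                 # weak
      base_level[genes[3]] <- max(base_level) * 10  # high
    }
  }
  if (!all(genes %in% names(base_level))) {
    stop("base_level must name every gene in the annotation", call. = FALSE)
  }
  if (any(base_level < 0)) stop("expression levels must be nonnegative", call. = FALSE)
  prof <- tibble::tibble(gene_id = genes)
  for (cond in conditions) {
    lv <- unname(base_level[genes])
    if (!is.null(fold_changes)) {
      for (g in names(fold_changes)) {
        fc <- fold_changes[[g]]
        if (!is.null(fc) && cond %in% names(fc)) {
          lv[genes == g] <- lv[genes == g] * fc[[cond]]
        }
      }
    }
    prof[[cond]] <- lv
  }
  attr(prof, "fold_changes") <- fold_changes
  prof
}
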