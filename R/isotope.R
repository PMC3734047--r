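#' Fragment and monomer specifications for 3HB methyl ester GC-MS
#'
#' `phb_fragments()` returns the three diagnostic fragment ions of
#' 3-hydroxybutyrate methyl ester with their carbon counts as read from
#' the fragment formulas: m/z 45 (CH3-CH=OH+, 2 C), m/z 87
#' (CH3-C(OH)H-CH2-C=O+, 4 C) and m/z 103 (CH3-O-CO-CH2-CH=OH+, 4 C —
#' the methyl carbon introduced by methanolysis is counted as written).
#' `phb_monomer()` is the P(3HB) repeat unit C4H6O2, 86.09 g/mol.
#'
#' @return `phb_fragments()`: tibble `label`, `n_carbons`;
#'   `phb_monomer()`: list `name`, `formula`, `molar_mass`, `n_carbons`.
#' @export
phb_fragments <- function() {
  tibble::tibble(label = c("mz45", "mz87", "mz103"),
                 n_carbons = c(2L, 4L, 4L))
}

#' @rdname phb_fragments
#' @export
phb_monomer <- function() {
  list(name = "3-hydroxybutyrate repeat unit", formula = "C4H6O2",
       molar_mass = 86.09, n_carbons = 4L)
}

#' 13C atom fraction of a fragment from its mass-isotopomer distribution
#'
#' The average probability that a carbon position of the fragment is
#' 13C: sum(i * Mi) / n_carbons after normalizing the abundance vector
#' M0..Mn to sum 1. For an exact binomial MID at per-carbon probability
#' p this returns p (binomial mean identity). Channels above
#' M+n_carbons, if present, are dropped with a warning before
#' normalization.
#'
#' @param abundances Numeric vector M0..Mn of nonnegative abundances
#'   (need not be normalized).
#' @param n_carbons Carbon count of the fragment; default
#'   `length(abundances) - 1`.
#' @return Atom fraction in \[0, 1\].
#' @export
#' @examples
#' atom_fraction(c(0.25, 0.5, 0.25))  # 0.5
atom_fraction <- function(abundances, n_carbons = length(abundances) - 1L) {
  stopifnot(n_carbons >= 1)
  if (length(abundances) > n_carbons + 1) {
    warning("MID has channels above M+", n_carbons,
            "; dropping them before normalization", call. = FALSE)
    abundances <- abundances[seq_len(n_carbons + 1)]
  }
  if (anyNA(abundances)) abundances <- abundances[!is.na(abundances)]
  if (any(abundances < 0)) stop("negative isotopomer abundance", call. = FALSE)
  tot <- sum(abundances)
  if (tot <= 0) stop("degenerate spectrum: all abundances zero", call. = FALSE)
  mid <- abundances / tot
  sum((seq_along(mid) - 1) * mid) / n_carbons
}

#' Mean 13C abundance over fragments, in percent
#'
#' Computes the atom fraction of each fragment MID and reports the
#' unweighted arithmetic mean as a percentage — the summary used as the
#' 13C abundance of the polymer fraction.
#'
#' @param mids A list of numeric MID vectors, or a data frame with
#'   `n_carbons` and `M0..Mn` columns (one row per fragment; unused
#'   high channels NA).
#' @return Mean 13C abundance in percent.
#' @export
mean_abundance <- function(mids) {
  if (is.data.frame(mids)) {
    mcols <- grep("^M[0-9]+$", names(mids), value = TRUE)
    mids <- purrr::map(seq_len(nrow(mids)), function(i) {
      v <- as.numeric(mids[i, mcols])
      n <- mids$n_carbons[i]
      structure(v[seq_len(n + 1)], n_carbons = n)
    })
  }
  if (length(mids) == 0) stop("need at least one fragment MID", call. = FALSE)
  fr <- vapply(mids, function(v) {
    n <- attr(v, "n_carbons")
    if (is.null(n)) n <- length(v) - 1L
    atom_fraction(v, n)
  }, numeric(1))
  mean(fr) * 100
}

#' 13C incorporation into the polymer, from labeled vs control abundance
#'
#' Converts the difference between the 13C abundance measured after
#' growth with the 13C-labeled substrate and the matched 12C control
#' (which carries the natural-abundance plus derivatization background,
#' so no separate natural-abundance correction is applied) into mmol of
#' newly incorporated 13C per gram of polymer:
#'
#' increase = delta x nbar_C / M_monomer x 1000,
#'
#' with delta the abundance difference as an atom fraction, nbar_C the
#' mean carbon count of the measured fragments (10/3 for the standard
#' 3HB methyl ester trio) and M_monomer the repeat-unit molar mass
#' (86.09 g/mol for P(3HB)). Full precision is kept internally;
#' round at reporting (two decimals is the conventional precision).
#'
#' Vectorized over strains/samples.
#'
#' @param abundance_labeled,abundance_control 13C abundances in
#'   percent.
#' @param fragments Fragment spec tibble (`label`, `n_carbons`);
#'   default [phb_fragments()].
#' @param monomer Monomer spec list; default [phb_monomer()].
#' @param strain Optional label column carried through.
#' @return An `incorporation_result` tibble: `strain` (if given),
#'   `abundance_labeled`, `abundance_control`, `delta` (atom fraction)
#'   and `increase` (mmol 13C / g polymer).
#' @export
#' @examples
#' incorporation_increase(2.22, 1.13)  # 0.42 mmol/g at 2 decimals
incorporation_increase <- function(abundance_labeled, abundance_control,
                                   fragments = phb_fragments(),
                                   monomer = phb_monomer(),
                                   strain = NULL) {
  stopifnot(nrow(fragments) >= 1, all(fragments$n_carbons >= 1))
  if (monomer$molar_mass <= 0) {
    stop("monomer molar mass must be positive", call. = FALSE)
  }
  delta <- (abundance_labeled - abundance_control) / 100
  nbar <- mean(fragments$n_carbons)
  increase <- delta * nbar / monomer$molar_mass * 1000
  out <- tibble::tibble(
    abundance_labeled = abundance_labeled,
    abundance_control = abundance_control,
    delta = delta,
    increase = increase
  )
  if (!is.null(strain)) out <- dplyr::mutate(out, strain = strain, .before = 1)
  structure(out, class = c("incorporation_result", class(out)),
            mean_fragment_carbons = nbar, molar_mass = monomer$molar_mass)
}

#' Fold ratio of 13C incorporation between two strains
#'
#' @param a,b `incorporation_result` rows (or bare increase values, in
#'   mmol/g); `b` is the reference and must have a positive increase.
#' @param digits Increases are rounded to this many decimals before
#'   dividing (default 2, the precision incorporation tables report);
#'   use `NULL` for full precision.
#' @return `a` / `b` as a single number.
#' @export
fold_ratio <- function(a, b, digits = 2) {
  inc <- function(z) if (is.data.frame(z)) z$increase else as.numeric(z)
  ia <- inc(a); ib <- inc(b)
  if (!is.null(digits)) {
    ia <- round(ia, digits); ib <- round(ib, digits)
  }
  if (any(ib <= 0)) {
    stop("reference increase must be positive for a fold ratio",
         call. = FALSE)
  }
  ia / ib
}

#' Mean and standard error of enrichment across replicate spectra
#'
#' Applies [atom_fraction()] to each replicate spectrum of one fragment
#' and summarizes: the per-carbon labeling probability estimate with
#' its standard error (absent for a single spectrum).
#'
#' @param mids A [simulate_mid()] tibble (`n_carbons`, `M0..Mn` per
#'   row) or list of MID vectors.
#' @return Tibble: `estimate`, `se`, `n_spectra`.
#' @export
estimate_enrichment <- function(mids) {
  if (is.data.frame(mids)) {
    mcols <- grep("^M[0-9]+$", names(mids), value = TRUE)
    fr <- vapply(seq_len(nrow(mids)), function(i) {
      atom_fraction(as.numeric(mids[i, mcols]), mids$n_carbons[i])
    }, numeric(1))
  } else {
    fr <- vapply(mids, atom_fraction, numeric(1))
  }
  n <- length(fr)
  tibble::tibble(
    estimate = mean(fr),
    se = if (n >= 2) sd(fr) / sqrt(n) else NA_real_,
    n_spectra = n
  )
}

#' Measured 13C abundances of P(3HB) for Rubisco disruption strains
#'
#' Loads the bundled GC-MS 13C-abundance table for R. eutropha H16 and
#' its Rubisco (cbbLS) single/double disruptants grown on fructose with
#' NaH13CO3 (labeled) or NaH12CO3 (control) additions: one row per
#' strain with both abundances in percent.
#'
#' @return Tibble: `strain`, `abundance_12c`, `abundance_13c`.
#' @export
phb_labeling <- function() {
  readr::read_tsv(system.file("extdata", "phb_13c_labeling.tsv",
                              package = "phaseq", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Bar chart of 13C incorporation per strain
#'
#' @param object An `incorporation_result` with a `strain` column.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.incorporation_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"strain" %in% names(df)) df$strain <- paste0("s", seq_len(nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$strain,
                                                      -.data$increase),
                                   y = .data$increase)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "13C increase (mmol / g polymer)") +
    ggplot2::theme_minimal()
}
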