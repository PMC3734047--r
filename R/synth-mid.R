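#' Exact binomial mass-isotopomer distribution
#'
#' Under independent per-carbon labeling, the probability that a
#' fragment with `n_carbons` carbon positions carries i heavy carbons is
#' Binom(n_carbons, p13); the M0..Mn abundance vector is that binomial
#' pmf. Natural 13C abundance corresponds to p13 = 0.0108.
#'
#' @param p13 Per-carbon probability of 13C, in \[0, 1\].
#' @param n_carbons Number of carbon positions (>= 1).
#' @return Numeric vector `M0..Mn` summing to 1 (within 1e-12), with
#'   names `M0`, `M1`, ...
#' @export
#' @examples
#' binomial_mid(0.5, 2)   # (0.25, 0.5, 0.25)
binomial_mid <- function(p13, n_carbons) {
  if (p13 < 0 || p13 > 1) stop("p13 must lie in [0, 1]", call. = FALSE)
  stopifnot(n_carbons >= 1)
  mid <- dbinom(0:n_carbons, size = n_carbons, prob = p13)
  names(mid) <- paste0("M", 0:n_carbons)
  mid
}

#' Simulate noisy mass-isotopomer spectra
#'
#' Each spectrum starts from the exact binomial MID at `p13`, multiplies
#' every channel by an independent lognormal factor with mean 1 and
#' coefficient of variation `noise_cv` (multiplicative measurement
#' noise), and renormalizes to sum 1.
#'
#' @inheritParams binomial_mid
#' @param noise_cv Coefficient of variation of the per-channel
#'   multiplicative noise (0 = noise free).
#' @param n_spectra Number of replicate spectra.
#' @param seed Integer seed; same seed, same spectra.
#' @return A tibble with columns `spectrum`, `n_carbons`, `M0..Mn`.
#' @export
simulate_mid <- function(p13, n_carbons, noise_cv = 0, n_spectra = 1,
                         seed = 1L) {
  base <- binomial_mid(p13, n_carbons)
  stopifnot(noise_cv >= 0, n_spectra >= 1)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- matrix(NA_real_, n_spectra, n_carbons + 1,
                dimnames = list(NULL, names(base)))
  for (s in seq_len(n_spectra)) {
    f <- if (noise_cv > 0) {
      rlnorm(n_carbons + 1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, n_carbons + 1)
    v <- base * f
    out[s, ] <- v / sum(v)
  }
  dplyr::bind_cols(
    tibble::tibble(spectrum = seq_len(n_spectra),
                   n_carbons = as.integer(n_carbons)),
    tibble::as_tibble(out)
  )
}

#' Write / read fragment MID tables
#'
#' TSV layout: one row per (sample, fragment) with columns
#' `sample_id`, `strain`, `condition`, `fragment_label`, `n_carbons`,
#' `M0..Mn` (unused high channels left NA for short fragments).
#'
#' @param mids A tibble in the layout above.
#' @param path File path.
#' @return `path` invisibly; `read_mid_tsv()` returns the tibble.
#' @export
write_mid_tsv <- function(mids, path) {
  readr::write_tsv(mids, path)
  invisible(path)
}

#' @rdname write_mid_tsv
#' @export
read_mid_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
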