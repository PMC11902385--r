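#' Normalized sample autocorrelation of a window
#'
#' The lag-m coefficient is the centered cross-product summed over the valid
#' overlap divided by the total centered sum of squares,
#' `sum_{n=1..N-m} (x_n - mu)(x_{n+m} - mu) / sum (x_n - mu)^2`,
#' so the lag-0 value is exactly 1.  This is the standard biased
#' autocorrelation estimator (as computed by [stats::acf()]).
#'
#' @param x Numeric window (>= 2 samples, nonzero variance), or one row of a
#'   window tibble's `samples` list-column.
#' @param max_lag Maximum lag; default the full window (`length(x) - 1`).
#' @return Numeric vector of `max_lag + 1` coefficients, lags 0..max_lag.
#' @export
#' @examples
#' window_acf(sin(2 * pi * 0.25 * (0:159) / 5))[1]  # 1
window_acf <- function(x, max_lag = length(x) - 1) {
  if (length(x) < 2) abort("Window must have at least 2 samples.")
  if (sd(x) == 0) abort("Degenerate window: zero variance.")
  nu <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  nu[1] <- 1  # exact by definition; acf() can be one ulp off
  nu
}

#' One-sided power spectrum of an autocorrelation sequence
#'
#' Magnitude of the discrete Fourier transform of the zero-padded
#' autocorrelation, truncated to the one-sided grid of `nfft / 2 + 1` bins.
#' With 160-sample windows (32 s at 5 Hz) and `nfft = 512` this yields the
#' 257-dimensional feature curve used throughout the package.  The magnitude
#' is clipped at zero (a no-op up to numerical noise) so curves are always
#' non-negative.
#'
#' @param acf_values Autocorrelation coefficients, lag 0 first.
#' @param nfft FFT length; must be at least `length(acf_values)`.
#' @return Numeric vector of `nfft / 2 + 1` non-negative power values.
#' @export
#' @examples
#' length(acf_power_spectrum(window_acf(rnorm(160))))  # 257
acf_power_spectrum <- function(acf_values, nfft = 512) {
  if (nfft < length(acf_values)) abort("`nfft` must be >= the ACF length.")
  padded <- c(acf_values, rep(0, nfft - length(acf_values)))
  pmax(Mod(fft(padded))[seq_len(nfft %/% 2 + 1)], 0)
}

#' Build the labeled power-spectral feature matrix
#'
#' Converts each window into its autocorrelation and one-sided power-spectral
#' curve, and stacks the curves as rows of a samples-by-frequency-bins tibble
#' with the reference RR label and provenance carried along.  This is the
#' central feature object: n retained windows by c frequency bins.
#'
#' @param windows A window tibble from [preprocess_ppg()] / [segment_windows()].
#' @param nfft FFT length (257 feature bins with the default 512).
#' @param feature_dim Either `nfft / 2 + 1` (default: FFT of the zero-padded
#'   full ACF) or the window length itself (e.g. 160: truncated-ACF variant,
#'   no padding), provided for sensitivity checks.
#' @return A tibble with columns `record_id`, `window`, `rr`,
#'   `origin` (`"original"`) and feature columns `ps001`, `ps002`, ...
#' @export
ps_matrix <- function(windows, nfft = 512, feature_dim = NULL) {
  if (nrow(windows) == 0) abort("At least one window is required.")
  lens <- lengths(windows$samples)
  if (length(unique(lens)) != 1) abort("All windows must have the same length.")
  n_samp <- lens[1]
  curves <- if (!is.null(feature_dim) && feature_dim == n_samp) {
    # truncated-ACF variant: the ACF itself is the feature curve
    purrr::map(windows$samples, function(s) pmax(window_acf(s), 0))
  } else {
    dim_out <- nfft %/% 2 + 1
    if (!is.null(feature_dim) && feature_dim != dim_out) {
      abort("`feature_dim` must equal nfft/2 + 1 or the window length.")
    }
    purrr::map(windows$samples, function(s) acf_power_spectrum(window_acf(s), nfft))
  }
  mat <- do.call(rbind, curves)
  colnames(mat) <- ps_col_names(ncol(mat))
  dplyr::bind_cols(
    tibble::tibble(record_id = windows$record_id, window = windows$window,
                   rr = windows$rr, origin = "original"),
    tibble::as_tibble(mat)
  )
}

#' Write / read a power-spectral matrix as CSV
#'
#' CSV round-trip at double precision: provenance and label columns first,
#' then one column per frequency bin.
#'
#' @param ps A PS tibble from [ps_matrix()] or [ipsg_augment()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the PS tibble (reader).
#' @export
write_ps_csv <- function(ps, path) {
  readr::write_csv(ps, path)
  invisible(path)
}

#' @rdname write_ps_csv
#' @export
read_ps_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
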