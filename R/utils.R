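#' Derive a reproducible child seed
#'
#' Every stochastic stage in the package draws its seed from one top-level
#' integer through this splitter, so a single `seed` argument makes a whole
#' pipeline run reproducible while keeping the stages' random streams
#' distinct.  The scheme hashes the tag string and any extra integers into
#' a positive 31-bit integer (valid R seed).
#'
#' @param seed Integer top-level seed.
#' @param tag Character scalar naming the consuming stage.
#' @param ... Additional integers (e.g. a repetition index) mixed in.
#' @return A positive integer scalar < 2^31.
#' @export
#' @examples
#' derive_seed(1, "bootstrap", 3)
derive_seed <- function(seed, tag, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  extra <- c(...)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  for (v in extra) h <- (h * 131 + (as.double(v) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483562 + 1)
}

# run code under a local RNG state so package internals never disturb the
# caller's random stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# names of the power-spectral feature columns, zero-padded for stable ordering
ps_col_names <- function(dim) sprintf("ps%03d", seq_len(dim))

#' Frequency grid of a power-spectral curve
#'
#' Bin k (1-based) maps to `(k - 1) * fs / nfft` Hz; with the default 5-Hz
#' resampled rate and `nfft = 512` the 257 one-sided bins span 0 to 2.5 Hz.
#'
#' @param dim Number of one-sided bins (usually `nfft / 2 + 1`).
#' @param nfft FFT length used to form the curve.
#' @param fs Sampling rate of the windowed waveform in Hz.
#' @return Numeric vector of `dim` frequencies in Hz.
#' @export
ps_frequencies <- function(dim = 257, nfft = 2 * (dim - 1), fs = 5) {
  (seq_len(dim) - 1) * fs / nfft
}

# extract the PS feature block of a tibble as a plain matrix
ps_feature_matrix <- function(data) {
  cols <- grep("^ps[0-9]+$", names(data), value = TRUE)
  if (length(cols) == 0) abort("`data` has no power-spectral feature columns (ps###).")
  as.matrix(data[cols])
}
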