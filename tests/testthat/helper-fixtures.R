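# In-code fixtures: fast synthetic PS matrices built from Gaussian-bump
# curves (a respiratory peak at rr/60 Hz plus noise), bypassing the signal
# pipeline where a test only needs curve-shaped rows with labels.

bump_curve <- function(rr, dim = 257, width = 0.02, noise_sd = 0.01) {
  freq <- ipsg::ps_frequencies(dim)
  pmax(exp(-(freq - rr / 60)^2 / (2 * width^2)) + rnorm(dim, sd = noise_sd), 0)
}

bump_ps_matrix <- function(rr, dim = 257, noise_sd = 0.01, seed = 1) {
  withr::with_seed(seed, {
    mat <- t(vapply(rr, bump_curve, numeric(dim), dim = dim,
                    noise_sd = noise_sd))
    colnames(mat) <- sprintf("ps%03d", seq_len(dim))
    dplyr::bind_cols(
      tibble::tibble(record_id = sprintf("r%04d", seq_along(rr)),
                     window = 1L, rr = rr, origin = "original"),
      tibble::as_tibble(mat)
    )
  })
}

# a tiny window tibble wrapping explicit sample vectors
make_windows <- function(samples, rr = 15) {
  tibble::tibble(record_id = "rec001", window = seq_along(samples),
                 start_s = 32 * (seq_along(samples) - 1), rr = rr,
                 samples = samples)
}
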