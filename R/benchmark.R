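# Canonical synthetic study designs used by the package's own validation:
# a balanced parameter-recovery benchmark and an imbalanced benchmark whose
# hypopnea scarcity reproduces the clinical imbalance pathology.  Both run
# the full generator -> preprocess -> PS-matrix path and return sequential
# train/test partitions, so they are end-to-end exercises of the pipeline,
# not shortcuts.

#' Balanced RR-recovery benchmark
#'
#' Simulates mixed-modulation records whose reference RRs sweep 6-30 brpm in
#' an interleaved pattern (so the sequential train and test partitions both
#' cover the range), preprocesses them and returns labeled PS matrices.
#' With the defaults (67 records of 96 s, 3 windows each) the design yields
#' about 200 windows; with `noise_sd = 0` the modulation is noiseless and a
#' well-specified regressor should recover RR to a small fraction of a brpm.
#'
#' @param seed Integer seed (drives the RR jitter and any signal noise).
#' @param n_records Number of records.
#' @param duration,fs Record length (s) and sampling rate (Hz).
#' @param depth Modulation depth.
#' @param noise_sd Additive signal noise SD (0 = noiseless).
#' @param label_noise_sd SD of Gaussian noise added to the stored RR labels
#'   (0 = exact labels); used for interval-coverage studies where the label
#'   noise is known.
#' @param train_frac Sequential split fraction.
#' @return A list with `train` and `test` PS tibbles.
#' @export
rr_recovery_benchmark <- function(seed = 1, n_records = 67, duration = 96,
                                  fs = 100, depth = 0.3, noise_sd = 0,
                                  label_noise_sd = 0, train_frac = 0.8) {
  base <- rep(seq(6, 30, length.out = 10), length.out = n_records)
  jit <- with_seed(derive_seed(seed, "rrjit"),
                   runif(n_records, -0.8, 0.8))
  rrs <- pmax(base + jit, 5)
  ds <- simulate_ppg_dataset(rr_dist = rrs, kinds = "mixed",
                             per_kind = n_records, duration = duration,
                             fs = fs, depth = depth, noise_sd = noise_sd,
                             seed = derive_seed(seed, "sim"))
  win <- preprocess_ppg(ds, sqi = FALSE)
  ps <- ps_matrix(win)
  if (label_noise_sd > 0) {
    ps$rr <- ps$rr + with_seed(derive_seed(seed, "labnoise"),
                               rnorm(nrow(ps), sd = label_noise_sd))
  }
  split_sequential(ps, train_frac = train_frac)
}

#' Imbalanced clinical-distribution benchmark
#'
#' The package's standing test bed for the augmentation method: 48 records
#' of which about 80% are normal-range, three hypopnea records sit in the
#' training portion (6.3, 7.1 brpm plus jitter) and a single hypopnea record
#' (6.7 brpm) in the test portion, with a modest dyspnea tail.  Strong
#' additive noise (`noise_sd = 0.6` against a unit-amplitude pulse) and weak
#' modulation (`depth = 0.15`) put the hypopnea respiratory peak near the
#' noise floor, so a regressor trained on the raw imbalance systematically
#' misses the hypopnea windows -- the failure mode the bootstrap
#' augmentation is designed to repair.
#'
#' @inheritParams rr_recovery_benchmark
#' @return A list with `train` and `test` PS tibbles (test = the last 8
#'   records: 1 hypopnea, 5 normal, 2 dyspnea).
#' @export
rr_imbalanced_benchmark <- function(seed = 1, duration = 96, fs = 100,
                                    depth = 0.15, noise_sd = 0.6) {
  rr_train <- c(6.3, seq(12.5, 19.5, length.out = 30), 7.1,
                seq(20.5, 25.5, length.out = 8))
  rr_test <- c(6.7, seq(13, 19, length.out = 5), 21.5, 24)
  rrs <- c(rr_train, rr_test)
  jit <- with_seed(derive_seed(seed, "jit"), runif(length(rrs), -0.3, 0.3))
  ds <- simulate_ppg_dataset(rr_dist = rrs + jit, kinds = "mixed",
                             per_kind = length(rrs), duration = duration,
                             fs = fs, depth = depth, noise_sd = noise_sd,
                             seed = derive_seed(seed, "sim"))
  win <- preprocess_ppg(ds, sqi = FALSE)
  ps <- ps_matrix(win)
  split_sequential(ps, train_frac = 1 - length(rr_test) / length(rrs))
}
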