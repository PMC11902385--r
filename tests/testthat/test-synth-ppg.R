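test_that("record length follows duration and sampling rate", {
  rec <- simulate_ppg(modulation_spec("bw", rr = 15), duration = 210,
                      fs = 500, noise_sd = 0, seed = 1)
  expect_length(rec$signal, 105000)
  expect_equal(rec$rr, 15)
  short <- simulate_ppg(modulation_spec("none"), duration = 3.5, fs = 100,
                        noise_sd = 0)
  expect_length(short$signal, 350)
})

test_that("zero modulation gives a strictly periodic pulse train", {
  rec <- simulate_ppg(modulation_spec("none", hr = 75), duration = 8,
                      fs = 500, noise_sd = 0)
  period <- 500 * 60 / 75  # 400 samples per beat
  x <- rec$signal
  expect_equal(x[seq_len(2000)], x[seq_len(2000) + period], tolerance = 1e-10)
})

test_that("BW modulation puts its energy at the respiratory frequency", {
  # residual of BW record minus unmodulated record is the baseline component
  dur <- 120; fs <- 200
  bw <- simulate_ppg(modulation_spec("bw", rr = 15, depth = 0.4),
                     duration = dur, fs = fs, noise_sd = 0)
  none <- simulate_ppg(modulation_spec("none", rr = 15), duration = dur,
                       fs = fs, noise_sd = 0)
  resid <- bw$signal - none$signal
  spec <- Mod(fft(resid))[seq_len(length(resid) %/% 2)]
  f_peak <- (which.max(spec[-1])) / dur  # skip DC bin
  expect_equal(f_peak, 0.25, tolerance = 1 / dur + 1e-9)
})

test_that("invalid modulation and generator specs error", {
  expect_error(modulation_spec("bw", rr = 80, hr = 75), "below the heart rate")
  expect_error(modulation_spec("bw", depth = 1.5), "0, 1")
  expect_error(simulate_ppg(modulation_spec("bw"), duration = -5), "positive")
  expect_error(simulate_ppg(modulation_spec("none", hr = 75), fs = 2),
               "twice the heart-rate")
})

test_that("dataset generation is deterministic and honors counts", {
  d1 <- simulate_ppg_dataset(per_kind = 3, duration = 40, fs = 50,
                             noise_sd = 0.02, seed = 7)
  d2 <- simulate_ppg_dataset(per_kind = 3, duration = 40, fs = 50,
                             noise_sd = 0.02, seed = 7)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 9)  # 3 kinds x 3
  expect_setequal(unique(d1$modulation), c("bw", "fm", "am"))
  d3 <- simulate_ppg_dataset(per_kind = 3, duration = 40, fs = 50, seed = 8)
  expect_false(identical(d1$signal[[1]], d3$signal[[1]]))
})

test_that("degenerate single-bin distribution pins every reference RR", {
  dist <- rr_distribution(lower = 15, upper = 15.0001, weight = 1)
  d <- simulate_ppg_dataset(rr_dist = dist, kinds = "bw", per_kind = 5,
                            duration = 40, fs = 50, seed = 1)
  expect_equal(d$rr, rep(15, 5), tolerance = 1e-3)
})

test_that("imbalanced distribution proportions match the spec within sampling error", {
  dist <- rr_distribution(lower = c(5, 12, 20), upper = c(8, 20, 30),
                          weight = c(0.1, 0.8, 0.1))
  d <- simulate_ppg_dataset(rr_dist = dist, kinds = "bw", per_kind = 400,
                            duration = 33, fs = 20, depth = 0, noise_sd = 0,
                            seed = 3)
  props <- c(mean(d$rr < 8), mean(d$rr >= 12 & d$rr < 20), mean(d$rr >= 20))
  # 3-sigma binomial tolerance at n = 400
  expect_true(all(abs(props - c(0.1, 0.8, 0.1)) <
                    3 * sqrt(c(0.1, 0.8, 0.1) * c(0.9, 0.2, 0.9) / 400)))
})

test_that("reference RR is recoverable from each modulation kind (noiseless)", {
  dur <- 120; fs <- 100
  for (kind in c("bw", "am", "fm")) {
    rec <- simulate_ppg(modulation_spec(kind, rr = 15, depth = 0.25),
                        duration = dur, fs = fs, noise_sd = 0)
    f_est <- switch(kind,
      bw = {
        # brute-force periodogram peak below the cardiac line
        spec <- Mod(fft(rec$signal - mean(rec$signal)))
        f <- (seq_along(spec) - 1) / dur
        band <- f > 0.05 & f < 1
        f[band][which.max(spec[band])]
      },
      am = {
        # periodogram of the interpolated beat-peak amplitude envelope
        b <- detect_beats(rec$signal, fs = fs)
        env <- approx(b$peak / fs, b$amplitude,
                      xout = seq(0, dur - 1, by = 0.25), rule = 2)$y
        spec <- Mod(fft(env - mean(env)))
        f <- (seq_along(spec) - 1) / (length(env) * 0.25)
        band <- f > 0.05 & f < 1
        f[band][which.max(spec[band])]
      },
      fm = {
        # periodogram of the inter-beat interval series
        b <- detect_beats(rec$signal, fs = fs)
        ibi <- diff(b$peak) / fs
        tt <- b$peak[-1] / fs
        env <- approx(tt, ibi, xout = seq(2, dur - 2, by = 0.25), rule = 2)$y
        spec <- Mod(fft(env - mean(env)))
        f <- (seq_along(spec) - 1) / (length(env) * 0.25)
        band <- f > 0.05 & f < 1
        f[band][which.max(spec[band])]
      })
    expect_equal(f_est, 15 / 60, tolerance = 1 / dur + 1e-9,
                 label = sprintf("estimated resp. frequency (%s)", kind))
  }
})

test_that("BW and AM act on disjoint signal aspects", {
  dur <- 120; fs <- 100
  f_resp <- 0.25
  energy_at <- function(x, f, dur) {
    spec <- Mod(fft(x - mean(x)))
    k <- round(f * dur) + 1
    max(spec[(k - 1):(k + 1)])
  }
  bw <- simulate_ppg(modulation_spec("bw", rr = 15, depth = 0.4),
                     duration = dur, fs = fs, noise_sd = 0)
  w_bw <- resample_5hz(bw$signal, fs = fs)
  # a baseline filter with its cutoff above the respiratory frequency
  # removes BW modulation energy almost entirely
  detr <- remove_baseline(w_bw, cutoff = 0.5, transition = 0.2)
  expect_lt(energy_at(detr, f_resp, dur), 0.05 * energy_at(w_bw, f_resp, dur))
  # ...but leaves the AM envelope intact (it lives on the cardiac line)
  am <- simulate_ppg(modulation_spec("am", rr = 15, depth = 0.4),
                     duration = dur, fs = fs, noise_sd = 0)
  detr_am <- remove_baseline(resample_5hz(am$signal, fs = fs),
                             cutoff = 0.5, transition = 0.2)
  b <- detect_beats(am$signal, fs = fs)
  env0 <- b$amplitude
  expect_gt(sd(env0) / mean(env0), 0.2)  # envelope modulation present
  # envelope depth on the detrended 5-Hz waveform is preserved
  w_env <- approx((seq_along(detr_am) - 1) / 5, detr_am,
                  xout = b$peak / fs, rule = 2)$y
  expect_gt(sd(w_env), 0.1 * mean(env0))
})

test_that("record files round-trip through the columnar-text format", {
  rec <- simulate_ppg(modulation_spec("am", rr = 12), duration = 10, fs = 50,
                      noise_sd = 0.01, seed = 2, record_id = "demo")
  path <- withr::local_tempfile(fileext = ".csv")
  write_ppg_record(rec, path)
  back <- read_ppg_record(path)
  expect_equal(back$signal, rec$signal, tolerance = 1e-6)
  expect_equal(back$rr, rec$rr)
  expect_equal(back$modulation, "am")
})
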