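test_that("classical band matches the hand-computed 3-row toy case", {
  band <- ps_classical_band(matrix(c(1, 2, 3), ncol = 1), alpha = 0.05)
  expect_equal(band$mean, 2)
  expect_equal(band$se, 1 / sqrt(3), tolerance = 1e-12)  # sd 1, n 3
  expect_equal(attr(band, "ct"), 4.302653, tolerance = 1e-6)
  expect_equal(attr(band, "df"), 2)
  expect_equal(band$lower, 2 - 4.302653 * 0.5773503, tolerance = 1e-6)
  expect_equal(band$upper, 2 + 4.302653 * 0.5773503, tolerance = 1e-6)
  expect_error(ps_classical_band(matrix(1, 1, 3)), "At least 2")
})

test_that("identical rows give a zero-width classical band", {
  P <- matrix(5, 10, 7)
  band <- ps_classical_band(P)
  expect_equal(band$sd, rep(0, 7))
  expect_equal(band$lower, band$mean)
  expect_equal(band$upper, band$mean)
})

test_that("classical bands nest across significance levels", {
  ps <- bump_ps_matrix(runif(20, 10, 20), dim = 50, seed = 8)
  b05 <- ps_classical_band(ps, alpha = 0.05)
  b01 <- ps_classical_band(ps, alpha = 0.01)
  expect_true(all(b01$lower <= b05$lower + 1e-12))
  expect_true(all(b01$upper >= b05$upper - 1e-12))
})

test_that("bootstrap resampling is seed-reproducible and well-defined", {
  ps <- bump_ps_matrix(c(10, 12, 14, 16, 18), dim = 20, seed = 2)
  r1 <- ps_bootstrap_resample(ps, seed = 99)
  r2 <- ps_bootstrap_resample(ps, seed = 99)
  expect_identical(r1, r2)
  # independent reimplementation of the same draw
  idx <- withr::with_seed(99, sample.int(5, 5, replace = TRUE))
  expect_identical(r1$record_id, ps$record_id[idx])
  # n = 1 resample is the input itself
  expect_identical(ps_bootstrap_resample(ps[3, ], seed = 1), ps[3, ])
})

test_that("expected fraction of rows absent from a resample matches (1-1/n)^n", {
  n <- 5
  fracs <- vapply(seq_len(10000), function(i) {
    idx <- withr::with_seed(i, sample.int(n, n, replace = TRUE))
    1 - length(unique(idx)) / n
  }, numeric(1))
  expect_equal(mean(fracs), (1 - 1 / n)^n, tolerance = 0.01)
})

test_that("bootstrap means of identical rows are degenerate", {
  ps <- bump_ps_matrix(rep(15, 6), dim = 30, noise_sd = 0, seed = 1)
  band <- ps_bootstrap_band(ps, B = 20, seed = 4)
  expect_equal(unname(band$bias), rep(0, 30), tolerance = 1e-12)
  expect_equal(unname(band$ps_star), rep(0, 30), tolerance = 1e-12)
  expect_equal(band$t_stats, rep(0, 20))
  expect_equal(band$c_star, 0)
  expect_equal(band$boot_lower, band$grand_mean)
})

test_that("bias obeys the CLT bound at B = 100 over 20 seeds", {
  ps <- bump_ps_matrix(runif(50, 8, 25), dim = 60, seed = 7)
  ok <- vapply(1:20, function(s) {
    band <- ps_bootstrap_band(ps, B = 100, seed = s)
    max(abs(band$bias)) <= 3 * max(band$ps_star) / sqrt(band$B)
  }, logical(1))
  expect_true(all(ok))
})

test_that("sup-t containment fraction equals its percentile definition within 1/B", {
  ps <- bump_ps_matrix(runif(50, 8, 25), dim = 60, seed = 3)
  band <- ps_bootstrap_band(ps, B = 100, alpha = 0.05, seed = 11)
  frac_t <- mean(band$t_stats <= band$c_star)
  expect_lte(abs(frac_t - 0.975), 1 / band$B)
  # replicate-mean curves entirely inside the sup-t band
  inside <- vapply(seq_len(band$B), function(i) {
    all(band$rep_means[i, ] >= band$boot_lower - 1e-12 &
          band$rep_means[i, ] <= band$boot_upper + 1e-12)
  }, logical(1))
  expect_lte(abs(mean(inside) - 0.975), 1 / band$B)
  # band is simultaneous around the grand mean
  expect_true(all(band$boot_lower <= band$grand_mean))
  expect_true(all(band$boot_upper >= band$grand_mean))
})

test_that("zero-variance bins are excluded from the sup with a warning", {
  ps <- bump_ps_matrix(runif(10, 10, 20), dim = 20, seed = 5)
  cols <- grep("^ps", names(ps))
  ps[[cols[1]]] <- 7  # constant bin
  expect_warning(band <- ps_bootstrap_band(ps, B = 30, seed = 1),
                 "zero-variance bins")
  expect_true(all(is.finite(band$t_stats)))
})

test_that("subgroup binning assigns labels to half-open intervals", {
  sub <- rr_subgroups(lower = c(-Inf, 8, 22, 24), upper = c(8, 10, 24, 26))
  idx <- suppressWarnings(bin_subgroups(c(6, 9, 15, 24), sub))
  expect_equal(idx, list(1L, 2L, integer(0), 4L), ignore_attr = TRUE)
  # empty label set: all subgroups empty, no warning
  expect_no_warning(idx0 <- bin_subgroups(numeric(0), sub))
  expect_true(all(lengths(idx0) == 0))
  # overlapping intervals rejected
  expect_error(rr_subgroups(lower = c(8, 9), upper = c(10, 11)), "overlap")
})

test_that("artificial curves are replicate means with the subgroup-mean label", {
  ps <- bump_ps_matrix(c(6.5, 7.1, 7.8), dim = 25, seed = 6)
  art <- ipsg_generate(ps, B = 40, seed = 2)
  expect_equal(nrow(art), 40)
  expect_true(all(art$origin == "artificial"))
  expect_equal(unique(art$rr), mean(ps$rr))
  # convex hull per bin: artificial values between column min and max
  P <- as.matrix(ps[grep("^ps", names(ps))])
  A <- as.matrix(art[grep("^ps", names(art))])
  expect_true(all(sweep(A, 2, apply(P, 2, min), ">=") |
                    abs(sweep(A, 2, apply(P, 2, min))) < 1e-12))
  expect_true(all(sweep(A, 2, apply(P, 2, max), "<=") |
                    abs(sweep(A, 2, apply(P, 2, max))) < 1e-12))
  # replicate-mean labels vary when requested
  art2 <- ipsg_generate(ps, B = 40, seed = 2, label = "replicate_mean")
  expect_gt(sd(art2$rr), 0)
  # degenerate subgroup of identical rows reproduces that row
  ps_same <- bump_ps_matrix(rep(7, 4), dim = 25, noise_sd = 0, seed = 1)
  art3 <- ipsg_generate(ps_same, B = 5, seed = 3)
  expect_equal(as.numeric(as.matrix(art3[grep("^ps", names(art3))])[1, ]),
               as.numeric(as.matrix(ps_same[grep("^ps", names(ps_same))])[1, ]))
  # B = 0 and empty-subgroup contracts
  expect_equal(nrow(ipsg_generate(ps, B = 0)), 0)
  expect_error(ipsg_generate(ps[0, ], B = 10), "empty subgroup")
})

test_that("fusion preserves originals and validates columns", {
  ps <- bump_ps_matrix(c(6, 7, 15, 16, 23), dim = 30, seed = 9)
  art <- ipsg_generate(ps[1:2, ], B = 10, seed = 1)
  fused <- fuse_ps(ps, art)
  expect_equal(nrow(fused), 15)
  expect_identical(fused[fused$origin == "original", ], ps)
  # identity when no artificial rows
  expect_identical(fuse_ps(ps, art[0, ]), ps)
  # column mismatch errors
  art_bad <- ipsg_generate(bump_ps_matrix(c(6, 7), dim = 20, seed = 1), B = 3)
  expect_error(fuse_ps(ps, art_bad), "mismatch")
  # shuffling permutes rows deterministically per seed
  f1 <- fuse_ps(ps, art, shuffle = TRUE, seed = 5)
  f2 <- fuse_ps(ps, art, shuffle = TRUE, seed = 5)
  expect_identical(f1, f2)
  expect_setequal(f1$record_id, fused$record_id)
})

test_that("end-to-end augmentation books the stated artificial counts", {
  # 636 rows covering all six default subgroups
  rr <- rep(c(6.5, 8.7, 10.5, 14, 16, 18, 22.3, 24.2, 26), length.out = 636)
  ps <- bump_ps_matrix(rr, dim = 40, seed = 10)
  fused <- ipsg_augment(ps, rr_subgroups(), seed = 3)
  expect_equal(sum(fused$origin == "artificial"), 600)
  expect_equal(nrow(fused), 1236)
  # restricted to originals the fusion is bit-identical to the input
  expect_identical(fused[fused$origin == "original", ], ps)
  # the 1152-row design gains the same 600 artificial rows
  rr2 <- rep(c(6.5, 8.7, 10.5, 14, 16, 18, 22.3, 24.2, 26),
             length.out = 1152)
  fused2 <- ipsg_augment(bump_ps_matrix(rr2, dim = 40, seed = 11),
                         rr_subgroups(), seed = 3)
  expect_equal(nrow(fused2), 1752)
  # per-subgroup caps subsample the inputs without changing output counts
  capped <- ipsg_augment(ps, rr_subgroups(n_max = 20), seed = 3)
  expect_equal(nrow(capped), 1236)
})
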