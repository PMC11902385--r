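test_that("sequential splits follow the floored-test-count arithmetic", {
  ps <- bump_ps_matrix(runif(636, 6, 30), dim = 10, seed = 1)
  sp <- split_sequential(ps, 0.8)
  expect_equal(nrow(sp$train), 509)
  expect_equal(nrow(sp$test), 127)
  sp2 <- split_sequential(ps, 0.7)
  expect_equal(nrow(sp2$test), floor(0.3 * 636))
  expect_error(split_sequential(ps, 1.0), "between 0 and 1")
  # artificial rows stay in training by default
  fused <- fuse_ps(ps, ipsg_generate(ps[1:5, ], B = 8, seed = 1))
  sp3 <- split_sequential(fused, 0.8)
  expect_equal(sum(sp3$train$origin == "artificial"), 8)
  expect_equal(sum(sp3$test$origin == "artificial"), 0)
  expect_identical(sp3$test, sp$test)
})

test_that("GPR recovers a linear synthetic map with small error", {
  withr::with_seed(31, {
    n <- 200
    X <- matrix(runif(n * 20, 0, 5), n, 20)
    colnames(X) <- sprintf("ps%03d", 1:20)
    y <- X[, 1] + rnorm(n, sd = 0.1)
  })
  d <- dplyr::bind_cols(tibble::tibble(rr = y, origin = "original"),
                        tibble::as_tibble(X))
  sp <- split_sequential(d, 0.8)
  fit <- rr_fit(sp$train, "gpr", seed = 1)
  expect_equal(fit$fit$kernel, "squaredexponential")  # default kernel
  mae <- rr_metrics(predict(fit, sp$test))$mae
  expect_lt(mae, 0.2)
})

test_that("fits are deterministic and predictions permutation-equivariant", {
  ps <- bump_ps_matrix(runif(60, 8, 25), dim = 30, seed = 12)
  for (m in c("gpr", "rf", "gba", "lstm")) {
    f1 <- rr_fit(ps, m, seed = 7)
    f2 <- rr_fit(ps, m, seed = 7)
    expect_equal(predict(f1, ps)$.pred, predict(f2, ps)$.pred,
                 tolerance = 1e-12, label = sprintf("%s determinism", m))
  }
  fit <- rr_fit(ps, "gpr", seed = 7)
  perm <- sample(nrow(ps))
  expect_equal(predict(fit, ps[perm, ])$.pred, predict(fit, ps)$.pred[perm])
})

test_that("all six model kinds satisfy the shared predict contract", {
  ps <- bump_ps_matrix(runif(60, 8, 25), dim = 30, seed = 13)
  fused <- suppressWarnings(ipsg_augment(ps, rr_subgroups(b = 10), seed = 1))
  for (m in c("gpr", "svm", "nn", "gba", "rf", "lstm")) {
    extra <- if (m == "lstm") list(hidden = 8, epochs = 5) else list()
    fit <- do.call(rr_fit, c(list(data = fused, model = m, seed = 3), extra))
    pr <- predict(fit, ps)
    expect_equal(nrow(pr), nrow(ps))
    expect_true(all(is.finite(pr$.pred)), label = sprintf("%s finite", m))
  }
  # dimension mismatch is rejected
  fit <- rr_fit(fused, "gpr", seed = 3)
  expect_error(predict(fit, bump_ps_matrix(c(10, 12), dim = 20, seed = 1)),
               "mismatch")
})

test_that("five-fold CV tuning picks from the documented grid", {
  ps <- bump_ps_matrix(runif(50, 8, 25), dim = 20, seed = 14)
  fit <- rr_fit(ps, "rf", tune = TRUE, seed = 2)
  expect_s3_class(fit$cv, "tbl_df")
  expect_equal(nrow(fit$cv), 2)          # num_trees in {30, 100}
  expect_true(all(is.finite(fit$cv$cv_mae)))
  expect_true(fit$params$num_trees %in% c(30, 100))
  expect_equal(fit$params$num_trees,
               fit$cv$num_trees[which.min(fit$cv$cv_mae)])
})

test_that("training on a duplicated single row interpolates its label", {
  one <- bump_ps_matrix(rep(12, 8), dim = 15, noise_sd = 0, seed = 1)
  expect_warning(fit <- rr_fit(one, "gpr", seed = 1), "Degenerate labels")
  pr <- suppressWarnings(predict(fit, one[1, ]))
  expect_equal(pr$.pred, 12, tolerance = 1e-6)
})

test_that("GPR predictive intervals behave like Gaussian intervals", {
  # full-resolution curves: the bump is resolved by the frequency grid, so
  # the label map is smooth and the fitted noise is small
  ps <- bump_ps_matrix(runif(80, 8, 25), dim = 257, noise_sd = 0.001,
                       seed = 15)
  fit <- rr_fit(ps, "gpr", seed = 1)
  pr95 <- predict(fit, ps, interval = TRUE, level = 0.95)
  expect_true(all(pr95$.lower <= pr95$.pred & pr95$.pred <= pr95$.upper))
  # near-noiseless training point: narrow interval at that point
  expect_lt(mean(pr95$.upper - pr95$.lower), 1)
  # widening: 99% intervals contain 95% intervals
  pr99 <- predict(fit, ps, interval = TRUE, level = 0.99)
  expect_true(all(pr99$.lower <= pr95$.lower + 1e-12))
  expect_true(all(pr99$.upper >= pr95$.upper - 1e-12))
  # non-GPR models refuse interval prediction
  rf <- rr_fit(ps, "rf", seed = 1)
  expect_error(predict(rf, ps, interval = TRUE), "GPR")
})

test_that("in-package GPR agrees with an independent GP implementation", {
  skip_if_not_installed("kernlab")
  withr::with_seed(41, {
    n <- 80
    X <- matrix(runif(n * 5), n, 5)
    y <- sin(3 * X[, 1]) + 0.5 * X[, 2] + rnorm(n, sd = 0.05)
  })
  # pin shared hyperparameters on both sides: SE kernel, unit signal SD
  ell <- 0.8; sn <- 0.1
  fit <- ipsg:::gpr_fit(X, y, kernel = "squaredexponential", optimize = FALSE)
  fit$ell <- ell; fit$sf <- 1; fit$sn <- sn
  fit$ybar <- 0  # kernlab regresses on the uncentered response
  K <- ipsg:::gpr_kfun("squaredexponential", ipsg:::gpr_dist(X), ell)
  diag(K) <- diag(K) + sn^2
  fit$chol <- chol(K)
  fit$alpha <- backsolve(fit$chol, forwardsolve(t(fit$chol), y))
  mine <- ipsg:::gpr_predict(fit, X)$mean
  ref <- kernlab::gausspr(X, y, kernel = "rbfdot",
                          kpar = list(sigma = 1 / (2 * ell^2)),
                          var = sn^2, scaled = FALSE)
  theirs <- as.numeric(kernlab::predict(ref, X))
  expect_equal(mine, theirs, tolerance = 1e-4)
})

test_that("GPR is robust across its five kernels on the synthetic benchmark", {
  kernels <- c("squaredexponential", "exponential", "matern32", "matern52",
               "rationalquadratic")
  maes <- matrix(NA_real_, 3, length(kernels),
                 dimnames = list(NULL, kernels))
  for (s in 1:3) {
    b <- rr_recovery_benchmark(seed = s, noise_sd = 0.4)
    for (k in kernels) {
      fit <- rr_fit(b$train, "gpr", kernel = k, seed = 1)
      maes[s, k] <- rr_metrics(predict(fit, b$test))$mae
    }
  }
  mean_mae <- colMeans(maes)
  expect_lt(max(mean_mae) / min(mean_mae) - 1, 0.5)
})
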