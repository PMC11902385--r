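#' Sequential train/test split of a PS dataset
#'
#' Splits the original rows in their record/window order: the first
#' `train_frac` fraction goes to training, the remainder (count floored) to
#' testing, so training never sees later windows of the test records.
#' Artificial rows, if present, are routed to the training partition by
#' default (evaluating on artificial labels would be circular); set
#' `artificial = "test"` only to reproduce augmented-test bookkeeping.
#'
#' @param data PS tibble (possibly fused, with an `origin` column).
#' @param train_frac Training fraction in (0, 1); 0.8 and 0.7 are the two
#'   standard scenarios.
#' @param artificial Where artificial rows go: `"train"` (default) or
#'   `"test"`.
#' @return A list with `train` and `test` tibbles.
#' @export
#' @examples
#' # 636 original rows at 80/20 -> 509 train / 127 test
split_sequential <- function(data, train_frac = 0.8,
                             artificial = c("train", "test")) {
  artificial <- match.arg(artificial)
  if (train_frac <= 0 || train_frac >= 1) {
    abort("`train_frac` must lie strictly between 0 and 1.")
  }
  if (!"origin" %in% names(data)) data$origin <- "original"
  orig <- data[data$origin == "original", , drop = FALSE]
  art <- data[data$origin != "original", , drop = FALSE]
  n <- nrow(orig)
  n_test <- floor(n * (1 - train_frac))
  n_train <- n - n_test
  if (n_train == 0 || n_test == 0) abort("Split leaves an empty partition.")
  train <- orig[seq_len(n_train), , drop = FALSE]
  test <- orig[seq(n_train + 1, n), , drop = FALSE]
  if (nrow(art) > 0) {
    if (artificial == "train") train <- dplyr::bind_rows(train, art)
    else test <- dplyr::bind_rows(test, art)
  }
  list(train = train, test = test)
}

# documented per-model tuning grids for five-fold CV (kept deliberately small)
default_grid <- function(model) {
  switch(model,
    gpr = tibble::tibble(kernel = gpr_kernels),
    svm = tidyr::expand_grid(cost = c(1, 10), epsilon = c(0.1, 1)),
    nn = tidyr::expand_grid(size = c(5, 10), decay = c(0, 0.1)),
    gba = tibble::tibble(nrounds = c(100, 300)),
    rf = tibble::tibble(num_trees = c(30, 100)),
    lstm = tibble::tibble(hidden = c(8, 16)),
    abort(sprintf("Unknown model kind '%s'.", model))
  )
}

fit_one <- function(model, X, y, params, seed) {
  switch(model,
    gpr = gpr_fit(X, y, kernel = params$kernel %||% "squaredexponential",
                  optimize = params$optimize %||% TRUE,
                  maxit = params$maxit %||% 50),
    svm = e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                     cost = params$cost %||% 1,
                     epsilon = params$epsilon %||% 0.1, scale = FALSE),
    nn = with_seed(seed, nnet::nnet(X, y, size = params$size %||% 10,
                                    decay = params$decay %||% 0,
                                    linout = TRUE, maxit = params$maxit %||% 200,
                                    MaxNWts = 1e5, trace = FALSE)),
    gba = {
      xgboost::xgb.train(
        params = list(eta = params$eta %||% 0.1,
                      max_depth = params$max_depth %||% 6,
                      subsample = params$subsample %||% 1,
                      objective = "reg:squarederror", nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(X, label = y),
        nrounds = params$nrounds %||% 300, verbose = 0)
    },
    rf = ranger::ranger(x = X, y = y, num.trees = params$num_trees %||% 30,
                        max.depth = params$max_depth %||% 8, seed = seed,
                        num.threads = 1),
    lstm = lstm_fit(X, y, hidden = params$hidden %||% 16,
                    pool_len = params$pool_len %||% 32,
                    epochs = params$epochs %||% 40,
                    lr = params$lr %||% 0.01, seed = seed)
  )
}

predict_one <- function(model, fit, X) {
  switch(model,
    gpr = gpr_predict(fit, X)$mean,
    svm = as.numeric(predict(fit, X)),
    nn = as.numeric(predict(fit, X)),
    gba = as.numeric(predict(fit, xgboost::xgb.DMatrix(X))),
    rf = predict(fit, data = as.data.frame(X), num.threads = 1)$predictions,
    lstm = lstm_predict(fit, X)
  )
}

#' Fit a respiratory-rate regressor on power-spectral curves
#'
#' The shared model interface: takes a PS tibble (feature columns `ps###`,
#' label column `rr`), optionally standardizes features (off by default),
#' optionally grid-searches a small documented hyperparameter grid by
#' five-fold cross-validated MAE, and refits on the full data with the
#' winning configuration.  All randomness is controlled by `seed`.
#'
#' @param data PS tibble with `rr` labels.
#' @param model One of `"gpr"` (Gaussian-process regression, the headline
#'   model with predictive intervals), `"svm"`, `"nn"`, `"gba"` (gradient
#'   boosting), `"rf"` (random forest), `"lstm"`.
#' @param tune Run the five-fold CV grid search? (Without tuning, the
#'   model's documented defaults are used; GPR always fits its kernel
#'   hyperparameters by marginal likelihood.)
#' @param folds CV folds (default 5).
#' @param standardize Center/scale the feature columns.
#' @param seed Integer seed.
#' @param ... Model-kind-specific hyperparameters overriding the defaults
#'   (e.g. `kernel = "matern52"` for GPR, `num_trees` for RF).
#' @return An object of class `rr_model`.
#' @export
rr_fit <- function(data, model = c("gpr", "svm", "nn", "gba", "rf", "lstm"),
                   tune = FALSE, folds = 5, standardize = FALSE, seed = 1,
                   ...) {
  model <- match.arg(model)
  if (nrow(data) == 0) abort("Training data is empty.")
  X <- ps_feature_matrix(data)
  y <- data$rr
  if (any(!is.finite(y))) abort("Labels must be finite.")
  if (sd(y) == 0) warn("Degenerate labels (single value); fit proceeds.")
  center <- scale_sd <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale_sd <- pmax(apply(X, 2, sd), 1e-12)
    X <- sweep(sweep(X, 2, center), 2, scale_sd, "/")
  }
  params <- list(...)
  cv <- NULL
  if (tune) {
    grid <- default_grid(model)
    if (nrow(data) < folds) abort("Need at least `folds` rows to tune.")
    fold_id <- with_seed(derive_seed(seed, "cv"),
                         sample(rep_len(seq_len(folds), nrow(X))))
    cv_mae <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
      pg <- utils::modifyList(params, as.list(grid[g, ]))
      mean(purrr::map_dbl(seq_len(folds), function(k) {
        tr <- fold_id != k
        f <- fit_one(model, X[tr, , drop = FALSE], y[tr], pg,
                     derive_seed(seed, "cvfit", g, k))
        mean(abs(predict_one(model, f, X[!tr, , drop = FALSE]) - y[!tr]))
      }))
    })
    best <- which.min(cv_mae)
    params <- utils::modifyList(params, as.list(default_grid(model)[best, ]))
    cv <- dplyr::bind_cols(grid, tibble::tibble(cv_mae = cv_mae))
  }
  fit <- fit_one(model, X, y, params, derive_seed(seed, "fit"))
  structure(list(model = model, fit = fit, params = params, cv = cv,
                 center = center, scale_sd = scale_sd,
                 n_features = ncol(X), seed = seed),
            class = "rr_model")
}

#' @export
print.rr_model <- function(x, ...) {
  cat(sprintf("<rr_model: %s, %d features%s>\n", x$model, x$n_features,
              if (!is.null(x$cv)) ", CV-tuned" else ""))
  invisible(x)
}

#' Predict respiratory rate (with optional GPR intervals)
#'
#' @param object An `rr_model` from [rr_fit()].
#' @param newdata PS tibble (or matrix) whose feature columns match training.
#' @param interval Return predictive interval bounds (GPR only).
#' @param level Interval level (default 0.95).
#' @param ... Unused.
#' @return A tibble with `.pred` and, when available, `rr` (reference),
#'   `.lower`, `.upper`, plus the input provenance columns.
#' @export
predict.rr_model <- function(object, newdata, interval = FALSE, level = 0.95,
                             ...) {
  X <- if (is.matrix(newdata)) newdata else ps_feature_matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("Feature dimension mismatch: model has %d, data has %d.",
                  object$n_features, ncol(X)))
  }
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale_sd, "/")
  }
  out <- tibble::tibble(.pred = predict_one(object$model, object$fit, X))
  if (interval) {
    if (object$model != "gpr") {
      abort("Predictive intervals are available for GPR models only.")
    }
    pr <- gpr_predict(object$fit, X, se = TRUE)
    z <- qnorm(1 - (1 - level) / 2)
    out$.pred <- pr$mean
    out$.lower <- pr$mean - z * pr$sd
    out$.upper <- pr$mean + z * pr$sd
    out$.level <- level
  }
  if (!is.matrix(newdata)) {
    keep <- intersect(c("record_id", "window", "rr", "origin"), names(newdata))
    out <- dplyr::bind_cols(newdata[keep], out)
  }
  out
}
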