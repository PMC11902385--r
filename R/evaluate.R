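#' Point-estimate error metrics
#'
#' MAE, RMSE and the coefficient of determination
#' `R2 = 1 - SSE/SST` of predictions against reference labels.
#'
#' @param data Tibble with prediction and reference columns (e.g. the output
#'   of [predict.rr_model()]).
#' @param truth,estimate Column names of the reference and the prediction.
#' @return One-row tibble with `mae`, `rmse`, `r2`, `n`.
#' @export
#' @examples
#' rr_metrics(tibble::tibble(rr = c(1, 2, 3), .pred = c(2, 0, 6)))
rr_metrics <- function(data, truth = "rr", estimate = ".pred") {
  y <- data[[truth]]
  p <- data[[estimate]]
  if (length(y) != length(p)) abort("Reference and prediction lengths differ.")
  e <- p - y
  r2 <- if (length(y) >= 2 && var(y) > 0) {
    1 - sum(e^2) / sum((y - mean(y))^2)
  } else {
    if (length(y) >= 2) abort("R2 undefined: zero-variance reference.")
    NA_real_
  }
  tibble::tibble(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), r2 = r2,
                 n = length(y))
}

#' Clinical respiratory-rate bins
#'
#' Hypopnea below 8 brpm, normal 12 to 20 brpm, dyspnea 20 brpm and above
#' (20 itself counts as dyspnea); rates in \[8, 12) belong to no clinical bin
#' and are excluded from subgroup summaries.
#'
#' @return An [rr_subgroups()]-shaped tibble with a `subgroup` name column.
#' @export
clinical_bins <- function() {
  tibble::tibble(subgroup = c("hypopnea", "normal", "dyspnea"),
                 lower = c(-Inf, 12, 20), upper = c(8, 20, Inf))
}

#' Per-subgroup mean absolute error
#'
#' @param data Prediction tibble with reference and prediction columns.
#' @param bins A tibble of named bins (default [clinical_bins()]).
#' @inheritParams rr_metrics
#' @return A tibble with one row per non-empty bin: `subgroup`, `mae`, `n`.
#' @export
subgroup_mae <- function(data, bins = clinical_bins(), truth = "rr",
                         estimate = ".pred") {
  y <- data[[truth]]
  e <- abs(data[[estimate]] - y)
  purrr::map(seq_len(nrow(bins)), function(i) {
    sel <- y >= bins$lower[i] & y < bins$upper[i]
    if (!any(sel)) return(NULL)
    tibble::tibble(subgroup = bins$subgroup[i], mae = mean(e[sel]),
                   n = sum(sel))
  }) |> purrr::compact() |> purrr::list_rbind()
}

#' Bland-Altman agreement statistics
#'
#' Mean error (prediction minus reference) and agreement limits
#' `ME -/+ k * SD` of the differences (sample SD, n - 1 denominator).
#' The limit multiplier defaults to 2; 1.96 is selectable.
#'
#' @inheritParams rr_metrics
#' @param k Limit multiplier.
#' @return One-row tibble: `me`, `sd`, `lower`, `upper`, `k`, `n`,
#'   `frac_within` (fraction of differences inside the limits).
#' @export
bland_altman <- function(data, truth = "rr", estimate = ".pred", k = 2) {
  d <- data[[estimate]] - data[[truth]]
  if (length(d) < 2) abort("Bland-Altman needs at least 2 points.")
  me <- mean(d)
  s <- sd(d)
  tibble::tibble(me = me, sd = s, lower = me - k * s, upper = me + k * s,
                 k = k, n = length(d),
                 frac_within = mean(d >= me - k * s & d <= me + k * s))
}

#' One-way ANOVA across model metric groups
#'
#' Fits `metric ~ group` with [stats::aov()] and reshapes the result into
#' the conventional Group / Error / Total table (SS, df, MS, F, p).  With
#' six models and 30 repetitions the dfs are 5 / 174 / 179.
#'
#' @param data Long tibble of per-repetition metrics.
#' @param value,group Column names of the metric and the grouping factor.
#' @return A tibble with rows `Group`, `Error`, `Total`.
#' @export
anova_oneway <- function(data, value = "mae", group = "model") {
  g <- factor(data[[group]])
  v <- data[[value]]
  if (nlevels(g) < 2) abort("ANOVA needs at least 2 groups.")
  if (any(table(g) < 2)) abort("ANOVA needs at least 2 values per group.")
  if (max(tapply(v, g, var)) == 0) {
    warn("Zero within-group variance; p reported as 0.")
    mu <- tapply(v, g, mean)
    ss_g <- sum(table(g) * (mu - mean(v))^2)
    df_g <- nlevels(g) - 1
    df_e <- length(v) - nlevels(g)
    return(tibble::tibble(
      source = c("Group", "Error", "Total"),
      ss = c(ss_g, 0, ss_g),
      df = c(df_g, df_e, df_g + df_e),
      ms = c(ss_g / df_g, 0, NA_real_),
      f = c(Inf, NA_real_, NA_real_),
      p = c(0, NA_real_, NA_real_)
    ))
  }
  fit <- aov(v ~ g)
  sm <- summary(fit)[[1]]
  ss_g <- sm[1, "Sum Sq"]; df_g <- sm[1, "Df"]
  ss_e <- sm[2, "Sum Sq"]; df_e <- sm[2, "Df"]
  f <- sm[1, "F value"]; p <- sm[1, "Pr(>F)"]
  if (!is.finite(f)) {
    warn("Zero within-group variance; p reported as 0.")
    f <- Inf; p <- 0
  }
  tibble::tibble(
    source = c("Group", "Error", "Total"),
    ss = c(ss_g, ss_e, ss_g + ss_e),
    df = c(df_g, df_e, df_g + df_e),
    ms = c(ss_g / df_g, ss_e / df_e, NA_real_),
    f = c(f, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_)
  )
}

#' Summary of predictive confidence intervals
#'
#' Test-set means and SDs of the point estimate, the interval bounds and the
#' interval width (upper minus lower).
#'
#' @param pred Prediction tibble with `.pred`, `.lower`, `.upper`.
#' @return A four-row tibble (`quantity` in rr / ci_lower / ci_upper /
#'   ci_width) with `mean` and `sd`.
#' @export
ci_summary <- function(pred) {
  if (!all(c(".lower", ".upper") %in% names(pred))) {
    abort("`pred` must carry interval bounds (.lower/.upper).")
  }
  w <- pred$.upper - pred$.lower
  tibble::tibble(
    quantity = c("rr", "ci_lower", "ci_upper", "ci_width"),
    mean = c(mean(pred$.pred), mean(pred$.lower), mean(pred$.upper), mean(w)),
    sd = c(sd(pred$.pred), sd(pred$.lower), sd(pred$.upper), sd(w))
  )
}

#' Relative performance improvement between two error values
#'
#' The reporting convention divides the difference by the smaller (better)
#' model's error: `(worse - better) / better * 100` percent.  This is
#' nonstandard (the denominator is the improved value, not the baseline) but
#' is the convention this package's reports follow.
#'
#' @param baseline,improved Error values (e.g. RMSE in brpm).
#' @return Percentage improvement.
#' @export
improvement_pct <- function(baseline, improved) {
  (baseline - improved) / improved * 100
}

#' Repeated evaluation study over models, with and without augmentation
#'
#' The full evaluation protocol: for each repetition the original rows are
#' split sequentially, the training partition is bootstrap-augmented (IPSG),
#' and every requested model kind is fitted twice -- on the plain and on the
#' augmented training set -- and scored on the fixed test partition.
#' Repetitions vary the augmentation and model seeds; the split stays fixed.
#'
#' @param ps Original PS tibble.
#' @param models Model kinds to run.
#' @param repetitions Number of repetitions (30 in the standard protocol).
#' @param subgroups [rr_subgroups()] spec for the augmentation.
#' @param train_frac Sequential split fraction.
#' @param ipsg Run the augmented variant, the plain variant, or both.
#' @param seed Top-level seed.
#' @param model_args Named list of per-model argument lists passed to
#'   [rr_fit()].
#' @return A tibble with one row per repetition x model x variant:
#'   metrics, clinical subgroup MAEs and Bland-Altman columns.
#' @export
rr_study <- function(ps, models = "gpr", repetitions = 30,
                     subgroups = rr_subgroups(), train_frac = 0.8,
                     ipsg = c("both", "with", "without"), seed = 1,
                     model_args = list()) {
  ipsg <- match.arg(ipsg)
  if (repetitions < 1) abort("`repetitions` must be >= 1.")
  variants <- switch(ipsg, both = c(FALSE, TRUE), with = TRUE, without = FALSE)
  parts <- split_sequential(ps, train_frac = train_frac)
  purrr::map(seq_len(repetitions), function(rep_i) {
    purrr::map(models, function(mod) {
      purrr::map(variants, function(aug) {
        train <- if (aug) {
          ipsg_augment(parts$train, subgroups = subgroups,
                       seed = derive_seed(seed, "augment", rep_i))
        } else parts$train
        args <- c(list(data = train, model = mod,
                       seed = derive_seed(seed, "model", rep_i)),
                  model_args[[mod]] %||% list())
        fit <- do.call(rr_fit, args)
        pred <- predict(fit, parts$test)
        met <- rr_metrics(pred)
        sub <- subgroup_mae(pred)
        ba <- bland_altman(pred)
        wide_sub <- setNames(as.list(sub$mae), paste0("mae_", sub$subgroup))
        dplyr::bind_cols(
          tibble::tibble(rep = rep_i, model = mod, ipsg = aug),
          met,
          tibble::as_tibble(wide_sub),
          tibble::tibble(ba_me = ba$me, ba_sd = ba$sd)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Aggregate a repeated study into mean-and-SD summaries
#'
#' @param study Output of [rr_study()].
#' @return A tibble with one row per model x variant and mean/SD columns for
#'   each metric.
#' @export
summarize_study <- function(study) {
  study |>
    dplyr::group_by(.data$model, .data$ipsg) |>
    dplyr::summarize(dplyr::across(
      dplyr::where(is.numeric) & !dplyr::any_of(c("rep", "n")),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop")
}
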