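#' Pointwise classical-t confidence band for a PS matrix
#'
#' For each frequency bin: sample mean, sample SD (n - 1 denominator),
#' standard error SD/sqrt(n), and the two-sided Student-t band
#' `mean -/+ t_{1-alpha/2, n-1} * se`.
#'
#' @param ps A PS tibble (feature columns `ps###`) or a plain numeric matrix
#'   with curves as rows.
#' @param alpha Significance level (default 0.05 for a 95% band).
#' @return An object of class `ps_ciband`: a tibble with one row per bin
#'   (`bin`, `freq`, `mean`, `sd`, `se`, `lower`, `upper`) and attributes
#'   `n`, `df`, `ct`, `alpha`.
#' @export
#' @examples
#' band <- ps_classical_band(matrix(c(1, 2, 3), ncol = 1))
#' attr(band, "ct")  # 4.303 (t at 0.975, df = 2)
ps_classical_band <- function(ps, alpha = 0.05) {
  P <- if (is.matrix(ps)) ps else ps_feature_matrix(ps)
  n <- nrow(P)
  if (n < 2) abort("At least 2 curves are required for a confidence band.")
  p_mu <- colMeans(P)
  p_sd <- apply(P, 2, sd)
  p_se <- p_sd / sqrt(n)
  df <- n - 1
  ct <- qt(1 - alpha / 2, df)
  out <- tibble::tibble(
    bin = seq_along(p_mu),
    freq = ps_frequencies(length(p_mu)),
    mean = p_mu, sd = p_sd, se = p_se,
    lower = p_mu - ct * p_se,
    upper = p_mu + ct * p_se
  )
  structure(out, class = c("ps_ciband", class(out)),
            n = n, df = df, ct = ct, alpha = alpha)
}

#' One nonparametric bootstrap resample of a PS matrix
#'
#' Draws n rows uniformly with replacement from the n rows of `ps`;
#' deterministic for a fixed seed.
#'
#' @param ps PS tibble or numeric matrix.
#' @param seed Integer seed.
#' @return An object of the same type as `ps` with resampled rows.
#' @export
ps_bootstrap_resample <- function(ps, seed = NULL) {
  n <- nrow(ps)
  if (is.null(n) || n < 1) abort("`ps` must have at least one row.")
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  ps[idx, , drop = FALSE]
}

#' Bootstrap replicate means and sup-t simultaneous band
#'
#' The core resampling engine: draws `B` bootstrap resamples of the curve
#' matrix, records each replicate mean curve `p_mu*(i)` (these are the
#' artificial curves of the augmentation scheme), and forms
#' \itemize{
#'   \item the grand bootstrap mean `p_mu* = mean_i p_mu*(i)` and the bias
#'     `p_mu - p_mu*` against the sample mean,
#'   \item the pointwise SD of the replicate means `ps*` (B - 1 denominator),
#'   \item the sup-t statistics `t(i) = max_bins |p_mu*(i) - p_mu| / ps*`,
#'     their empirical `100 (1 - alpha/2)` percentile `c*`, and the
#'     simultaneous band `p_mu* -/+ c* ps*`.
#' }
#' Frequency bins with zero replicate-mean variance are excluded from the sup
#' (with a warning) rather than dividing by zero; an all-zero `ps*` (all
#' resamples identical) yields a degenerate zero-width band with `c* = 0`.
#'
#' @param ps PS tibble or numeric matrix (curves as rows).
#' @param B Number of bootstrap resamples (default 100).
#' @param alpha Significance level.
#' @param seed Integer seed; replicate i uses the derived seed
#'   `derive_seed(seed, "boot", i)`.
#' @return An object of class `ipsg_band`: a list with `freq`, `p_mu`,
#'   `p_sd`, `p_se`, `df`, `ct`, `ci_lower`/`ci_upper` (classical band),
#'   `rep_means` (B x c matrix), `grand_mean`, `ps_star`, `bias`, `t_stats`,
#'   `c_star`, `boot_lower`/`boot_upper` (sup-t band), `B`, `alpha`, `n`.
#' @export
ps_bootstrap_band <- function(ps, B = 100, alpha = 0.05, seed = 1) {
  if (B < 1) abort("`B` must be >= 1.")
  P <- if (is.matrix(ps)) ps else ps_feature_matrix(ps)
  n <- nrow(P)
  if (n < 1) abort("`ps` must have at least one row.")
  classical <- if (n >= 2) ps_classical_band(P, alpha = alpha) else NULL
  p_mu <- colMeans(P)

  rep_means <- matrix(NA_real_, B, ncol(P))
  for (i in seq_len(B)) {
    idx <- with_seed(derive_seed(seed, "boot", i),
                     sample.int(n, n, replace = TRUE))
    rep_means[i, ] <- colMeans(P[idx, , drop = FALSE])
  }
  grand_mean <- colMeans(rep_means)
  ps_star <- apply(rep_means, 2, sd)
  if (B == 1) ps_star <- rep(0, ncol(P))
  bias <- p_mu - grand_mean

  ok <- ps_star > 0
  if (!any(ok)) {
    if (any(abs(sweep(rep_means, 2, p_mu)) > 1e-12)) {
      abort("Degenerate band: zero bootstrap variance at every bin.")
    }
    t_stats <- rep(0, B)
  } else {
    if (!all(ok)) {
      warn(sprintf("%d zero-variance bins excluded from the sup-t statistic.",
                   sum(!ok)))
    }
    dev <- abs(sweep(rep_means[, ok, drop = FALSE], 2, p_mu[ok]))
    t_stats <- apply(sweep(dev, 2, ps_star[ok], "/"), 1, max)
  }
  c_star <- as.numeric(quantile(t_stats, 1 - alpha / 2, type = 7))

  structure(list(
    freq = ps_frequencies(ncol(P)),
    p_mu = p_mu,
    p_sd = if (is.null(classical)) rep(NA_real_, ncol(P)) else classical$sd,
    p_se = if (is.null(classical)) rep(NA_real_, ncol(P)) else classical$se,
    df = n - 1,
    ct = if (is.null(classical)) NA_real_ else attr(classical, "ct"),
    ci_lower = if (is.null(classical)) NULL else classical$lower,
    ci_upper = if (is.null(classical)) NULL else classical$upper,
    rep_means = rep_means,
    grand_mean = grand_mean,
    ps_star = ps_star,
    bias = bias,
    t_stats = t_stats,
    c_star = c_star,
    boot_lower = grand_mean - c_star * ps_star,
    boot_upper = grand_mean + c_star * ps_star,
    B = B, alpha = alpha, n = n, seed = seed
  ), class = "ipsg_band")
}

#' @export
print.ipsg_band <- function(x, ...) {
  cat(sprintf(
    "<ipsg_band: n = %d curves, B = %d resamples, alpha = %g, c* = %.3f, max|bias| = %.3g>\n",
    x$n, x$B, x$alpha, x$c_star, max(abs(x$bias))))
  invisible(x)
}

#' Respiratory-rate subgroup specification
#'
#' Half-open RR intervals `[lower, upper)` with a per-interval artificial
#' sample count `b` and an optional cap `n_max` on the number of original
#' rows fed to the bootstrap (rows beyond the cap are subsampled without
#' replacement under the augmentation seed).  The default reproduces the
#' six under-represented bands of the reference experiment, 100 artificial
#' curves each: below 8, 8-9, 10-11, 22-23, 24, and 25+ brpm.
#'
#' @param lower,upper Interval edges in brpm (use `-Inf`/`Inf` for open ends).
#' @param b Artificial curves to generate per interval.
#' @param n_max Optional per-interval cap on input rows (`NA` = use all).
#' @return A tibble with columns `lower`, `upper`, `b`, `n_max`.
#' @export
rr_subgroups <- function(lower = c(-Inf, 8, 10, 22, 24, 25),
                         upper = c(8, 10, 12, 24, 25, Inf),
                         b = 100, n_max = NA_integer_) {
  if (length(lower) != length(upper)) abort("`lower` and `upper` lengths differ.")
  o <- order(lower)
  if (any(upper[o][-length(o)] > lower[o][-1] + 1e-12)) {
    abort("Subgroup intervals must not overlap.")
  }
  tibble::tibble(lower = lower, upper = upper,
                 b = rep_len(b, length(lower)),
                 n_max = rep_len(n_max, length(lower)))
}

#' Assign labels to subgroup intervals
#'
#' @param rr Numeric vector of reference RR labels (brpm).
#' @param subgroups An [rr_subgroups()] tibble.
#' @return A list of integer index vectors, one per subgroup row; labels
#'   outside every interval belong to no subgroup.  Empty subgroups trigger a
#'   warning (not an error).
#' @export
#' @examples
#' bin_subgroups(c(6, 9, 15, 24), rr_subgroups(c(-Inf, 8, 22, 24), c(8, 10, 24, 26)))
bin_subgroups <- function(rr, subgroups) {
  idx <- purrr::map(seq_len(nrow(subgroups)), function(i) {
    which(rr >= subgroups$lower[i] & rr < subgroups$upper[i])
  })
  empty <- lengths(idx) == 0
  if (any(empty) && length(rr) > 0) {
    warn(sprintf("%d empty subgroup(s) skipped.", sum(empty)))
  }
  idx
}

#' Generate artificial PS curves for one subgroup
#'
#' Each artificial curve is the replicate mean of one bootstrap resample of
#' the subgroup's rows; each artificial label is the subgroup's mean
#' reference RR (constant across the subgroup's artificial rows), or the
#' per-replicate mean of the resampled rows' labels when
#' `label = "replicate_mean"`.
#'
#' @param ps_sub PS tibble restricted to one subgroup (>= 1 row).
#' @param B Number of artificial curves (0 allowed: empty output).
#' @param seed Integer seed.
#' @param label `"subgroup_mean"` (default) or `"replicate_mean"`.
#' @return A PS tibble of `B` rows with `origin = "artificial"`.
#' @export
ipsg_generate <- function(ps_sub, B = 100, seed = 1,
                          label = c("subgroup_mean", "replicate_mean")) {
  label <- match.arg(label)
  if (nrow(ps_sub) == 0) {
    if (B > 0) abort("Cannot augment an empty subgroup.")
    return(ps_sub[0, , drop = FALSE])
  }
  P <- ps_feature_matrix(ps_sub)
  n <- nrow(P)
  cols <- ncol(P)
  if (B == 0) {
    out <- ps_sub[0, , drop = FALSE]
    out$origin <- character(0)
    return(out)
  }
  curves <- matrix(NA_real_, B, cols)
  labs <- numeric(B)
  for (i in seq_len(B)) {
    idx <- with_seed(derive_seed(seed, "boot", i),
                     sample.int(n, n, replace = TRUE))
    curves[i, ] <- colMeans(P[idx, , drop = FALSE])
    labs[i] <- if (label == "replicate_mean") mean(ps_sub$rr[idx]) else mean(ps_sub$rr)
  }
  colnames(curves) <- colnames(P)
  dplyr::bind_cols(
    tibble::tibble(record_id = sprintf("art%04d", seq_len(B)),
                   window = NA_integer_, rr = labs, origin = "artificial"),
    tibble::as_tibble(curves)
  )
}

#' Fuse original and artificial PS curves
#'
#' Row-concatenates the original matrix and the artificial curves, keeping
#' the `origin` flag; optionally shuffles rows under a recorded seed
#' (the "random mixing" step before training).
#'
#' @param ps Original PS tibble.
#' @param artificial Artificial PS tibble (possibly empty).
#' @param shuffle Shuffle fused rows?
#' @param seed Seed for the shuffle.
#' @return The fused PS tibble; restricted to `origin == "original"` it is
#'   identical to the input.
#' @export
fuse_ps <- function(ps, artificial, shuffle = FALSE, seed = 1) {
  if (nrow(artificial) > 0) {
    ps_cols <- grep("^ps[0-9]+$", names(ps), value = TRUE)
    art_cols <- grep("^ps[0-9]+$", names(artificial), value = TRUE)
    if (!identical(ps_cols, art_cols)) {
      abort("Original and artificial curves have mismatched feature columns.")
    }
  }
  fused <- dplyr::bind_rows(ps, artificial)
  if (shuffle) {
    fused <- fused[with_seed(derive_seed(seed, "shuffle"),
                             sample.int(nrow(fused))), , drop = FALSE]
  }
  fused
}

#' Bootstrap-augment the under-represented RR subgroups of a PS matrix
#'
#' The end-to-end augmentation step: bins the labels into the subgroup
#' intervals, optionally caps each subgroup's input rows (`n_max`), generates
#' `b` artificial replicate-mean curves per non-empty subgroup, and fuses
#' them with the original matrix.
#'
#' @param ps PS tibble from [ps_matrix()].
#' @param subgroups An [rr_subgroups()] tibble.
#' @param seed Integer seed driving subsampling and all bootstrap draws.
#' @param label Artificial-label rule, see [ipsg_generate()].
#' @param shuffle Shuffle the fused rows?
#' @return The fused PS tibble with `origin` flags; with the default six
#'   subgroups at `b = 100` a 636-row input gains 600 artificial rows.
#' @export
ipsg_augment <- function(ps, subgroups = rr_subgroups(), seed = 1,
                         label = "subgroup_mean", shuffle = FALSE) {
  idx <- bin_subgroups(ps$rr, subgroups)
  art <- purrr::map(seq_along(idx), function(i) {
    rows <- idx[[i]]
    if (length(rows) == 0) return(NULL)
    cap <- subgroups$n_max[i]
    if (!is.na(cap) && length(rows) > cap) {
      rows <- with_seed(derive_seed(seed, "subsample", i),
                        sample(rows, cap))
    }
    ipsg_generate(ps[rows, , drop = FALSE], B = subgroups$b[i],
                  seed = derive_seed(seed, "subgroup", i), label = label)
  }) |> purrr::compact() |> purrr::list_rbind()
  if (is.null(art) || nrow(art) == 0) {
    art <- ps[0, , drop = FALSE]
  } else {
    art$record_id <- sprintf("art%04d", seq_len(nrow(art)))
  }
  fuse_ps(ps, art, shuffle = shuffle, seed = seed)
}
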