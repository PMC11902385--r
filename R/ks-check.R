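#' Two-sample Kolmogorov-Smirnov check of two mean curves
#'
#' Tests whether two mean power-spectral curves can be regarded as draws from
#' the same continuous distribution, treating the frequency-bin values of
#' each curve as observations (the convention of this validation step; note
#' that neighbouring bins are not independent, so the p-value is a
#' descriptive consistency measure rather than a calibrated test).  The
#' statistic is the sup distance between the two empirical CDFs; the p-value
#' comes from the asymptotic Kolmogorov distribution.
#'
#' @param f1,f2 Numeric vectors (e.g. original and artificial mean curves).
#' @param alpha Significance level for the reject flag.
#' @return A one-row tibble: `ks` (sup-CDF distance), `p`, `h` (1 if the
#'   null of a common distribution is rejected at `alpha`, else 0),
#'   `alpha`, `n1`, `n2`.
#' @export
#' @examples
#' ks_curve_test(rnorm(50), rnorm(50))
ks_curve_test <- function(f1, f2, alpha = 0.05) {
  if (length(f1) == 0 || length(f2) == 0) abort("Both curves must be non-empty.")
  if (any(!is.finite(f1)) || any(!is.finite(f2))) abort("Curves must be finite.")
  res <- suppressWarnings(ks.test(f1, f2, exact = FALSE))
  tibble::tibble(ks = as.numeric(res$statistic), p = res$p.value,
                 h = as.integer(res$p.value < alpha), alpha = alpha,
                 n1 = length(f1), n2 = length(f2))
}

#' KS consistency report for every augmented subgroup
#'
#' For each subgroup compares the mean of the subgroup's original curves with
#' the mean of its artificial curves via [ks_curve_test()].
#'
#' @param fused A fused PS tibble from [ipsg_augment()].
#' @param subgroups The [rr_subgroups()] tibble used for augmentation.
#' @param alpha Significance level.
#' @return A tibble with one row per non-empty subgroup: interval edges,
#'   original/artificial row counts and the KS columns.
#' @export
ks_subgroup_report <- function(fused, subgroups = rr_subgroups(), alpha = 0.05) {
  orig <- fused[fused$origin == "original", , drop = FALSE]
  art <- fused[fused$origin == "artificial", , drop = FALSE]
  idx_o <- suppressWarnings(bin_subgroups(orig$rr, subgroups))
  idx_a <- suppressWarnings(bin_subgroups(art$rr, subgroups))
  purrr::map(seq_len(nrow(subgroups)), function(i) {
    if (length(idx_o[[i]]) == 0 || length(idx_a[[i]]) == 0) return(NULL)
    f1 <- colMeans(ps_feature_matrix(orig[idx_o[[i]], , drop = FALSE]))
    f2 <- colMeans(ps_feature_matrix(art[idx_a[[i]], , drop = FALSE]))
    dplyr::bind_cols(
      tibble::tibble(lower = subgroups$lower[i], upper = subgroups$upper[i],
                     n_original = length(idx_o[[i]]),
                     n_artificial = length(idx_a[[i]])),
      ks_curve_test(f1, f2, alpha = alpha)
    )
  }) |> purrr::compact() |> purrr::list_rbind()
}
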