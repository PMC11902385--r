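#' Tidy an IPSG bootstrap band
#'
#' One row per frequency bin with the sample mean, classical-t band, grand
#' bootstrap mean, bootstrap SD, bias and sup-t band.
#'
#' @param x An `ipsg_band` from [ps_bootstrap_band()].
#' @param ... Unused.
#' @return A tibble with `bin`, `freq`, `mean`, `ci_lower`, `ci_upper`,
#'   `boot_mean`, `boot_sd`, `bias`, `boot_lower`, `boot_upper`.
#' @export
tidy.ipsg_band <- function(x, ...) {
  tibble::tibble(
    bin = seq_along(x$freq), freq = x$freq,
    mean = x$p_mu,
    ci_lower = x$ci_lower %||% rep(NA_real_, length(x$freq)),
    ci_upper = x$ci_upper %||% rep(NA_real_, length(x$freq)),
    boot_mean = x$grand_mean, boot_sd = x$ps_star, bias = x$bias,
    boot_lower = x$boot_lower, boot_upper = x$boot_upper
  )
}

#' @rdname tidy.ipsg_band
#' @export
glance.ipsg_band <- function(x, ...) {
  tibble::tibble(n = x$n, B = x$B, alpha = x$alpha, df = x$df, ct = x$ct,
                 c_star = x$c_star, max_bias = max(abs(x$bias)),
                 max_boot_sd = max(x$ps_star))
}

#' Tidy a fitted RR model
#'
#' @param x An `rr_model` from [rr_fit()].
#' @param ... Unused.
#' @return For tidy: the CV grid with scores when the model was tuned,
#'   otherwise the fitted hyperparameters; for glance: a one-row fit summary.
#' @export
tidy.rr_model <- function(x, ...) {
  if (!is.null(x$cv)) return(x$cv)
  if (x$model == "gpr") {
    return(tibble::tibble(term = c("kernel", "length_scale", "signal_sd",
                                   "noise_sd"),
                          value = c(x$fit$kernel, format(x$fit$ell),
                                    format(x$fit$sf), format(x$fit$sn))))
  }
  tibble::tibble(term = names(x$params),
                 value = purrr::map_chr(x$params, ~format(.x)[1]))
}

#' @rdname tidy.rr_model
#' @export
glance.rr_model <- function(x, ...) {
  tibble::tibble(model = x$model, n_features = x$n_features,
                 tuned = !is.null(x$cv), seed = x$seed)
}
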