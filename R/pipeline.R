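#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run (simulate ->
#' preprocess -> extract -> augment -> validate -> train -> report) with the
#' package defaults, validating the combination before any stage runs.
#'
#' @param n_records,duration,fs,depth,hr,noise_sd Generator settings (see
#'   [simulate_ppg_dataset()]); `n_records` is the per-kind count.
#' @param kinds Modulation kinds to simulate.
#' @param rr_dist RR distribution (tibble or explicit numeric RRs).
#' @param window_s,nfft Window length (s) and FFT length.
#' @param sqi Apply signal-quality screening.
#' @param subgroups Augmentation subgroup spec.
#' @param alpha Band / test significance level.
#' @param B Bootstrap resamples for the diagnostic band.
#' @param models Model kinds to train.
#' @param train_frac Sequential split fraction.
#' @param repetitions Evaluation repetitions.
#' @param seed Top-level seed.
#' @return A validated `rr_config` list.
#' @export
rr_config <- function(n_records = 64, duration = 210, fs = 500, depth = 0.3,
                      hr = 75, noise_sd = 0.02, kinds = c("bw", "fm", "am"),
                      rr_dist = rr_distribution(), window_s = 32, nfft = 512,
                      sqi = TRUE, subgroups = rr_subgroups(), alpha = 0.05,
                      B = 100, models = "gpr", train_frac = 0.8,
                      repetitions = 5, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1) abort("`train_frac` must be in (0, 1).")
  if (duration < window_s) abort("`duration` must cover at least one window.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (B < 1 || repetitions < 1 || n_records < 1) {
    abort("`B`, `repetitions` and `n_records` must be >= 1.")
  }
  structure(as.list(environment()), class = "rr_config")
}

#' Run the full pipeline and write its artifacts
#'
#' Executes every stage in order on a synthetic dataset, writing each
#' intermediate to `out_dir` (windows CSV, PS matrix CSV, augmented CSV,
#' band JSON, KS report JSON, study CSV, report JSON and a manifest of
#' seeds).  Rerunning with the same config and seed reproduces the exact
#' stage outputs byte for byte.
#'
#' @param config An [rr_config()].
#' @param out_dir Output directory (`NULL` skips writing).
#' @param quiet Suppress per-stage messages.
#' @return A list with the in-memory stage outputs: `dataset`, `windows`,
#'   `ps`, `band`, `fused`, `ks`, `study`, `summary`, `anova`.
#' @export
rr_run_pipeline <- function(config = rr_config(), out_dir = NULL,
                            quiet = FALSE) {
  stopifnot(inherits(config, "rr_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(obj, name, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    obj
  }

  say("simulate: %d records x %d kinds", config$n_records,
      length(config$kinds))
  dataset <- simulate_ppg_dataset(
    rr_dist = config$rr_dist, kinds = config$kinds,
    per_kind = config$n_records, duration = config$duration, fs = config$fs,
    depth = config$depth, hr = config$hr, noise_sd = config$noise_sd,
    seed = derive_seed(config$seed, "simulate"))

  say("preprocess: %d-s windows", config$window_s)
  windows <- preprocess_ppg(dataset, window_s = config$window_s,
                            sqi = config$sqi)
  emit(windows |> dplyr::mutate(samples = purrr::map_chr(
    .data$samples, ~paste(signif(.x, 8), collapse = ";"))),
    "windows.csv", function(o, p) readr::write_csv(o, p))

  say("extract: %d windows -> PS matrix", nrow(windows))
  ps <- ps_matrix(windows, nfft = config$nfft)
  emit(ps, "ps_matrix.csv", function(o, p) write_ps_csv(o, p))

  say("band: B = %d bootstrap resamples", config$B)
  band <- ps_bootstrap_band(ps, B = config$B, alpha = config$alpha,
                            seed = derive_seed(config$seed, "band"))
  emit(band, "band.json", function(o, p) {
    jsonlite::write_json(c(glance(o), list(
      mean = o$p_mu, boot_mean = o$grand_mean, boot_sd = o$ps_star,
      bias = o$bias, boot_lower = o$boot_lower, boot_upper = o$boot_upper)),
      p, auto_unbox = TRUE, digits = NA)
  })

  say("augment: %d subgroups", nrow(config$subgroups))
  fused <- ipsg_augment(ps, subgroups = config$subgroups,
                        seed = derive_seed(config$seed, "augment"))
  emit(fused, "augmented.csv", function(o, p) write_ps_csv(o, p))

  say("validate: KS per subgroup")
  ks <- ks_subgroup_report(fused, subgroups = config$subgroups,
                           alpha = config$alpha)
  emit(ks, "ks_report.json", function(o, p) {
    jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA)
  })

  say("train/evaluate: %s, %d repetition(s)",
      paste(config$models, collapse = "/"), config$repetitions)
  study <- rr_study(ps, models = config$models,
                    repetitions = config$repetitions,
                    subgroups = config$subgroups,
                    train_frac = config$train_frac,
                    seed = derive_seed(config$seed, "study"))
  emit(study, "study.csv", function(o, p) readr::write_csv(o, p))

  summary_tbl <- summarize_study(study)
  anova_tbl <- if (length(unique(study$model)) >= 2 &&
                   min(table(study$model[study$ipsg])) >= 2) {
    anova_oneway(study[study$ipsg, , drop = FALSE])
  }
  report <- list(summary = summary_tbl, anova = anova_tbl,
                 ks = ks, band = as.list(glance(band)))
  emit(report, "report.json", function(o, p) {
    jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA)
  })
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(seed = config$seed, n_records = config$n_records,
           duration = config$duration, fs = config$fs, B = config$B,
           repetitions = config$repetitions,
           r_version = as.character(getRversion())),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  invisible(list(dataset = dataset, windows = windows, ps = ps, band = band,
                 fused = fused, ks = ks, study = study,
                 summary = summary_tbl, anova = anova_tbl))
}
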