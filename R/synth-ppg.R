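#' Cardiac pulse template
#'
#' A smooth two-component pulse (systolic peak plus dicrotic bump), built as a
#' sum of Gaussian bells over normalized beat phase in [0, 1).  Any smooth
#' pulse with a single dominant maximum works for pipeline testing; this shape
#' is a conventional minimal PPG morphology.
#'
#' @param amplitudes Component amplitudes (a.u.).
#' @param centers Component centers as fractions of the beat period.
#' @param widths Component widths as fractions of the beat period.
#' @return An object of class `beat_template`.
#' @export
#' @examples
#' tpl <- beat_template()
#' phase <- seq(0, 1, length.out = 200)
#' plot(phase, eval_beat_template(tpl, phase), type = "l")
beat_template <- function(amplitudes = c(1, 0.35),
                          centers = c(0.30, 0.65),
                          widths = c(0.10, 0.12)) {
  stopifnot(length(amplitudes) == length(centers),
            length(centers) == length(widths))
  if (any(amplitudes < 0) || any(widths <= 0)) {
    abort("Beat template amplitudes must be >= 0 and widths > 0.")
  }
  structure(list(amplitudes = amplitudes, centers = centers, widths = widths),
            class = "beat_template")
}

#' Evaluate a beat template at normalized phases
#'
#' @param template A [beat_template()].
#' @param phase Numeric vector of beat phases; only the fractional part is used.
#' @return Numeric vector of pulse amplitudes (a.u., non-negative).
#' @export
eval_beat_template <- function(template, phase) {
  phase <- phase %% 1
  out <- numeric(length(phase))
  for (i in seq_along(template$amplitudes)) {
    # wrap the bell so the pulse is periodic in phase
    d <- phase - template$centers[i]
    d <- d - round(d)
    out <- out + template$amplitudes[i] * exp(-d^2 / (2 * template$widths[i]^2))
  }
  out
}

#' Respiratory modulation specification
#'
#' Describes how breathing modulates the PPG: `"bw"` adds a low-frequency
#' baseline oscillation at the respiratory frequency, `"am"` multiplies the
#' pulse train by a respiratory envelope, `"fm"` modulates the inter-beat
#' interval, `"mixed"` applies all three, `"none"` disables modulation.
#'
#' @param kind One of `"bw"`, `"am"`, `"fm"`, `"mixed"`, `"none"`.
#' @param depth Modulation depth, dimensionless in \[0, 1\].
#' @param rr Respiratory rate in breaths per minute (brpm); the respiratory
#'   frequency is `rr / 60` Hz.
#' @param hr Heart rate in beats per minute; default 75 bpm.
#' @return An object of class `modulation_spec`.
#' @export
modulation_spec <- function(kind = c("bw", "am", "fm", "mixed", "none"),
                            depth = 0.3, rr = 15, hr = 75) {
  kind <- match.arg(kind)
  if (depth < 0 || depth > 1) abort("Modulation depth must lie in [0, 1].")
  if (rr <= 0 || hr <= 0) abort("Rates must be positive.")
  if (kind != "none" && rr / 60 >= hr / 60) {
    abort("Respiratory frequency must be below the heart rate.")
  }
  structure(list(kind = kind, depth = depth, rr = rr, hr = hr),
            class = "modulation_spec")
}

#' Simulate one respiratory-modulated PPG record
#'
#' Generates a pulse train at the heart rate and applies the requested
#' respiratory modulation: baseline wander (additive sinusoid at the
#' respiratory frequency), amplitude modulation (multiplicative envelope),
#' or frequency modulation (sinusoidal modulation of the instantaneous beat
#' frequency), plus additive white Gaussian noise.
#'
#' @param mod A [modulation_spec()].
#' @param duration Record length in seconds.
#' @param fs Sampling frequency in Hz; must exceed twice the heart-rate
#'   frequency.
#' @param template A [beat_template()].
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @param seed Integer seed for the noise stream (`NULL` leaves the RNG alone).
#' @param record_id Identifier stored with the record.
#' @return An object of class `ppg_record`: a list with `signal`, `fs`,
#'   `duration`, `record_id`, `rr` (reference respiratory rate, brpm),
#'   `modulation` and `noise_sd`.
#' @export
#' @examples
#' rec <- simulate_ppg(modulation_spec("bw", rr = 15), duration = 60, fs = 100)
#' length(rec$signal)  # 6000
simulate_ppg <- function(mod, duration = 210, fs = 500,
                         template = beat_template(), noise_sd = 0.02,
                         seed = NULL, record_id = "rec001") {
  stopifnot(inherits(mod, "modulation_spec"))
  if (duration <= 0) abort("`duration` must be positive.")
  if (fs <= 2 * mod$hr / 60) abort("`fs` must exceed twice the heart-rate frequency.")
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  f_hr <- mod$hr / 60
  f_resp <- mod$rr / 60
  resp <- sin(2 * pi * f_resp * t)

  # instantaneous beat frequency; FM modulates it at the respiratory frequency
  f_inst <- rep(f_hr, n)
  if (mod$kind %in% c("fm", "mixed")) {
    f_inst <- f_hr * (1 + mod$depth * resp)
  }
  phase <- cumsum(f_inst) / fs
  sig <- eval_beat_template(template, phase)

  if (mod$kind %in% c("am", "mixed")) {
    sig <- sig * (1 + mod$depth * resp)
  }
  if (mod$kind %in% c("bw", "mixed")) {
    sig <- sig + mod$depth * resp
  }
  if (noise_sd > 0) {
    sig <- sig + with_seed(seed, rnorm(n, sd = noise_sd))
  }
  structure(list(signal = sig, fs = fs, duration = duration,
                 record_id = record_id, rr = mod$rr,
                 modulation = mod$kind, noise_sd = noise_sd),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record %s: %.0f s @ %g Hz, %s modulation, RR %.1f brpm>\n",
              x$record_id, x$duration, x$fs, x$modulation, x$rr))
  invisible(x)
}

#' Imbalanced respiratory-rate distribution
#'
#' Bins with sampling weights from which per-record reference RRs are drawn
#' (uniformly within the chosen bin).  The default mirrors the clinical
#' imbalance this package targets: most records in the normal range with the
#' mode at 14-18 brpm and thin tails below 8 (hypopnea) and above
#' 20 brpm (dyspnea).
#'
#' @param lower,upper Bin edges in brpm (half-open bins `[lower, upper)`).
#' @param weight Non-negative sampling weights, normalized internally.
#' @return A tibble with columns `lower`, `upper`, `weight`.
#' @export
rr_distribution <- function(lower = c(5, 8, 12, 14, 18, 20, 25),
                            upper = c(8, 12, 14, 18, 20, 25, 35),
                            weight = c(0.04, 0.06, 0.20, 0.40, 0.15, 0.10, 0.05)) {
  if (length(lower) != length(upper) || length(lower) != length(weight)) {
    abort("`lower`, `upper` and `weight` must have equal length.")
  }
  if (any(weight < 0) || sum(weight) <= 0) abort("Weights must be >= 0 with a positive sum.")
  if (any(upper <= lower)) abort("Each bin needs upper > lower.")
  o <- order(lower)
  if (any(upper[o][-length(o)] > lower[o][-1] + 1e-12)) abort("Bins must not overlap.")
  tibble::tibble(lower = lower, upper = upper, weight = weight / sum(weight))
}

#' Simulate a dataset of modulated PPG records
#'
#' Draws per-record reference RRs from an [rr_distribution()] and generates
#' `per_kind` records for each requested modulation kind.  The defaults follow
#' the 192-record synthetic study design: 64 records each of baseline,
#' amplitude and frequency modulation, 210 s at 500 Hz.
#'
#' @param rr_dist An [rr_distribution()] tibble, or a numeric vector of
#'   explicit per-record RRs (recycled across kinds).
#' @param kinds Modulation kinds to generate.
#' @param per_kind Records per kind.
#' @param duration,fs Record length (s) and sampling rate (Hz).
#' @param depth Modulation depth.
#' @param hr Heart rate in bpm.
#' @param noise_sd Additive noise SD (a.u.).
#' @param seed Integer seed; fixed seeds give bit-identical datasets.
#' @return A tibble with one row per record: `record_id`, `modulation`, `rr`,
#'   `fs`, `duration` and a `signal` list-column of numeric vectors.
#' @export
#' @examples
#' ds <- simulate_ppg_dataset(per_kind = 2, duration = 64, fs = 100, seed = 1)
#' nrow(ds)  # 6
simulate_ppg_dataset <- function(rr_dist = rr_distribution(),
                                 kinds = c("bw", "fm", "am"),
                                 per_kind = 64, duration = 210, fs = 500,
                                 depth = 0.3, hr = 75, noise_sd = 0.02,
                                 seed = 1) {
  if (per_kind < 1) abort("`per_kind` must be >= 1.")
  n <- per_kind * length(kinds)
  if (is.numeric(rr_dist)) {
    rrs <- rep_len(rr_dist, n)
  } else {
    if (!all(c("lower", "upper", "weight") %in% names(rr_dist)) ||
        nrow(rr_dist) == 0 || sum(rr_dist$weight) <= 0) {
      abort("`rr_dist` must be an rr_distribution() tibble or a numeric vector.")
    }
    rrs <- with_seed(derive_seed(seed, "rr_draw"), {
      bins <- sample.int(nrow(rr_dist), n, replace = TRUE, prob = rr_dist$weight)
      runif(n, rr_dist$lower[bins], rr_dist$upper[bins])
    })
  }
  grid <- tidyr::expand_grid(modulation = kinds, idx = seq_len(per_kind))
  grid$record_id <- sprintf("%s%03d", grid$modulation, grid$idx)
  grid$rr <- rrs
  recs <- purrr::pmap(list(grid$modulation, grid$rr, grid$record_id,
                           seq_len(n)), function(kind, rr, id, i) {
    simulate_ppg(modulation_spec(kind, depth = depth, rr = rr, hr = hr),
                 duration = duration, fs = fs, noise_sd = noise_sd,
                 seed = derive_seed(seed, "noise", i), record_id = id)
  })
  tibble::tibble(record_id = grid$record_id,
                 modulation = grid$modulation,
                 rr = grid$rr, fs = fs, duration = duration,
                 signal = purrr::map(recs, "signal"))
}

#' Write / read a PPG record as columnar text
#'
#' One record per file: two-column CSV (time in s, amplitude in a.u.) with a
#' JSON sidecar (`<path>.json`) carrying the sampling rate, reference RR and
#' modulation kind.
#'
#' @param record A `ppg_record` from [simulate_ppg()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a `ppg_record` (reader).
#' @export
write_ppg_record <- function(record, path) {
  stopifnot(inherits(record, "ppg_record"))
  n <- length(record$signal)
  readr::write_csv(tibble::tibble(time = (seq_len(n) - 1) / record$fs,
                                  amplitude = record$signal), path)
  meta <- record[c("fs", "duration", "record_id", "rr", "modulation", "noise_sd")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ppg_record
#' @export
read_ppg_record <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(signal = dat$amplitude, fs = meta$fs, duration = meta$duration,
                 record_id = meta$record_id, rr = meta$rr,
                 modulation = meta$modulation, noise_sd = meta$noise_sd),
            class = "ppg_record")
}
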