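#' Kaiser-window FIR low-pass specification
#'
#' @param cutoff Cutoff frequency in Hz.
#' @param transition Transition-band width in Hz.
#' @param attenuation Stopband attenuation in dB (Kaiser design formulas pick
#'   the window shape parameter beta and the tap count; the count is forced
#'   odd for a linear-phase type-I filter).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff = 35, transition = 5, attenuation = 40) {
  if (cutoff <= 0 || transition <= 0 || attenuation <= 0) {
    abort("Filter parameters must be positive.")
  }
  structure(list(cutoff = cutoff, transition = transition,
                 attenuation = attenuation), class = "filter_spec")
}

# Kaiser design: beta and odd tap count for the requested attenuation and
# normalized transition width
kaiser_design <- function(spec, fs) {
  a <- spec$attenuation
  beta <- if (a > 50) {
    0.1102 * (a - 8.7)
  } else if (a >= 21) {
    0.5842 * (a - 21)^0.4 + 0.07886 * (a - 21)
  } else 0
  dw <- 2 * pi * spec$transition / fs
  n <- ceiling((a - 8) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1              # even order -> odd tap count
  list(order = n, beta = beta)
}

#' Zero-phase Kaiser low-pass filter
#'
#' Designs a linear-phase FIR low-pass with a Kaiser window and applies it
#' forward-backward (zero phase).  Defaults remove high-frequency content
#' above 35 Hz from a raw PPG waveform.
#'
#' @param x Numeric signal, or a `ppg_record`.
#' @param fs Sampling rate in Hz (taken from the record when `x` is one).
#' @param spec A [filter_spec()].
#' @return Filtered numeric vector of the same length.
#' @export
ppg_lowpass <- function(x, fs = NULL, spec = filter_spec()) {
  if (inherits(x, "ppg_record")) {
    fs <- x$fs
    x <- x$signal
  }
  if (is.null(fs)) abort("`fs` is required when `x` is a plain vector.")
  if (spec$cutoff >= fs / 2) abort("Cutoff must be below the Nyquist frequency.")
  des <- kaiser_design(spec, fs)
  b <- signal::fir1(des$order, spec$cutoff / (fs / 2), type = "low",
                    window = signal::kaiser(des$order + 1, des$beta))
  b <- b / sum(b)  # exact unit DC gain
  zero_phase_fir(b, x)
}

# forward-backward FIR filtering with symmetric edge padding; exactly zero
# phase and ~double the design attenuation
zero_phase_fir <- function(b, x) {
  nb <- length(b)
  n <- length(x)
  npad <- min(n - 1, 3 * nb)
  xp <- c(2 * x[1] - x[seq(npad + 1, 2)], x,
          2 * x[n] - x[seq(n - 1, n - npad)])
  y <- stats::filter(xp, b, sides = 1)
  y[is.na(y)] <- xp[is.na(y)]
  y <- rev(stats::filter(rev(y), b, sides = 1))
  y[is.na(y)] <- xp[is.na(y)]
  as.numeric(y[seq(npad + 1, length.out = n)])
}

#' Detect pulse peaks and troughs with a per-beat quality flag
#'
#' Three-point local maxima above an amplitude threshold and separated by a
#' refractory period are taken as pulse peaks; troughs are the minima between
#' consecutive peaks.  The signal-quality index (SQI) flags a beat bad when
#' its inter-beat interval or its amplitude deviates from the running median
#' by more than the configured tolerances.
#'
#' @param x Numeric signal, or a `ppg_record`.
#' @param fs Sampling rate in Hz.
#' @param refractory Minimum peak separation in seconds (default 0.4 s,
#'   i.e. heart rates up to 150 bpm).
#' @param height Peak threshold as a fraction of the amplitude range above the
#'   signal median.
#' @param interval_tol,amplitude_tol SQI tolerances: maximum relative
#'   deviation of the beat interval / peak amplitude from the running median.
#' @return A tibble with one row per beat: `peak` (sample index), `trough`
#'   (preceding trough index, `NA` for the first beat), `amplitude`, and the
#'   logical `good` SQI flag.
#' @export
detect_beats <- function(x, fs = NULL, refractory = 0.4, height = 0.15,
                         interval_tol = 0.3, amplitude_tol = 0.5) {
  if (inherits(x, "ppg_record")) {
    fs <- x$fs
    x <- x$signal
  }
  if (is.null(fs)) abort("`fs` is required when `x` is a plain vector.")
  if (sd(x) == 0) abort("Flat signal: no beats can be detected.")
  n <- length(x)
  thr <- median(x) + height * (max(x) - median(x))
  cand <- which(x > thr &
                  c(FALSE, diff(x) > 0) &
                  c(diff(x) <= 0, FALSE))
  if (length(cand) == 0) abort("No pulse peaks found above the threshold.")
  # greedy refractory pruning: keep the larger of two peaks closer than the
  # refractory period
  min_gap <- round(refractory * fs)
  peaks <- integer(0)
  for (p in cand) {
    if (length(peaks) == 0 || p - peaks[length(peaks)] >= min_gap) {
      peaks <- c(peaks, p)
    } else if (x[p] > x[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- p
    }
  }
  troughs <- c(NA_integer_,
               purrr::map_int(seq_len(length(peaks) - 1), function(i) {
                 seg <- peaks[i]:peaks[i + 1]
                 seg[which.min(x[seg])]
               }))
  amp <- x[peaks]
  good <- rep(TRUE, length(peaks))
  if (length(peaks) >= 3) {
    ibi <- diff(peaks)
    med_ibi <- runmed(ibi, k = min(length(ibi), 9) - (1 - min(length(ibi), 9) %% 2))
    bad_ibi <- abs(ibi - med_ibi) / med_ibi > interval_tol
    good[-1][bad_ibi] <- FALSE
    med_amp <- runmed(amp, k = min(length(amp), 9) - (1 - min(length(amp), 9) %% 2))
    good[abs(amp - med_amp) / pmax(abs(med_amp), 1e-12) > amplitude_tol] <- FALSE
  }
  tibble::tibble(peak = peaks, trough = troughs, amplitude = amp, good = good)
}

#' Resample a waveform to 5 Hz by linear interpolation
#'
#' @param x Numeric signal, or a `ppg_record`.
#' @param fs Original sampling rate in Hz.
#' @param fs_out Target rate (5 Hz throughout this pipeline).
#' @return Numeric vector of `round(duration * fs_out)` samples on a uniform
#'   grid starting at t = 0.
#' @export
#' @examples
#' length(resample_5hz(sin(seq(0, 400, by = 1 / 125))[1:50000], fs = 125))  # 2000
resample_5hz <- function(x, fs = NULL, fs_out = 5) {
  if (inherits(x, "ppg_record")) {
    fs <- x$fs
    x <- x$signal
  }
  if (is.null(fs)) abort("`fs` is required when `x` is a plain vector.")
  if (length(x) == 0) abort("Empty signal.")
  duration <- length(x) / fs
  n_out <- round(duration * fs_out)
  t_out <- (seq_len(n_out) - 1) / fs_out
  approx((seq_along(x) - 1) / fs, x, xout = t_out, rule = 2)$y
}

#' Remove the respiratory-band-preserving baseline
#'
#' Subtracts the very-low-frequency component (Kaiser low-pass below
#' `cutoff`) from a 5-Hz waveform, i.e. detrending that leaves respiratory
#' oscillations (>~ 0.1 Hz) intact.
#'
#' @param x Numeric 5-Hz waveform.
#' @param fs Sampling rate (5 Hz).
#' @param cutoff Baseline cutoff in Hz.
#' @param transition Transition width of the baseline filter in Hz.
#' @return Numeric vector: `x` minus its baseline, mean approximately zero.
#' @export
remove_baseline <- function(x, fs = 5, cutoff = 0.0665, transition = 0.05) {
  spec <- filter_spec(cutoff = cutoff, transition = transition, attenuation = 40)
  baseline <- ppg_lowpass(x, fs = fs, spec = spec)
  x - baseline
}

#' Split a 5-Hz waveform into non-overlapping fixed-length windows
#'
#' @param x Numeric 5-Hz waveform.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds (32 s gives 160 samples at 5 Hz).
#' @param rr Reference RR label(s): a scalar (constant over the record) or one
#'   value per window.
#' @param record_id Identifier carried into each window row.
#' @return A tibble with one row per complete window: `record_id`, `window`,
#'   `start_s`, `rr` and a `samples` list-column (each `window_s * fs`
#'   samples).  A record shorter than one window yields zero rows.
#' @export
#' @examples
#' nrow(segment_windows(rnorm(2000), rr = 15))  # 12 windows from 400 s
segment_windows <- function(x, fs = 5, window_s = 32, rr = NA_real_,
                            record_id = "rec001") {
  if (window_s <= 0) abort("`window_s` must be positive.")
  wlen <- round(window_s * fs)
  k <- floor(length(x) / wlen)
  if (k == 0) {
    return(tibble::tibble(record_id = character(), window = integer(),
                          start_s = numeric(), rr = numeric(),
                          samples = list()))
  }
  rr <- if (length(rr) == 1) rep(rr, k) else rr
  if (length(rr) != k) abort("`rr` must be scalar or one value per window.")
  tibble::tibble(
    record_id = record_id,
    window = seq_len(k),
    start_s = (seq_len(k) - 1) * window_s,
    rr = rr,
    samples = purrr::map(seq_len(k), function(i) x[((i - 1) * wlen + 1):(i * wlen)])
  )
}

#' Preprocess a PPG dataset into labeled 32-s windows
#'
#' Runs the full chain per record: Kaiser low-pass (35 Hz), optional per-window
#' SQI screening from detected beats, linear resampling to 5 Hz, baseline
#' removal (0.0665 Hz), and non-overlapping 32-s segmentation.
#'
#' @param dataset A tibble from [simulate_ppg_dataset()] (columns `record_id`,
#'   `rr`, `fs`, `signal`), or a single `ppg_record`.
#' @param window_s Window length in seconds.
#' @param lowpass A [filter_spec()] for the 35-Hz stage, or `NULL` to skip it
#'   (e.g. when `fs` is too low for the default design).
#' @param sqi Apply signal-quality screening: windows overlapping more than
#'   `sqi_max_bad` bad-beat fraction are dropped.
#' @param sqi_max_bad Maximum tolerated fraction of bad beats per window.
#' @param baseline_cutoff Baseline-removal cutoff in Hz.
#' @return A window tibble as from [segment_windows()], rows from all records
#'   stacked in record order.
#' @export
preprocess_ppg <- function(dataset, window_s = 32, lowpass = filter_spec(),
                           sqi = TRUE, sqi_max_bad = 0.2,
                           baseline_cutoff = 0.0665) {
  if (inherits(dataset, "ppg_record")) {
    dataset <- tibble::tibble(record_id = dataset$record_id, rr = dataset$rr,
                              fs = dataset$fs, signal = list(dataset$signal))
  }
  purrr::pmap(list(dataset$record_id, dataset$rr, dataset$fs, dataset$signal),
              function(id, rr, fs, sig) {
    # the high-frequency stage only applies when the record is sampled
    # fast enough for the cutoff to sit below Nyquist
    clean <- if (is.null(lowpass) || lowpass$cutoff >= fs / 2) sig
             else ppg_lowpass(sig, fs = fs, spec = lowpass)
    beats <- if (sqi) detect_beats(clean, fs = fs) else NULL
    wave <- resample_5hz(clean, fs = fs)
    wave <- remove_baseline(wave, cutoff = baseline_cutoff)
    win <- segment_windows(wave, fs = 5, window_s = window_s, rr = rr,
                           record_id = id)
    if (sqi && nrow(win) > 0) {
      keep <- purrr::map_lgl(seq_len(nrow(win)), function(i) {
        lo <- win$start_s[i]
        hi <- lo + window_s
        in_win <- beats$peak / fs >= lo & beats$peak / fs < hi
        if (!any(in_win)) return(TRUE)
        mean(!beats$good[in_win]) <= sqi_max_bad
      })
      win <- win[keep, , drop = FALSE]
    }
    win
  }) |> purrr::list_rbind()
}
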