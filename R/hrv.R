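#' Time-domain HRV metrics for one window
#'
#' meanNN is the mean RR, SDNN the sample (n-1) standard deviation, RMSSD
#' the root mean square of successive differences, NN50 the count of
#' successive differences strictly greater than 50 ms, and pNN50 its
#' percentage of the n-1 differences. Windows with fewer than two
#' intervals are invalid: all five metrics carry the -1 sentinel.
#'
#' @param rr_ms Numeric vector of RR intervals (ms).
#' @return A one-row tibble: `valid`, `meanNN`, `SDNN`, `RMSSD`, `NN50`,
#'   `pNN50`.
#' @export
hrv_time_domain <- function(rr_ms) {
  v <- td_metrics(rr_ms)
  tibble::tibble(valid = !is.null(attr(v, "valid")) && attr(v, "valid"),
                 meanNN = v[1], SDNN = v[2], RMSSD = v[3],
                 NN50 = v[4], pNN50 = v[5])
}

td_metrics <- function(rr_ms) {
  if (length(rr_ms) < 2) {
    return(structure(rep(HRV_SENTINEL, 5), valid = FALSE))
  }
  d <- diff(rr_ms)
  nn50 <- sum(abs(d) > 50)
  structure(c(mean(rr_ms), sd(rr_ms), sqrt(mean(d^2)), nn50,
              100 * nn50 / length(d)),
            valid = TRUE)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over Hann-tapered, linearly detrended
#' segments with the given overlap. One-sided density: summing
#' `psd * df` over all frequencies approximates the signal variance.
#'
#' @param x Evenly sampled signal.
#' @param fs Sampling rate (Hz).
#' @param seg_len Segment length in samples (capped at `length(x)`).
#' @param overlap Fractional overlap between segments.
#' @return A tibble with `freq` (Hz) and `psd` (x-units^2 per Hz).
#' @export
welch_psd <- function(x, fs, seg_len = length(x), overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  if (seg_len < 8) abort("signal too short for spectral estimation",
                         class = "afbnp_input_error")
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  u <- sum(w^2)
  t_idx <- seq_len(seg_len)
  t_c <- t_idx - mean(t_idx)
  t_ss <- sum(t_c^2)
  acc <- numeric(floor(seg_len / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- seg - mean(seg) - (sum(t_c * seg) / t_ss) * t_c # linear detrend
    sp <- abs(fft(seg * w))^2 / (fs * u)
    half <- sp[seq_along(acc)]
    half[-1] <- 2 * half[-1]
    if (seg_len %% 2 == 0) half[length(half)] <- half[length(half)] / 2
    acc <- acc + half
  }
  psd <- acc / length(starts)
  tibble::tibble(freq = (seq_along(psd) - 1L) * fs / seg_len, psd = psd)
}

band_power <- function(spec, lo, hi, include_hi = FALSE) {
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq >= lo & (if (include_hi) spec$freq <= hi else spec$freq < hi)
  sum(spec$psd[sel]) * df
}

#' Frequency-domain HRV metrics for one window
#'
#' The RR tachogram is linearly interpolated onto an even grid at
#' `resample_hz`, mean-removed, and its Welch spectrum integrated over
#' the standard bands: LF 0.04-0.15 Hz, HF 0.15-0.40 Hz, TP
#' 0.0033-0.40 Hz. A window is spectrally feasible when it has at least
#' two intervals and at least `min_tachogram_min` minutes between the
#' first and last interval onset; otherwise LF, HF, LF/HF and TP carry
#' the -1 sentinel. LF/HF is sentinelled (with a warning) when HF is
#' exactly zero, keeping the feature matrix finite.
#'
#' @param rr An `rr_series` tibble (`onset_ms`, `rr_ms`).
#' @param resample_hz Tachogram resampling rate (Hz).
#' @param seg_min Welch segment length (minutes).
#' @param overlap Segment overlap fraction.
#' @param min_tachogram_min Minimum interpolable tachogram span (minutes).
#' @return One-row tibble: `spectral_valid`, `LF`, `HF`, `LF_HF`, `TP`
#'   (power in ms^2).
#' @export
hrv_frequency_domain <- function(rr, resample_hz = 4, seg_min = 5,
                                 overlap = 0.5, min_tachogram_min = 5) {
  v <- fd_metrics(rr, resample_hz, seg_min, overlap, min_tachogram_min)
  tibble::tibble(spectral_valid = attr(v, "valid"),
                 LF = v[1], HF = v[2], LF_HF = v[3], TP = v[4])
}

fd_metrics <- function(rr, resample_hz = 4, seg_min = 5, overlap = 0.5,
                       min_tachogram_min = 5) {
  if (nrow(rr) < 2) return(structure(rep(HRV_SENTINEL, 4), valid = FALSE))
  span <- rr$onset_ms[nrow(rr)] - rr$onset_ms[1]
  if (span < min_tachogram_min * 60 * 1000) {
    return(structure(rep(HRV_SENTINEL, 4), valid = FALSE))
  }
  grid <- seq(rr$onset_ms[1], rr$onset_ms[nrow(rr)], by = 1000 / resample_hz)
  tach <- approx(rr$onset_ms, rr$rr_ms, xout = grid, ties = "ordered")$y
  tach <- tach - mean(tach)
  spec <- welch_psd(tach, fs = resample_hz,
                    seg_len = min(length(tach), round(seg_min * 60 * resample_hz)),
                    overlap = overlap)
  lf <- band_power(spec, 0.04, 0.15)
  hf <- band_power(spec, 0.15, 0.40, include_hi = TRUE)
  tp <- band_power(spec, 0.0033, 0.40, include_hi = TRUE)
  lf_hf <- if (hf > 0) lf / hf else {
    warn("HF power is zero; LF/HF set to sentinel -1")
    HRV_SENTINEL
  }
  structure(c(lf, hf, lf_hf, tp), valid = TRUE)
}

#' Per-window HRV feature table
#'
#' Applies [hrv_time_domain()] and [hrv_frequency_domain()] to every
#' window from [segment_windows()]. A window is valid only when both
#' families are computable (>= 2 intervals and a spectrally feasible
#' tachogram); invalid windows carry the -1 sentinel in all nine metrics,
#' which downstream masking honours.
#'
#' @param windows Window tibble from [segment_windows()].
#' @param ... Passed to [hrv_frequency_domain()].
#' @return Tibble with `window_index`, `start_ms`, `partial`, `valid`,
#'   and the nine metrics `meanNN`..`TP`.
#' @export
hrv_window_features <- function(windows, ...) {
  mats <- purrr::map(windows$rr, function(rr) {
    td <- td_metrics(rr$rr_ms)
    fd <- fd_metrics(rr, ...)
    valid <- attr(td, "valid") && attr(fd, "valid")
    if (!valid) c(0, rep(HRV_SENTINEL, 9)) else c(1, td, fd)
  })
  m <- do.call(rbind, mats)
  colnames(m) <- c("valid", hrv_metric_names)
  dplyr::bind_cols(
    windows[c("window_index", "start_ms", "partial")],
    tibble::tibble(valid = m[, "valid"] == 1),
    tibble::as_tibble(m[, hrv_metric_names, drop = FALSE])
  )
}

#' Whole-recording RR and heart-rate summaries
#'
#' minRR/maxRR/avgRR over the cleaned full-recording RR series; heart-rate
#' summaries via instantaneous HR = 60000/RR (so minHR = 60000/maxRR,
#' maxHR = 60000/minRR, avgHR = 60000/avgRR); meanRMSSD as the mean RMSSD
#' over valid windows (-1 sentinel when no window is valid). Despite the
#' conventional "72 h" label these summaries span the entire recording.
#'
#' @param rr Full-recording cleaned `rr_series` tibble.
#' @param window_features Tibble from [hrv_window_features()].
#' @return One-row tibble: `minRR`, `maxRR`, `avgRR`, `minHR`, `maxHR`,
#'   `avgHR`, `meanRMSSD`.
#' @export
hrv_long_term <- function(rr, window_features) {
  if (!nrow(rr)) {
    abort("cannot summarize an empty RR series", class = "afbnp_input_error")
  }
  v <- window_features$RMSSD[window_features$valid]
  tibble::tibble(
    minRR = min(rr$rr_ms), maxRR = max(rr$rr_ms), avgRR = mean(rr$rr_ms),
    minHR = 60000 / max(rr$rr_ms), maxHR = 60000 / min(rr$rr_ms),
    avgHR = 60000 / mean(rr$rr_ms),
    meanRMSSD = if (length(v)) mean(v) else HRV_SENTINEL
  )
}

#' Preprocess one recording and extract all HRV features
#'
#' The full per-recording chain: noise-peak removal, RR computation,
#' plausibility filtering, quality gating, 30-min windowing, per-window
#' HRV, and whole-recording summaries.
#'
#' @param ann An [rpeak_annotation()].
#' @param window_min Window length (minutes).
#' @param lo_ms,hi_ms RR plausibility bounds (ms).
#' @param ... Passed to [hrv_frequency_domain()].
#' @return List with `quality` (tibble row), `windows` (feature tibble),
#'   `summary` (tibble row or NULL if the cleaned series is empty), and
#'   `rr` (the cleaned series).
#' @export
extract_recording_features <- function(ann, window_min = 30,
                                       lo_ms = 300, hi_ms = 2000, ...) {
  quality <- quality_gate(ann)
  cleaned <- remove_noise_peaks(ann)
  rr <- filter_rr(compute_rr(cleaned), lo_ms, hi_ms)
  wins <- segment_windows(rr, window_min = window_min,
                          span_ms = ann$recording_span_ms)
  wf <- hrv_window_features(wins, ...)
  summary <- if (nrow(rr)) hrv_long_term(rr, wf) else NULL
  list(quality = quality, windows = wf, summary = summary, rr = rr)
}
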