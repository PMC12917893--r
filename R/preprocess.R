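#' R-peak annotation object
#'
#' The device-output surrogate consumed by the preprocessing stage:
#' strictly increasing R-peak timestamps (ms from recording start) plus
#' noise-labelled half-open intervals `[start_ms, end_ms)`. Overlapping or
#' touching noise intervals are merged on construction and clipped to the
#' recording span.
#'
#' @param peak_times_ms Numeric vector of strictly increasing timestamps.
#' @param noise_intervals Tibble/data frame with `start_ms`, `end_ms`.
#' @param recording_span_ms Total recording duration (ms), > 0.
#' @param recording_id Identifier.
#' @return An `rpeak_annotation` object.
#' @export
rpeak_annotation <- function(peak_times_ms,
                             noise_intervals = NULL,
                             recording_span_ms = NULL,
                             recording_id = "R001") {
  peak_times_ms <- as.numeric(peak_times_ms)
  if (is.unsorted(peak_times_ms, strictly = TRUE)) {
    abort("R-peak timestamps must be strictly increasing",
          class = "afbnp_input_error")
  }
  if (is.null(recording_span_ms)) {
    recording_span_ms <- if (length(peak_times_ms)) max(peak_times_ms) else 0
  }
  assert_scalar_number(recording_span_ms, "recording_span_ms", lo = 0)
  if (is.null(noise_intervals)) {
    noise_intervals <- tibble::tibble(start_ms = numeric(), end_ms = numeric())
  }
  noise_intervals <- tibble::as_tibble(noise_intervals)
  stopifnot(all(c("start_ms", "end_ms") %in% names(noise_intervals)))
  noise_intervals <- merge_noise_intervals(noise_intervals, recording_span_ms)
  structure(
    list(recording_id = recording_id,
         peak_times_ms = peak_times_ms,
         noise_intervals = noise_intervals,
         recording_span_ms = recording_span_ms),
    class = "rpeak_annotation"
  )
}

#' @export
print.rpeak_annotation <- function(x, ...) {
  cat(sprintf("<rpeak_annotation> %s: %d peaks over %.2f h, %d noise intervals\n",
              x$recording_id, length(x$peak_times_ms),
              x$recording_span_ms / 3.6e6, nrow(x$noise_intervals)))
  invisible(x)
}

merge_noise_intervals <- function(iv, span_ms) {
  if (!nrow(iv)) return(iv[c("start_ms", "end_ms")])
  iv <- iv |>
    dplyr::mutate(start_ms = pmax(.data$start_ms, 0),
                  end_ms = pmin(.data$end_ms, span_ms)) |>
    dplyr::filter(.data$end_ms > .data$start_ms) |>
    dplyr::arrange(.data$start_ms)
  if (!nrow(iv)) return(iv)
  starts <- iv$start_ms; ends <- iv$end_ms
  keep_s <- starts[1]; out_s <- numeric(); out_e <- numeric(); cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
      keep_s <- starts[i]; cur_e <- ends[i]
    }
  }
  tibble::tibble(start_ms = c(out_s, keep_s), end_ms = c(out_e, cur_e))
}

#' Remove R-peaks that fall inside noise-labelled intervals
#'
#' A peak with timestamp `t` is removed iff `start <= t < end` for some
#' noise interval (half-open convention: a peak exactly at an interval's
#' end is kept). Noise intervals are retained for quality accounting.
#' Idempotent.
#'
#' @param ann An [rpeak_annotation()].
#' @return A new `rpeak_annotation` with in-noise peaks removed.
#' @export
remove_noise_peaks <- function(ann) {
  stopifnot(inherits(ann, "rpeak_annotation"))
  iv <- ann$noise_intervals
  if (!nrow(iv) || !length(ann$peak_times_ms)) return(ann)
  # intervals are merged & disjoint: findInterval on the flattened bounds
  bounds <- as.vector(rbind(iv$start_ms, iv$end_ms))
  pos <- findInterval(ann$peak_times_ms, bounds, left.open = FALSE)
  inside <- pos %% 2L == 1L
  ann$peak_times_ms <- ann$peak_times_ms[!inside]
  ann
}

#' Compute RR intervals from successive R-peaks
#'
#' @param ann An [rpeak_annotation()] or a numeric vector of peak times.
#' @return An `rr_series` tibble with columns `onset_ms` (timestamp of the
#'   first peak of each interval) and `rr_ms`. Fewer than two peaks give
#'   an empty series.
#' @export
compute_rr <- function(ann) {
  peaks <- if (inherits(ann, "rpeak_annotation")) ann$peak_times_ms else as.numeric(ann)
  if (is.unsorted(peaks, strictly = TRUE)) {
    abort("peaks must be strictly increasing", class = "afbnp_input_error")
  }
  if (length(peaks) < 2) {
    return(tibble::tibble(onset_ms = numeric(), rr_ms = numeric()))
  }
  tibble::tibble(onset_ms = peaks[-length(peaks)], rr_ms = diff(peaks))
}

#' Drop physiologically implausible RR intervals
#'
#' Intervals outside `[lo_ms, hi_ms]` are removed together with their
#' onsets; gaps are not re-bridged. The defaults cover the ventricular
#' response range seen in atrial fibrillation.
#'
#' @param rr An `rr_series` tibble from [compute_rr()].
#' @param lo_ms,hi_ms Plausibility bounds (ms), `lo_ms < hi_ms`.
#' @return The filtered `rr_series` tibble.
#' @export
filter_rr <- function(rr, lo_ms = 300, hi_ms = 2000) {
  if (!(lo_ms < hi_ms)) {
    abort("`lo_ms` must be < `hi_ms`", class = "afbnp_config_error")
  }
  dplyr::filter(rr, .data$rr_ms >= lo_ms, .data$rr_ms <= hi_ms)
}

#' Recording-level quality gate
#'
#' A recording is usable iff its merged noise intervals cover at most 20%
#' of the span and the analyzable time (span minus noise) is at least
#' 48 hours.
#'
#' @param ann An [rpeak_annotation()].
#' @param max_noise_fraction Maximum tolerated noise coverage.
#' @param min_analyzable_hours Minimum analyzable time (h).
#' @return A one-row tibble: `recording_id`, `noise_fraction`,
#'   `analyzable_hours`, `usable`, `reasons` (comma-separated failed
#'   gates, empty if usable).
#' @export
quality_gate <- function(ann, max_noise_fraction = 0.20,
                         min_analyzable_hours = 48) {
  stopifnot(inherits(ann, "rpeak_annotation"))
  if (ann$recording_span_ms <= 0) {
    abort("recording span must be positive", class = "afbnp_input_error")
  }
  noise_ms <- sum(ann$noise_intervals$end_ms - ann$noise_intervals$start_ms)
  nf <- noise_ms / ann$recording_span_ms
  ah <- (ann$recording_span_ms - noise_ms) / 3.6e6
  reasons <- c(
    if (nf > max_noise_fraction) "noise_fraction",
    if (ah < min_analyzable_hours) "analyzable_hours"
  )
  tibble::tibble(
    recording_id = ann$recording_id,
    noise_fraction = nf,
    analyzable_hours = ah,
    usable = length(reasons) == 0L,
    reasons = paste(reasons, collapse = ",")
  )
}

#' Segment an RR series into fixed windows
#'
#' Windows lie on a fixed grid anchored at the recording start
#' (`[k*W, (k+1)*W)` in ms); each interval belongs to the window
#' containing its onset, so windows are disjoint and no interval is lost.
#' The trailing partial window is kept and flagged. Windows with fewer
#' than two intervals are returned as-is for downstream sentinel
#' handling.
#'
#' @param rr An `rr_series` tibble.
#' @param window_min Window length in minutes (default 30).
#' @param span_ms Recording span determining the number of windows;
#'   defaults to the end of the last interval.
#' @return A tibble with one row per window: `window_index` (1-based),
#'   `start_ms`, `partial`, `n_intervals`, and a list-column `rr` of
#'   per-window `rr_series` tibbles.
#' @export
segment_windows <- function(rr, window_min = 30, span_ms = NULL) {
  assert_scalar_number(window_min, "window_min", lo = 1e-9)
  w_ms <- window_min * 60 * 1000
  if (is.null(span_ms)) {
    span_ms <- if (nrow(rr)) max(rr$onset_ms + rr$rr_ms) else 0
  }
  n_win <- max(1L, as.integer(ceiling(span_ms / w_ms)))
  # onsets are sorted, so window membership is a set of contiguous ranges
  idx <- if (nrow(rr)) pmin(floor(rr$onset_ms / w_ms), n_win - 1L) + 1L else integer()
  counts <- tabulate(idx, nbins = n_win)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  per <- purrr::map2(starts, ends, function(s, e) {
    if (e < s) rr[0, , drop = FALSE] else rr[s:e, , drop = FALSE]
  })
  tibble::tibble(
    window_index = seq_len(n_win),
    start_ms = (seq_len(n_win) - 1) * w_ms,
    partial = (seq_len(n_win)) * w_ms > span_ms,
    n_intervals = counts,
    rr = per
  )
}
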