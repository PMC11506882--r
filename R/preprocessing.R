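## Filtering, class-period extraction and sliding-window segmentation.
##
## Clinical iEEG pipelines band-limit the raw signal (default 4th-order
## Butterworth, 0.5-150 Hz), cut a pre-seizure period and a seizure period
## around each annotated onset, and slice both into fixed-length windows.
## The pre-seizure class is the smaller one, so it is oversampled with a
## denser sliding-window stride.

#' Labelled window container
#'
#' @param windows List of channels x window_len numeric matrices, all of
#'   equal shape.
#' @param labels Integer class ids, 0 = pre-seizure, 1 = seizure; one per
#'   window.
#' @param offsets Optional 0-based sample offsets of each window in its
#'   source recording.
#' @param events Optional integer id of the seizure event each window's
#'   period belongs to (used for event-wise splitting).
#' @param fs Sampling rate the windows were cut at.
#' @return An object of class `"window_set"`.
#' @export
window_set <- function(windows, labels, offsets = NULL, events = NULL,
                       fs = NA_real_) {
  if (!is.list(windows) || length(windows) == 0L)
    stopf("windows must be a non-empty list of matrices")
  dims <- vapply(windows, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all windows must share the same channels x length shape")
  labels <- as.integer(labels)
  if (length(labels) != length(windows)) stopf("one label per window required")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0 or 1")
  if (is.null(offsets)) offsets <- rep(NA_integer_, length(windows))
  if (is.null(events)) events <- rep(NA_integer_, length(windows))
  structure(list(windows = windows, labels = labels,
                 window_len = dims[2, 1], n_channels = dims[1, 1],
                 offsets = as.integer(offsets), events = as.integer(events),
                 fs = fs),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows (%d pre-seizure, %d seizure), %d channels x %d samples\n",
              length(x$windows), sum(x$labels == 0L), sum(x$labels == 1L),
              x$n_channels, x$window_len))
  invisible(x)
}

#' @export
length.window_set <- function(x) length(x$windows)

#' Subset a window set
#'
#' @param x A `"window_set"`.
#' @param idx Indices of the windows to keep (any base subscript form).
#' @return A `"window_set"` with the selected windows, labels, offsets
#'   and event ids.
#' @export
`[.window_set` <- function(x, idx) subset_window_set(x, idx)

subset_window_set <- function(ws, idx) {
  window_set(ws$windows[idx], ws$labels[idx], ws$offsets[idx],
             ws$events[idx], ws$fs)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each channel independently with a Butterworth band-pass applied
#' forward and backward (zero phase, so annotated onset times are not
#' shifted; the effective magnitude response is the squared design
#' response). If `high_hz >= fs/2` the band degenerates to a high-pass at
#' `low_hz`.
#'
#' @param recording An `"ieeg_recording"`.
#' @param low_hz,high_hz Band edges in Hz; defaults 0.5 and 150.
#' @param order Filter order of the underlying design (default 4).
#' @return The filtered `"ieeg_recording"` (same shape, channel order and
#'   annotations).
#' @export
bandpass_filter <- function(recording, low_hz = 0.5, high_hz = 150,
                            order = 4L) {
  stopifnot(inherits(recording, "ieeg_recording"))
  fs <- recording$fs
  if (!is_count(order)) stopf("order must be a positive integer")
  if (low_hz <= 0) stopf("low_hz must be > 0 (got %g)", low_hz)
  if (high_hz <= low_hz) stopf("high_hz (%g) must exceed low_hz (%g)",
                               high_hz, low_hz)
  if (low_hz >= fs / 2) stopf("low_hz (%g) must be below Nyquist (%g)",
                              low_hz, fs / 2)
  flt <- if (high_hz >= fs / 2) {
    signal::butter(order, low_hz / (fs / 2), type = "high")
  } else {
    signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  }
  out <- t(apply(recording$signal, 1L, function(ch)
    signal::filtfilt(flt, ch)))
  recording$signal <- out
  recording
}

# Analytic magnitude response of the default band-pass at frequency f_hz,
# squared for the forward-backward application. Exposed for tests and the
# acceptance script as the filter's closed-form oracle.
#' Zero-phase Butterworth gain at a single frequency
#'
#' @param f_hz Frequency at which to evaluate the gain.
#' @inheritParams bandpass_filter
#' @param fs Sampling rate.
#' @return The scalar amplitude gain of the forward-backward filter.
#' @export
butterworth_zero_phase_gain <- function(f_hz, low_hz = 0.5, high_hz = 150,
                                        order = 4L, fs = 512) {
  flt <- if (high_hz >= fs / 2)
    signal::butter(order, low_hz / (fs / 2), type = "high")
  else
    signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  w <- pi * f_hz / (fs / 2)
  z <- exp(1i * w)
  h <- sum(flt$b * z^(-(seq_along(flt$b) - 1))) /
    sum(flt$a * z^(-(seq_along(flt$a) - 1)))
  Mod(h)^2
}

#' Extract pre-seizure and seizure periods around annotated onsets
#'
#' For each annotated seizure starting at `t0`: the pre-seizure (class 0)
#' interval is `[t0 - pre_seizure_min*60, t0)`, clipped to the recording
#' start and to the previous seizure's annotated end; the seizure
#' (class 1) interval is `[t0, t0 + min(seizure_min*60, annotated
#' duration))`. Intervals are half-open in seconds and never overlap
#' across seizures.
#'
#' @param recording An `"ieeg_recording"` with at least one seizure
#'   annotation.
#' @param pre_seizure_min Pre-seizure period length in minutes (default 5).
#' @param seizure_min Maximum seizure period length in minutes (default 30).
#' @return Data frame with columns `start_s`, `end_s`, `class`
#'   (0 or 1) and `event` (1-based seizure index).
#' @export
extract_class_periods <- function(recording, pre_seizure_min = 5,
                                  seizure_min = 30) {
  stopifnot(inherits(recording, "ieeg_recording"))
  ann <- recording$annotations
  if (is.null(ann) || nrow(ann) == 0L)
    stopf("recording has no seizure annotations")
  ann <- ann[order(ann$start_s), , drop = FALSE]
  out <- list()
  prev_end <- 0
  for (i in seq_len(nrow(ann))) {
    t0 <- ann$start_s[i]
    pre_start <- t0 - pre_seizure_min * 60
    clipped <- max(pre_start, prev_end, 0)
    if (clipped > pre_start)
      warnf("pre-seizure interval of event %d clipped to [%g, %g)",
            i, clipped, t0)
    if (clipped < t0)
      out[[length(out) + 1L]] <- data.frame(start_s = clipped, end_s = t0,
                                            class = 0L, event = i)
    sz_end <- t0 + min(seizure_min * 60, ann$end_s[i] - t0)
    out[[length(out) + 1L]] <- data.frame(start_s = t0, end_s = sz_end,
                                          class = 1L, event = i)
    prev_end <- ann$end_s[i]
  }
  do.call(rbind, out)
}

#' Segment class periods into overlapping sliding windows
#'
#' Within each period, windows start at `period_start + k * stride`
#' (`k = 0, 1, ...`) for as long as the full window fits. The pre-seizure
#' class typically uses a smaller stride (denser overlap) to rebalance the
#' classes; with `stride_class0_s = NULL` it is chosen automatically so
#' the class-0 window count matches class 1 within about 10% (reported via
#' a message).
#'
#' @param recording The source `"ieeg_recording"`.
#' @param periods Data frame from [extract_class_periods()].
#' @param window_s Window length in seconds (default 2).
#' @param stride_class1_s Stride for seizure periods (default 2, i.e. no
#'   overlap).
#' @param stride_class0_s Stride for pre-seizure periods, or `NULL` for
#'   automatic class balancing.
#' @return A `"window_set"` with labels, sample offsets and event ids.
#' @export
segment_windows <- function(recording, periods, window_s = 2,
                            stride_class1_s = 2, stride_class0_s = NULL) {
  stopifnot(inherits(recording, "ieeg_recording"))
  fs <- recording$fs
  wl <- as.integer(round(window_s * fs))
  if (wl < 1L) stopf("window_s too small for fs = %g", fs)
  lens <- periods$end_s - periods$start_s
  if (all(lens < window_s))
    stopf("window_s = %g s is longer than every class period", window_s)
  if (is.null(stride_class0_s)) {
    n1 <- sum(pmax(0, floor((lens[periods$class == 1L] - window_s) /
                              stride_class1_s) + 1))
    len0 <- sum(pmax(0, lens[periods$class == 0L] - window_s))
    stride_class0_s <- if (n1 > 0 && len0 > 0)
      max(len0 / n1, 1 / fs) else stride_class1_s
    message(sprintf("auto class-0 stride: %.3f s (targeting ~%d windows)",
                    stride_class0_s, n1))
  }
  if (stride_class0_s <= 0 || stride_class1_s <= 0)
    stopf("strides must be positive")
  windows <- list(); labels <- integer(); offsets <- integer()
  events <- integer()
  for (i in seq_len(nrow(periods))) {
    p <- periods[i, ]
    stride <- if (p$class == 0L) stride_class0_s else stride_class1_s
    if (p$end_s - p$start_s < window_s) next
    n_k <- floor((p$end_s - p$start_s - window_s) / stride) + 1
    for (k in seq_len(n_k) - 1L) {
      start_samp <- as.integer(round((p$start_s + k * stride) * fs))
      if (start_samp + wl > ncol(recording$signal)) break
      windows[[length(windows) + 1L]] <-
        recording$signal[, start_samp + seq_len(wl), drop = FALSE]
      labels <- c(labels, p$class)
      offsets <- c(offsets, start_samp)
      events <- c(events, p$event)
    }
  }
  if (length(windows) == 0L) stopf("no windows produced")
  window_set(windows, labels, offsets, events, fs = fs)
}
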