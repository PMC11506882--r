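## Synthetic multichannel recordings with known directed coupling.
##
## Validating a directed-connectivity pipeline needs data whose causal graph
## is known exactly. A vector autoregressive (VAR) process provides that:
## each channel follows its own AR(1) dynamics plus lagged contributions from
## explicitly listed source channels, so the ground-truth adjacency is the
## support of the coupling list. Seizure-like epochs are emulated by
## switching to a second coupling topology and adding a rhythmic
## oscillation, mirroring how ictal iEEG differs from background in both
## connectivity and spectral content.

#' Directed VAR coupling specification
#'
#' Describes the dynamics of one class of multichannel signal: per-channel
#' first-order autoregression plus directed lagged couplings between
#' channels, driven by i.i.d. Gaussian innovations.
#'
#' @param n_channels Number of channels (>= 1).
#' @param edges Directed couplings: a data frame with columns `source`,
#'   `target` (0-based channel indices) and `strength` (in `[0, 1)`), or
#'   `NULL` for none. Self-edges are rejected; use `ar_self` instead.
#' @param ar_self Autoregressive coefficient applied to each channel's own
#'   previous sample; scalar or length `n_channels`, each `|coef| < 1`.
#' @param noise_sd Innovation standard deviation; scalar or length
#'   `n_channels` (>= 0; 0 gives a noise-free check fixture).
#'   Per-channel values set distinct signal scales without touching the
#'   coupling structure.
#' @param lag Coupling lag in samples (>= 1) shared by all edges.
#'
#' @details The implied VAR is checked for spectral stability at
#'   construction: the companion matrix of the full coefficient set must
#'   have spectral radius < 1, otherwise the spec is rejected.
#'
#' @return An object of class `"coupling_spec"`.
#' @examples
#' coupling_spec(2, data.frame(source = 0, target = 1, strength = 0.6))
#' @export
coupling_spec <- function(n_channels, edges = NULL, ar_self = 0.5,
                          noise_sd = 1, lag = 1L) {
  if (!is_count(n_channels)) stopf("n_channels must be a positive integer")
  n_channels <- as.integer(n_channels)
  if (is.null(edges)) {
    edges <- data.frame(source = integer(), target = integer(),
                        strength = numeric())
  }
  if (!is.data.frame(edges) ||
      !all(c("source", "target", "strength") %in% names(edges)))
    stopf("edges must be a data frame with columns source, target, strength")
  edges$source <- as.integer(edges$source)
  edges$target <- as.integer(edges$target)
  if (nrow(edges) > 0) {
    if (any(edges$source == edges$target))
      stopf("self-edges are not allowed; use ar_self")
    if (any(edges$source < 0 | edges$source >= n_channels |
            edges$target < 0 | edges$target >= n_channels))
      stopf("edge indices must lie in [0, n_channels)")
    if (any(edges$strength < 0 | edges$strength >= 1))
      stopf("edge strengths must lie in [0, 1)")
  }
  ar_self <- rep_len(as.numeric(ar_self), n_channels)
  if (any(abs(ar_self) >= 1)) stopf("|ar_self| must be < 1")
  noise_sd <- rep_len(as.numeric(noise_sd), n_channels)
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0))
    stopf("noise_sd values must be nonnegative")
  if (!is_count(lag)) stopf("lag must be a positive integer")
  lag <- as.integer(lag)

  spec <- structure(
    list(n_channels = n_channels, edges = edges, ar_self = ar_self,
         noise_sd = as.numeric(noise_sd), lag = lag),
    class = "coupling_spec")
  rho <- var_spectral_radius(spec)
  if (rho >= 1)
    stopf("unstable coupling spec: companion spectral radius %.4f >= 1", rho)
  spec$spectral_radius <- rho
  spec
}

# Coefficient matrices A_1..A_L with A_l[target+1, source+1] contributions.
var_coef_matrices <- function(spec) {
  n <- spec$n_channels
  L <- spec$lag
  A <- replicate(L, matrix(0, n, n), simplify = FALSE)
  diag(A[[1L]]) <- spec$ar_self
  if (nrow(spec$edges) > 0) {
    for (i in seq_len(nrow(spec$edges))) {
      e <- spec$edges[i, ]
      A[[L]][e$target + 1L, e$source + 1L] <-
        A[[L]][e$target + 1L, e$source + 1L] + e$strength
    }
  }
  A
}

var_spectral_radius <- function(spec) {
  n <- spec$n_channels
  L <- spec$lag
  A <- var_coef_matrices(spec)
  comp <- matrix(0, n * L, n * L)
  for (l in seq_len(L)) comp[seq_len(n), (l - 1L) * n + seq_len(n)] <- A[[l]]
  if (L > 1) comp[n + seq_len(n * (L - 1L)), seq_len(n * (L - 1L))] <-
    diag(n * (L - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Shared recursion: run VAR dynamics over a pre-drawn matrix of standard
# normal innovations, with the active spec selectable per sample. Zero
# initial history.
var_recurse <- function(eps, spec_at) {
  n <- nrow(eps)
  T <- ncol(eps)
  x <- matrix(0, n, T)
  for (t in seq_len(T)) {
    sp <- spec_at(t)
    xt <- eps[, t] * sp$noise_sd
    if (t > 1L) xt <- xt + sp$ar_self * x[, t - 1L]
    if (t > sp$lag && nrow(sp$edges) > 0) {
      src <- x[sp$edges$source + 1L, t - sp$lag]
      rs <- rowsum(sp$edges$strength * src, sp$edges$target)
      idx <- as.integer(rownames(rs)) + 1L
      xt[idx] <- xt[idx] + rs[, 1L]
    }
    x[, t] <- xt
  }
  x
}

#' Simulate a stationary VAR process with known directed coupling
#'
#' @param spec A [coupling_spec()].
#' @param n_samples Number of samples to generate (must exceed the lag).
#' @param seed Integer seed; the output is a deterministic function of
#'   `(spec, n_samples, seed)`.
#' @return A `n_channels x n_samples` numeric matrix.
#' @examples
#' sp <- coupling_spec(2, data.frame(source = 0, target = 1, strength = 0.6))
#' x <- simulate_var(sp, 1024, seed = 1)
#' @export
simulate_var <- function(spec, n_samples, seed) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (!is_count(n_samples) || n_samples <= spec$lag)
    stopf("n_samples must be an integer > lag (%d)", spec$lag)
  eps <- with_seed(seed,
                   matrix(stats::rnorm(spec$n_channels * n_samples),
                          spec$n_channels, n_samples))
  var_recurse(eps, function(t) spec)
}

#' Ground-truth adjacency of a coupling specification
#'
#' @param spec A [coupling_spec()].
#' @return An `N x N` binary matrix with entry `(s, t) = 1` iff the spec
#'   contains a directed edge from channel `s` to channel `t` (1-based
#'   matrix positions for 0-based spec indices); zero diagonal.
#' @export
ground_truth_adjacency <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  n <- spec$n_channels
  adj <- matrix(0L, n, n)
  if (nrow(spec$edges) > 0)
    adj[cbind(spec$edges$source + 1L, spec$edges$target + 1L)] <- 1L
  adj
}

#' Synthetic recording specification
#'
#' Combines a background and an ictal [coupling_spec()] with a sampling
#' rate and a set of ictal (seizure) intervals. Within ictal intervals the
#' dynamics switch to the ictal coupling topology and a sinusoidal
#' oscillation of stated frequency and amplitude is added to every channel;
#' the VAR state carries over at the boundaries, so switching introduces no
#' artificial discontinuity beyond the coefficient change.
#'
#' @param background,ictal [coupling_spec()] objects with equal channel
#'   counts.
#' @param fs Sampling rate in Hz.
#' @param duration_s Total recording duration in seconds.
#' @param onsets Ictal intervals: data frame with columns `start_s`,
#'   `end_s` (disjoint, ordered, within the recording) or `NULL` for none.
#' @param ictal_oscillation_hz,ictal_amplitude Frequency (Hz) and amplitude
#'   of the additive ictal rhythm.
#' @param seed Integer seed for the innovation stream.
#' @return An object of class `"recording_spec"`.
#' @export
recording_spec <- function(background, ictal = background, fs = 512,
                           duration_s, onsets = NULL,
                           ictal_oscillation_hz = 7,
                           ictal_amplitude = 0, seed = 1L) {
  stopifnot(inherits(background, "coupling_spec"),
            inherits(ictal, "coupling_spec"))
  if (background$n_channels != ictal$n_channels)
    stopf("background and ictal specs must have equal n_channels")
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be positive")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stopf("duration_s must be positive")
  if (is.null(onsets))
    onsets <- data.frame(start_s = numeric(), end_s = numeric())
  if (!all(c("start_s", "end_s") %in% names(onsets)))
    stopf("onsets must have columns start_s, end_s")
  if (nrow(onsets) > 0) {
    o <- onsets[order(onsets$start_s), , drop = FALSE]
    if (any(o$end_s <= o$start_s)) stopf("onset intervals must have end > start")
    if (any(o$start_s < 0) || any(o$end_s > duration_s))
      stopf("onset intervals must lie within [0, duration]")
    if (nrow(o) > 1 && any(o$start_s[-1L] < o$end_s[-nrow(o)]))
      stopf("onset intervals must be disjoint")
    onsets <- o
  }
  structure(list(background = background, ictal = ictal, fs = fs,
                 duration_s = duration_s, onsets = onsets,
                 ictal_oscillation_hz = ictal_oscillation_hz,
                 ictal_amplitude = ictal_amplitude,
                 seed = as.integer(seed)),
            class = "recording_spec")
}

#' Simulate a labelled multichannel recording
#'
#' Generates a full recording from a [recording_spec()]: background VAR
#' dynamics outside the onset intervals, ictal VAR dynamics plus an
#' additive sinusoid inside them, with seizure annotations attached that
#' match the spec's onsets exactly. With no onsets the output is
#' bit-identical to [simulate_var()] on the background spec with the same
#' seed.
#'
#' @param spec A [recording_spec()].
#' @return An `"ieeg_recording"` object: list with `signal`
#'   (channels x samples), `fs`, `channel_names`, and `annotations`
#'   (data frame `start_s`, `end_s`, `label`).
#' @export
simulate_recording <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  n <- spec$background$n_channels
  T <- as.integer(round(spec$duration_s * spec$fs))
  eps <- with_seed(spec$seed, matrix(stats::rnorm(n * T), n, T))
  tt <- (seq_len(T) - 1L) / spec$fs
  ictal_mask <- rep(FALSE, T)
  if (nrow(spec$onsets) > 0) {
    for (i in seq_len(nrow(spec$onsets)))
      ictal_mask <- ictal_mask |
        (tt >= spec$onsets$start_s[i] & tt < spec$onsets$end_s[i])
  }
  x <- var_recurse(eps, function(t)
    if (ictal_mask[t]) spec$ictal else spec$background)
  if (any(ictal_mask) && spec$ictal_amplitude != 0) {
    osc <- spec$ictal_amplitude * sin(2 * pi * spec$ictal_oscillation_hz * tt)
    x[, ictal_mask] <- sweep(x[, ictal_mask, drop = FALSE], 2,
                             osc[ictal_mask], `+`)
  }
  ann <- spec$onsets
  ann$label <- rep("seizure", nrow(ann))
  new_recording(x, spec$fs, annotations = ann)
}

#' Construct a recording object
#'
#' @param signal Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional character vector, one per channel.
#' @param annotations Data frame with `start_s`, `end_s`, `label`
#'   (seizure events), or `NULL`.
#' @return An `"ieeg_recording"` object.
#' @export
new_recording <- function(signal, fs, channel_names = NULL,
                          annotations = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stopf("signal must be a numeric channels x samples matrix")
  if (nrow(signal) < 1L) stopf("recording needs at least one channel")
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be positive")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stopf("channel_names length must match channel count")
  dur <- ncol(signal) / fs
  if (is.null(annotations))
    annotations <- data.frame(start_s = numeric(), end_s = numeric(),
                              label = character())
  if (nrow(annotations) > 0 &&
      (any(annotations$start_s < 0) || any(annotations$end_s > dur + 1e-9)))
    stopf("annotations must lie within [0, duration]")
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 annotations = annotations),
            class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("iEEG recording: %d channels x %d samples @ %g Hz (%.1f s), %d seizure annotation(s)\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Write / read a recording as a plain-text directory container
#'
#' The container is a directory holding `signal.tsv` (samples in columns,
#' one row per channel), `annotations.csv` (`start_s,end_s,label`) and
#' `meta.json` (`fs`, `channel_names`). Round-trips to full double
#' precision.
#'
#' @param recording An `"ieeg_recording"`.
#' @param path Directory to create/populate.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `"ieeg_recording"`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "ieeg_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(format(recording$signal, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     file.path(path, "signal.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.csv(recording$annotations, file.path(path, "annotations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(fs = recording$fs,
                            channel_names = recording$channel_names),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sig_file <- file.path(path, "signal.tsv")
  if (!file.exists(sig_file)) stopf("no signal.tsv under %s", path)
  signal <- as.matrix(utils::read.table(sig_file, sep = "\t",
                                        colClasses = "numeric"))
  dimnames(signal) <- NULL
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  ann_file <- file.path(path, "annotations.csv")
  ann <- if (file.exists(ann_file))
    utils::read.csv(ann_file, colClasses = c(start_s = "numeric",
                                             end_s = "numeric",
                                             label = "character"))
  else NULL
  new_recording(signal, meta$fs, meta$channel_names, ann)
}

#' Simulate a labelled two-class window set
#'
#' Desk-scale fixture generator for classifier experiments: draws
#' independent fixed-length windows from two coupling specifications with
#' optional ictal-style oscillation on class 1 and optional time reversal
#' of class-1 windows.
#'
#' Time reversal gives a "direction-only" fixture: reversing a stationary
#' Gaussian VAR preserves every channel's marginal dynamics and all
#' symmetric zero-lag dependence between channels, but flips the direction
#' of lagged information flow. Symmetric connectivity measures (absolute
#' correlation, zero-lag mutual information) are therefore blind to the
#' class label by construction, while directed measures (transfer entropy,
#' Granger causality) see it.
#'
#' @param n_per_class Windows per class.
#' @param spec0,spec1 [coupling_spec()] for class 0 / class 1.
#' @param window_len Samples per window.
#' @param seed Master seed; each window gets a derived sub-seed.
#' @param oscillation_hz,oscillation_amplitude Additive sinusoid on class-1
#'   windows (amplitude 0 disables); `fs` gives its time base.
#' @param fs Nominal sampling rate attached to the window set.
#' @param reverse_class1 If `TRUE`, class-1 windows are time-reversed
#'   simulations of `spec1`.
#' @param burn_in Samples discarded at the start of each simulated window
#'   so windows are draws from the stationary regime.
#' @return A `"window_set"` (see [window_set()]).
#' @export
simulate_window_classes <- function(n_per_class, spec0, spec1,
                                    window_len = 256L, seed = 1L,
                                    oscillation_hz = 7,
                                    oscillation_amplitude = 0,
                                    fs = 128, reverse_class1 = FALSE,
                                    burn_in = 64L) {
  stopifnot(inherits(spec0, "coupling_spec"), inherits(spec1, "coupling_spec"))
  if (spec0$n_channels != spec1$n_channels)
    stopf("class specs must share n_channels")
  total <- window_len + burn_in
  windows <- vector("list", 2L * n_per_class)
  labels <- integer(2L * n_per_class)
  tt <- (seq_len(window_len) - 1L) / fs
  osc <- oscillation_amplitude * sin(2 * pi * oscillation_hz * tt)
  for (i in seq_len(n_per_class)) {
    w0 <- simulate_var(spec0, total, derive_seed(seed, i))
    windows[[i]] <- w0[, burn_in + seq_len(window_len), drop = FALSE]
    labels[i] <- 0L
    w1 <- simulate_var(spec1, total, derive_seed(seed, n_per_class + i))
    w1 <- w1[, burn_in + seq_len(window_len), drop = FALSE]
    if (reverse_class1) w1 <- w1[, rev(seq_len(window_len)), drop = FALSE]
    if (oscillation_amplitude != 0) w1 <- sweep(w1, 2, osc, `+`)
    windows[[n_per_class + i]] <- w1
    labels[n_per_class + i] <- 1L
  }
  window_set(windows, labels, fs = fs)
}
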