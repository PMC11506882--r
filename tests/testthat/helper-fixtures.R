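# Shared desk-scale fixtures, built in code at test time.

two_channel_spec <- function(strength = 0.6) {
  coupling_spec(2, data.frame(source = 0, target = 1, strength = strength),
                ar_self = 0.5)
}

# Separable two-class fixture: classes differ in coupling topology and in
# spectral content (additive ictal-style oscillation on class 1).
separable_fixture <- function(n_per_class = 200, seed = 11) {
  spec0 <- coupling_spec(8, data.frame(source = c(0, 2, 4),
                                       target = c(1, 3, 5),
                                       strength = 0.5), ar_self = 0.5)
  spec1 <- coupling_spec(8, data.frame(source = c(1, 3, 6),
                                       target = c(0, 2, 7),
                                       strength = 0.5), ar_self = 0.5)
  simulate_window_classes(n_per_class, spec0, spec1, window_len = 256,
                          seed = seed, oscillation_amplitude = 1.5,
                          oscillation_hz = 7, fs = 128)
}

# Direction-only fixture: class 1 windows are time-reversed draws of the
# same unidirectionally coupled VAR, so marginals and symmetric zero-lag
# dependence match across classes while information flow reverses.
# Driver channels get a larger innovation scale: every graph estimator
# here is invariant to per-channel scaling (bins, regressions and
# correlations are computed per channel), so the graphs are untouched,
# but the scale signature makes "which neighbour a node aggregates"
# visible in the attention layer's features.
direction_only_fixture <- function(n_per_class = 80, seed = 21,
                                   n_channels = 4, window_len = 128) {
  spec <- coupling_spec(n_channels,
                        data.frame(source = c(0, 2), target = c(1, 3),
                                   strength = 0.65), ar_self = 0.4,
                        noise_sd = rep_len(c(3, 1), n_channels))
  simulate_window_classes(n_per_class, spec, spec,
                          window_len = window_len, seed = seed,
                          fs = 128, reverse_class1 = TRUE)
}

# Small training configuration used by harness tests. Coarse 4-bin TE
# discretization suits the short 1-s windows (plug-in bias grows with
# bins^2 / samples); node-flattening keeps per-channel aggregation
# patterns visible to the classifier; density sparsification at the true
# edge count keeps only the strongest directed edges instead of forcing
# an in-edge onto every node (top-k would inject noise edges on nodes
# with no true driver).
desk_control <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 25L, heads = 4L, lstm_hidden = 8L,
                   out_dim = 8L, sub_windows = 4L, seed = 1L,
                   learning_rate = 2e-3, batch_size = 32L,
                   pooling = "flatten", te = te_params(n_bins = 4),
                   sparsify = "density", sparsify_parameter = 2 / 12)
  do.call(cstgat_control, utils::modifyList(defaults, args))
}

# Two-seizure synthetic recording for subject-level experiments.
two_seizure_recording <- function(seed = 5, fs = 64) {
  bg <- coupling_spec(4, data.frame(source = 0, target = 1,
                                    strength = 0.5), ar_self = 0.4)
  ict <- coupling_spec(4, data.frame(source = c(2, 3),
                                     target = c(1, 0),
                                     strength = 0.6), ar_self = 0.4)
  spec <- recording_spec(bg, ict, fs = fs, duration_s = 400,
                         onsets = data.frame(start_s = c(100, 300),
                                             end_s = c(140, 340)),
                         ictal_oscillation_hz = 6, ictal_amplitude = 2,
                         seed = seed)
  simulate_recording(spec)
}
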