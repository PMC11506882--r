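# cstgat

Seizure detection in multichannel intracranial EEG (iEEG) from *directed*
causal connectivity. The premise: seizures reorganize which recording
sites drive which, so a window classifier should see the directed
channel-interaction graph, not just the waveforms.

## Model

For an `N × T` signal window:

1. **Causal graph** — pairwise transfer entropy between channels,

   `T(Y→X) = Σ p(x_{i+1}, x_i^{(k)}, y_i^{(l)}) · log₂ [ p(x_{i+1} | x_i^{(k)}, y_i^{(l)}) / p(x_{i+1} | x_i^{(k)}) ]`

   estimated by plug-in histogram counts and sparsified into a directed
   adjacency. Granger causality, mutual information, and absolute
   correlation are drop-in alternative builders for comparison (the last
   two are symmetric, i.e. direction-blind — that contrast is the point
   of the ablation harness).
2. **Spatial encoder** — the window is split into `S` sub-windows; each
   is encoded by a multi-head graph attention layer (masked softmax
   attention over in-neighbourhoods, heads fused by averaging, ELU).
3. **Temporal encoder** — the `S` spatial encodings form a sequence read
   by a bidirectional LSTM (final forward ∥ backward state).
4. **Classifier** — affine + softmax; trained with cross-entropy and
   Adam. Backpropagation is fully analytic, verified against finite
   differences.

A vector-autoregressive simulator with known directed coupling makes the
whole pipeline testable without any external data: connectivity recovery
is validated against ground truth, and classification on fixtures whose
classes differ only in coupling direction separates directed from
symmetric graph builders.

See `vignettes/causal-graph-seizure-detection.Rmd` for methods,
parameter guidance, generator realism/limits, and design decisions.

## Worked example

Simulate two window classes that differ in coupling topology and
spectrum, build transfer-entropy graphs, fit, and evaluate held-out
windows:

```r
library(cstgat)

bg  <- coupling_spec(4, data.frame(source = 0, target = 1, strength = 0.6),
                     ar_self = 0.4)
ict <- coupling_spec(4, data.frame(source = c(2, 3), target = c(1, 0),
                                   strength = 0.6), ar_self = 0.4)
ws <- simulate_window_classes(60, bg, ict, window_len = 128, seed = 7,
                              oscillation_amplitude = 1.5,
                              oscillation_hz = 8, fs = 128)
graphs <- window_graphs(ws, "te", te_params(n_bins = 4),
                        sparsify = "density", parameter = 2 / 12)

test  <- c(1:15, 61:75)                     # hold out 15 windows per class
train <- setdiff(seq_along(ws$windows), test)
ctl <- cstgat_control(epochs = 20, heads = 4, lstm_hidden = 8,
                      sub_windows = 4, learning_rate = 2e-3, seed = 1,
                      pooling = "flatten")
fit <- cstgat(ws[train], graphs[train], ctl)
print(fit)
#> Causal spatio-temporal graph attention classifier (full)
#>   graph: TE | heads: 4 | F': 8 | H: 8 | S: 4
#>   trained 20 epochs on 90 windows (final loss 0.1018)

evaluate_model(fit, ws[test], graphs[test])$metrics
#> Acc 93.33% | Sen 100.00% | Spe 86.67% | Pre 88.24% | F1 93.75%
```

The fitted object supports `print`, `summary`, `coef`, `predict`
(probabilities or classes), and `plot` (loss history). Recordings with
seizure annotations go through `simulate_recording()`,
`bandpass_filter()`, `extract_class_periods()` and `segment_windows()`;
`subject_experiment()` runs an event-wise (per-seizure) train/test
split, and `ablation_suite()` / `head_sweep()` reproduce the comparison
grids. A command-line front end is installed at
`system.file("cli", "cstgat", package = "cstgat")`.

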