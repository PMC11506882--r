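## Training loop, metrics, experiment protocols and the ablation harness.

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 5e-4 and weight decay 1e-5, cross-entropy loss, 8 attention heads,
#' dropout 0.2, LSTM hidden size 192, 500 epochs. Desk-scale experiments
#' in the tests and scripts override `epochs`, `lstm_hidden` and
#' `out_dim` downward.
#'
#' @param epochs Training epochs (default 500).
#' @param learning_rate Adam step size (default 5e-4).
#' @param weight_decay L2 coefficient added to the gradient (default 1e-5).
#' @param heads Attention heads (default 8).
#' @param dropout Dropout rate on attention coefficients and the
#'   pre-classifier features (default 0.2).
#' @param lstm_hidden LSTM hidden size H (default 192).
#' @param out_dim Attention output size F' (default 8).
#' @param sub_windows Temporal sub-windows S per window (default 8).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Master seed for initialization, shuffling and dropout.
#' @param graph_method Connectivity used to build per-window graphs:
#'   `"te"`, `"gc"`, `"fc"` or `"mi"`.
#' @param components `"full"`, `"gat_only"` or `"bilstm_only"`.
#' @param pooling Node pooling of attention embeddings: `"mean"` or
#'   `"flatten"` (see [init_params()]).
#' @param te Estimator parameters, a [te_params()].
#' @param sparsify,sparsify_parameter Graph sparsification rule (see
#'   [build_graph()]).
#' @param leaky_slope Attention LeakyReLU negative slope.
#' @return A list of class `"cstgat_control"`.
#' @export
cstgat_control <- function(epochs = 500L, learning_rate = 5e-4,
                           weight_decay = 1e-5, heads = 8L, dropout = 0.2,
                           lstm_hidden = 192L, out_dim = 8L,
                           sub_windows = 8L, batch_size = 32L, seed = 1L,
                           graph_method = c("te", "gc", "fc", "mi"),
                           components = c("full", "gat_only",
                                          "bilstm_only"),
                           pooling = c("mean", "flatten"),
                           te = te_params(), sparsify = "top_k_in",
                           sparsify_parameter = 3, leaky_slope = 0.2) {
  graph_method <- match.arg(graph_method)
  components <- match.arg(components)
  pooling <- match.arg(pooling)
  if (!is_count(epochs)) stopf("epochs must be >= 1")
  if (learning_rate < 0) stopf("learning_rate must be >= 0")
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, heads = as.integer(heads),
                 dropout = dropout, lstm_hidden = as.integer(lstm_hidden),
                 out_dim = as.integer(out_dim),
                 sub_windows = as.integer(sub_windows),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), graph_method = graph_method,
                 components = components, pooling = pooling,
                 te = te, sparsify = sparsify,
                 sparsify_parameter = sparsify_parameter,
                 leaky_slope = leaky_slope),
            class = "cstgat_control")
}

# One Adam step over the nested parameter/gradient lists.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  new_p <- map_params(function(p, m, v) p - lr * (m / bc1) /
                        (sqrt(v / bc2) + eps),
                      params, state$m, state$v)
  list(params = new_p, state = state)
}

#' Fit the causal spatio-temporal graph attention classifier
#'
#' The central fitting function. Takes a labelled [window_set()] and (one
#' graph per window) directed connectivity graphs, and trains the
#' attention + bidirectional-LSTM classifier by mini-batch Adam on the
#' cross-entropy loss. If `graphs` is `NULL` they are computed from the
#' windows with the connectivity method in `control`.
#'
#' @param windows A `"window_set"` with >= 2 windows per class.
#' @param graphs List of `"graph_spec"`, one per window, or `NULL`.
#' @param control A [cstgat_control()].
#' @param validation Optional list `list(windows =, graphs =)` used to
#'   record held-out accuracy per epoch.
#' @return An object of class `"cstgat"`: list with `params`
#'   (`"cstgat_params"`), `control`, `history` (data frame with one row
#'   per epoch: `epoch`, `loss`, `val_acc`, `seconds`), `graphs`
#'   metadata and class labels seen.
#' @seealso [predict.cstgat()], [evaluate_model()], [ablation_suite()]
#' @export
cstgat <- function(windows, graphs = NULL, control = cstgat_control(),
                   validation = NULL) {
  stopifnot(inherits(windows, "window_set"),
            inherits(control, "cstgat_control"))
  if (min(table(factor(windows$labels, levels = 0:1))) < 2)
    stopf("need at least 2 training windows per class")
  if (is.null(graphs))
    graphs <- window_graphs(windows, control$graph_method, control$te,
                            control$sparsify, control$sparsify_parameter)
  if (length(graphs) != length(windows$windows))
    stopf("need exactly one graph per window")
  S <- control$sub_windows
  if (windows$window_len %% S != 0)
    stopf("window length %d not divisible by sub_windows = %d",
          windows$window_len, S)
  params <- init_params(windows$n_channels, windows$window_len %/% S,
                        heads = control$heads, out_dim = control$out_dim,
                        hidden = control$lstm_hidden, sub_windows = S,
                        variant = control$components,
                        pooling = control$pooling,
                        leaky_slope = control$leaky_slope,
                        seed = derive_seed(control$seed, 1L))
  meta <- attr(params, "meta")
  state <- list(t = 0L, m = zeros_like(unclass_params(params)),
                v = zeros_like(unclass_params(params)))
  n <- length(windows$windows)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_acc = numeric(), seconds = numeric())
  adjs <- lapply(graphs, function(g) g$adjacency)

  with_seed(derive_seed(control$seed, 2L), {
    for (epoch in seq_len(control$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = control$batch_size)) {
        idx <- ord[start:min(start + control$batch_size - 1L, n)]
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          dropm <- if (control$dropout > 0)
            make_dropout_masks(params, control$dropout) else NULL
          fwd <- model_forward(params, windows$windows[[i]], adjs[[i]],
                               label = windows$labels[i], dropm = dropm)
          if (!is.finite(fwd$loss))
            stopf("non-finite training loss at epoch %d", epoch)
          batch_loss <- batch_loss + fwd$loss
          g <- model_backward(params, fwd, windows$labels[i], dropm)
          grads <- if (is.null(grads)) g else
            map_params(`+`, grads, g)
        }
        grads <- map_params(function(g) g / length(idx), grads)
        if (control$weight_decay > 0)
          grads <- map_params(function(g, p) g + control$weight_decay * p,
                              grads, unclass_params(params))
        st <- adam_step(unclass_params(params), grads, state,
                        control$learning_rate)
        state <- st$state
        new_p <- st$params
        attr(new_p, "meta") <- meta
        class(new_p) <- c("cstgat_params", "list")
        params <- new_p
        epoch_loss <- epoch_loss + batch_loss
      }
      val_acc <- NA_real_
      if (!is.null(validation)) {
        ev <- evaluate_model(params, validation$windows, validation$graphs)
        val_acc <- ev$metrics$acc
      }
      history[epoch, ] <- list(epoch, epoch_loss / n, val_acc,
                               proc.time()[["elapsed"]] - t0)
    }
  })
  structure(list(params = params, control = control, history = history,
                 n_windows = n,
                 class_counts = table(factor(windows$labels, levels = 0:1)),
                 graph_method = control$graph_method),
            class = "cstgat")
}

#' @export
print.cstgat <- function(x, ...) {
  m <- attr(x$params, "meta")
  cat(sprintf("Causal spatio-temporal graph attention classifier (%s)\n",
              m$variant))
  cat(sprintf("  graph: %s | heads: %d | F': %d | H: %d | S: %d\n",
              toupper(x$graph_method), m$heads, m$out_dim, m$hidden,
              m$sub_windows))
  cat(sprintf("  trained %d epochs on %d windows (final loss %.4f)\n",
              nrow(x$history), x$n_windows,
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.cstgat <- function(object, ...) {
  h <- object$history
  cat("Training history:\n")
  print(utils::tail(h, 5), row.names = FALSE)
  cat(sprintf("\nParameters: %d learnable values\n",
              length(flatten_params(unclass_params(object$params)))))
  invisible(object)
}

#' @export
coef.cstgat <- function(object, ...) object$params

#' @export
plot.cstgat <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "mean training loss",
                 main = "Training convergence", ...)
  if (any(is.finite(h$val_acc))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_acc, type = "l", col = "red", axes = FALSE,
                   xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation accuracy", side = 4, line = 2, col = "red")
  }
  invisible(x)
}

#' Predict class probabilities or labels for new windows
#'
#' @param object A fitted `"cstgat"`.
#' @param newdata A `"window_set"`.
#' @param graphs Per-window graphs, or `NULL` to compute them with the
#'   fitted model's graph method.
#' @param type `"prob"` for an n x 2 probability matrix, `"class"` for
#'   hard 0/1 labels (ties go to the seizure class).
#' @param ... Unused.
#' @return Matrix of probabilities or integer vector of labels.
#' @export
predict.cstgat <- function(object, newdata, graphs = NULL,
                           type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "window_set"))
  ctl <- object$control
  if (is.null(graphs))
    graphs <- window_graphs(newdata, ctl$graph_method, ctl$te,
                            ctl$sparsify, ctl$sparsify_parameter)
  probs <- t(vapply(seq_along(newdata$windows), function(i)
    model_forward(object$params, newdata$windows[[i]],
                  graphs[[i]]$adjacency)$prob, numeric(2)))
  colnames(probs) <- c("pre_seizure", "seizure")
  if (type == "prob") probs else as.integer(probs[, 2L] >= probs[, 1L])
}

#' Confusion counts with seizure as the positive class
#'
#' @param predicted,truth Integer 0/1 vectors of equal length.
#' @return List of class `"confusion_counts"` with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stopf("prediction/label length mismatch")
  structure(list(TP = sum(predicted == 1L & truth == 1L),
                 FP = sum(predicted == 1L & truth == 0L),
                 TN = sum(predicted == 0L & truth == 0L),
                 FN = sum(predicted == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (recall on seizure windows), specificity,
#' precision and F1:
#' `acc = (TP+TN)/(TP+FP+TN+FN)`, `sen = TP/(TP+FN)`,
#' `spe = TN/(TN+FP)`, `pre = TP/(TP+FP)`,
#' `f1 = 2*sen*pre/(sen+pre)`. Zero-denominator conventions: `pre = 0`
#' when no positive predictions exist, `f1 = 0` when `sen + pre = 0`;
#' likewise `sen`/`spe` are 0 when their class is absent.
#'
#' @param counts A `"confusion_counts"` (or list with TP/FP/TN/FN).
#' @return List of class `"seizure_metrics"` with `acc`, `sen`, `spe`,
#'   `pre`, `f1`, each in `[0, 1]`.
#' @export
confusion_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stopf("all-zero confusion counts")
  sdiv <- function(num, den) if (den == 0) 0 else num / den
  sen <- sdiv(TP, TP + FN)
  pre <- sdiv(TP, TP + FP)
  structure(list(acc = (TP + TN) / total,
                 sen = sen,
                 spe = sdiv(TN, TN + FP),
                 pre = pre,
                 f1 = sdiv(2 * sen * pre, sen + pre)),
            class = "seizure_metrics")
}

#' @export
print.seizure_metrics <- function(x, ...) {
  cat(sprintf("Acc %.2f%% | Sen %.2f%% | Spe %.2f%% | Pre %.2f%% | F1 %.2f%%\n",
              100 * x$acc, 100 * x$sen, 100 * x$spe, 100 * x$pre,
              100 * x$f1))
  invisible(x)
}

#' Evaluate fitted parameters on a labelled window set
#'
#' Argmax over softmax probabilities (ties to the seizure class), then
#' confusion counts and metrics.
#'
#' @param fit A `"cstgat"` fit or a bare `"cstgat_params"`.
#' @param windows A `"window_set"`.
#' @param graphs Per-window graphs (required when `fit` is bare params).
#' @return List with `counts` (`"confusion_counts"`) and `metrics`
#'   (`"seizure_metrics"`).
#' @export
evaluate_model <- function(fit, windows, graphs = NULL) {
  stopifnot(inherits(windows, "window_set"))
  params <- if (inherits(fit, "cstgat")) fit$params else fit
  if (is.null(graphs)) {
    if (!inherits(fit, "cstgat"))
      stopf("graphs must be supplied when evaluating bare parameters")
    ctl <- fit$control
    graphs <- window_graphs(windows, ctl$graph_method, ctl$te,
                            ctl$sparsify, ctl$sparsify_parameter)
  }
  pred <- vapply(seq_along(windows$windows), function(i) {
    p <- model_forward(params, windows$windows[[i]],
                       graphs[[i]]$adjacency)$prob
    as.integer(p[2L] >= p[1L])
  }, integer(1))
  counts <- confusion_counts(pred, windows$labels)
  list(counts = counts, metrics = confusion_metrics(counts))
}

# Stable content hash of a split (window offsets/events and labels) so
# harness rows can assert they shared identical folds.
split_hash <- function(train_idx, test_idx) {
  v <- c(length(train_idx), sort(train_idx), -1L, length(test_idx),
         sort(test_idx))
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Subject-specific train/test experiment on one recording
#'
#' Runs the full pipeline on a single annotated recording: band-pass
#' filtering, class-period extraction, sliding-window segmentation,
#' per-window connectivity graphs, training on one fold and metric
#' evaluation on the held-out fold. The default protocol splits by
#' seizure event — whole events (and their pre-seizure periods) are held
#' out, never shuffled windows, because neighbouring overlapping windows
#' share samples and window-level shuffling leaks them across folds.
#'
#' @param recording An `"ieeg_recording"` with >= 2 annotated seizures.
#' @param control A [cstgat_control()].
#' @param split `"event"` (default: last event held out) or
#'   `"shuffled"` (stratified window-level split, provided to
#'   demonstrate leakage; do not use for reporting).
#' @param test_fraction Test share for the shuffled protocol.
#' @param pre_seizure_min,seizure_min,window_s,stride_class1_s Passed to
#'   the preprocessing stages.
#' @param filter_band Length-2 band edges in Hz, or `NULL` to skip
#'   filtering.
#' @return List with `metrics`, `counts`, `fit`, `split` (indices and
#'   hash).
#' @export
subject_experiment <- function(recording, control = cstgat_control(),
                               split = c("event", "shuffled"),
                               test_fraction = 0.5,
                               pre_seizure_min = 5, seizure_min = 30,
                               window_s = 2, stride_class1_s = 2,
                               filter_band = NULL) {
  split <- match.arg(split)
  stopifnot(inherits(recording, "ieeg_recording"))
  if (nrow(recording$annotations) < 2L)
    stopf(paste("event-wise splitting needs >= 2 seizures so train and",
                "test folds each contain ictal data"))
  if (!is.null(filter_band))
    recording <- bandpass_filter(recording, filter_band[1], filter_band[2])
  periods <- extract_class_periods(recording, pre_seizure_min, seizure_min)
  ws <- segment_windows(recording, periods, window_s, stride_class1_s)
  graphs <- window_graphs(ws, control$graph_method, control$te,
                          control$sparsify, control$sparsify_parameter)
  n <- length(ws$windows)
  if (split == "event") {
    test_event <- max(ws$events)
    test_idx <- which(ws$events == test_event)
    train_idx <- setdiff(seq_len(n), test_idx)
  } else {
    test_idx <- with_seed(derive_seed(control$seed, 99L), {
      unlist(lapply(0:1, function(cl) {
        cand <- which(ws$labels == cl)
        sample(cand, max(1L, round(test_fraction * length(cand))))
      }))
    })
    train_idx <- setdiff(seq_len(n), test_idx)
  }
  fit <- cstgat(subset_window_set(ws, train_idx), graphs[train_idx],
                control)
  ev <- evaluate_model(fit, subset_window_set(ws, test_idx),
                       graphs[test_idx])
  list(metrics = ev$metrics, counts = ev$counts, fit = fit,
       split = list(protocol = split, train = train_idx, test = test_idx,
                    hash = split_hash(train_idx, test_idx)))
}

fixture_as_folds <- function(fixture, seed, test_fraction = 0.25) {
  if (!is.null(fixture$train)) return(fixture)
  ws <- fixture
  stopifnot(inherits(ws, "window_set"))
  n <- length(ws$windows)
  test_idx <- with_seed(derive_seed(seed, 7L), {
    unlist(lapply(0:1, function(cl) {
      cand <- which(ws$labels == cl)
      sample(cand, max(1L, round(test_fraction * length(cand))))
    }))
  })
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = subset_window_set(ws, train_idx),
       test = subset_window_set(ws, test_idx),
       hash = split_hash(train_idx, test_idx))
}

run_variant <- function(fixture, control) {
  folds <- fixture_as_folds(fixture, control$seed)
  g_train <- window_graphs(folds$train, control$graph_method, control$te,
                           control$sparsify, control$sparsify_parameter)
  g_test <- window_graphs(folds$test, control$graph_method, control$te,
                          control$sparsify, control$sparsify_parameter)
  fit <- cstgat(folds$train, g_train, control)
  ev <- evaluate_model(fit, folds$test, g_test)
  list(metrics = ev$metrics, fit = fit,
       hash = if (!is.null(folds$hash)) folds$hash else
         split_hash(seq_along(folds$train$windows),
                    seq_along(folds$test$windows)))
}

#' Ablation grid over graph builders and model components
#'
#' Runs the six-variant grid — attention-only and recurrent-only
#' components on the transfer-entropy graph, plus the full model on
#' mutual-information, correlation, Granger and transfer-entropy graphs —
#' with a shared seed and a shared train/test split.
#'
#' @param fixture Either a labelled `"window_set"` (split internally,
#'   stratified 75/25) or a list `list(train =, test =)` of window sets.
#' @param base_config A [cstgat_control()]; each row only overrides
#'   `graph_method`/`components`.
#' @return Data frame with one row per variant: `variant`,
#'   `graph_method`, `components`, `acc`, `sen`, `spe`, `pre`, `f1`,
#'   `seed`, `split_hash`.
#' @export
ablation_suite <- function(fixture, base_config = cstgat_control()) {
  grid <- data.frame(
    graph_method = c("te", "te", "mi", "fc", "gc", "te"),
    components = c("gat_only", "bilstm_only", "full", "full", "full",
                   "full"),
    stringsAsFactors = FALSE)
  grid$variant <- sprintf("%s+%s", toupper(grid$graph_method),
                          c("GAT", "BiLSTM", "GAT+BiLSTM", "GAT+BiLSTM",
                            "GAT+BiLSTM", "GAT+BiLSTM"))
  folds <- fixture_as_folds(fixture, base_config$seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ctl <- base_config
    ctl$graph_method <- grid$graph_method[i]
    ctl$components <- grid$components[i]
    res <- run_variant(folds, ctl)
    m <- res$metrics
    data.frame(variant = grid$variant[i],
               graph_method = grid$graph_method[i],
               components = grid$components[i],
               acc = m$acc, sen = m$sen, spe = m$spe, pre = m$pre,
               f1 = m$f1, seed = base_config$seed,
               split_hash = res$hash, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attention-head sweep
#'
#' Re-trains the configured model once per head count, all else fixed
#' (shared seed and split), and reports held-out accuracy per head
#' count.
#'
#' @param fixture As in [ablation_suite()].
#' @param heads_list Integer vector of head counts (each >= 1).
#' @param base_config A [cstgat_control()].
#' @return Data frame with columns `heads` and `acc`.
#' @export
head_sweep <- function(fixture, heads_list, base_config = cstgat_control()) {
  if (any(heads_list < 1)) stopf("head counts must be >= 1")
  folds <- fixture_as_folds(fixture, base_config$seed)
  acc <- vapply(heads_list, function(h) {
    ctl <- base_config
    ctl$heads <- as.integer(h)
    run_variant(folds, ctl)$metrics$acc
  }, numeric(1))
  data.frame(heads = as.integer(heads_list), acc = acc)
}

#' Write a JSON run manifest
#'
#' Records the seed, full configuration and a content hash of the input
#' labels/offsets so a run can be reproduced from the manifest alone.
#'
#' @param path Output JSON file.
#' @param control A [cstgat_control()].
#' @param windows Optional `"window_set"` whose identity is hashed.
#' @param extra Named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, control, windows = NULL, extra = list()) {
  manifest <- c(list(seed = control$seed,
                     config = unclass(control),
                     timestamp = format(Sys.time(), tz = "UTC")),
                extra)
  if (!is.null(windows))
    manifest$input_hash <- split_hash(windows$labels + 1L,
                                      seq_along(windows$windows))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
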