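# Tiny training problems keep these tests fast: 4 channels, short windows,
# a handful of epochs.

tiny_fixture <- function(n_per_class = 8, seed = 90) {
  spec0 <- coupling_spec(4, NULL, ar_self = 0.3)
  spec1 <- coupling_spec(4, NULL, ar_self = 0.3)
  simulate_window_classes(n_per_class, spec0, spec1, window_len = 32,
                          seed = seed, oscillation_amplitude = 2,
                          oscillation_hz = 8, fs = 64)
}

tiny_control <- function(...) {
  defaults <- list(epochs = 3L, sub_windows = 2L, heads = 2L,
                   out_dim = 4L, lstm_hidden = 4L, sparsify_parameter = 1)
  do.call(desk_control, utils::modifyList(defaults, list(...)))
}

test_that("confusion metrics match hand-worked and degenerate examples", {
  m <- confusion_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(m[c("acc", "sen", "spe", "pre", "f1")]),
               c(acc = 1, sen = 1, spe = 1, pre = 1, f1 = 1))
  m2 <- confusion_metrics(list(TP = 0, TN = 50, FP = 0, FN = 50))
  expect_equal(m2$sen, 0); expect_equal(m2$spe, 1)
  expect_equal(m2$pre, 0); expect_equal(m2$f1, 0)
  m3 <- confusion_metrics(list(TP = 40, FN = 10, TN = 45, FP = 5))
  expect_equal(m3$acc, 0.85)
  expect_equal(m3$sen, 0.80)
  expect_equal(m3$spe, 0.90)
  expect_equal(m3$pre, 40 / 45)
  expect_equal(m3$f1, 2 * 0.8 * (40 / 45) / (0.8 + 40 / 45))
  expect_error(confusion_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "all-zero")
})

test_that("metrics agree exactly with an independent oracle on random counts", {
  set.seed(91)
  for (i in 1:200) {
    v <- rmultinom(1, sample(1:500, 1), rep(0.25, 4))[, 1]
    m <- confusion_metrics(list(TP = v[1], FP = v[2], TN = v[3], FN = v[4]))
    o <- oracle_metrics(v[1], v[2], v[3], v[4])
    expect_identical(unlist(m[names(o)]), unlist(o))
  }
})

test_that("a zero learning rate leaves parameters untouched", {
  ws <- tiny_fixture()
  g <- window_graphs(ws, "fc", parameter = 1)
  ctl <- tiny_control(learning_rate = 0, weight_decay = 0, dropout = 0)
  fit <- cstgat(ws, g, ctl)
  init <- init_params(ws$n_channels, ws$window_len / ctl$sub_windows,
                      heads = ctl$heads, out_dim = ctl$out_dim,
                      hidden = ctl$lstm_hidden,
                      sub_windows = ctl$sub_windows,
                      pooling = ctl$pooling,
                      seed = cstgat:::derive_seed(ctl$seed, 1L))
  expect_equal(cstgat:::flatten_params(cstgat:::unclass_params(fit$params)),
               cstgat:::flatten_params(cstgat:::unclass_params(init)))
})

test_that("training is bit-reproducible given the same config and seed", {
  ws <- tiny_fixture()
  g <- window_graphs(ws, "fc", parameter = 1)
  ctl <- tiny_control()
  f1 <- cstgat(ws, g, ctl)
  f2 <- cstgat(ws, g, ctl)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(coef(f1), coef(f2))
})

test_that("evaluation counts are conserved and order-invariant", {
  ws <- tiny_fixture()
  g <- window_graphs(ws, "fc", parameter = 1)
  fit <- cstgat(ws, g, tiny_control())
  ev <- evaluate_model(fit, ws, g)
  cc <- ev$counts
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, length(ws$windows))
  perm <- rev(seq_along(ws$windows))
  ev2 <- evaluate_model(fit, cstgat:::subset_window_set(ws, perm), g[perm])
  expect_identical(ev$metrics, ev2$metrics)
  # predictions as labels agree with the counts
  pred <- predict(fit, ws, g, type = "class")
  expect_equal(sum(pred == 1 & ws$labels == 1), cc$TP)
})

test_that("an always-seizure model scores perfect sensitivity on seizure data", {
  ws <- tiny_fixture()
  g <- window_graphs(ws, "fc", parameter = 1)
  keep <- which(ws$labels == 1L)
  ws1 <- cstgat:::subset_window_set(ws, keep)
  fit <- cstgat(ws, g, tiny_control())
  # force the classifier toward class 1
  fit$params$classifier$b <- c(-50, 50)
  ev <- evaluate_model(fit, ws1, g[keep])
  expect_equal(ev$metrics$sen, 1)
  expect_equal(ev$metrics$acc, 1)
  expect_equal(ev$counts$TN + ev$counts$FP, 0)
})

test_that("training history records every epoch and aborts on bad labels", {
  ws <- tiny_fixture()
  g <- window_graphs(ws, "fc", parameter = 1)
  fit <- cstgat(ws, g, tiny_control(epochs = 4L))
  expect_equal(nrow(fit$history), 4)
  expect_true(all(is.finite(fit$history$loss)))
  one_class <- cstgat:::subset_window_set(ws, which(ws$labels == 0L))
  expect_error(cstgat(one_class, control = tiny_control()), "per class")
})

test_that("subject experiments split by seizure event without sample overlap", {
  rec <- two_seizure_recording()
  ctl <- tiny_control(sub_windows = 4L)
  suppressMessages(
    res <- subject_experiment(rec, ctl, split = "event",
                              pre_seizure_min = 1, seizure_min = 0.5,
                              window_s = 2))
  expect_true(all(unlist(res$metrics) >= 0 & unlist(res$metrics) <= 1))
  expect_length(intersect(res$split$train, res$split$test), 0)
  # determinism
  suppressMessages(
    res2 <- subject_experiment(rec, ctl, split = "event",
                               pre_seizure_min = 1, seizure_min = 0.5,
                               window_s = 2))
  expect_identical(res$metrics, res2$metrics)
  # fewer than two seizures is rejected with the protocol explained
  rec1 <- rec
  rec1$annotations <- rec1$annotations[1, ]
  expect_error(subject_experiment(rec1, ctl), "2 seizures")
})

test_that("the ablation grid runs six variants over one shared split", {
  ws <- tiny_fixture(n_per_class = 6)
  tab <- ablation_suite(ws, tiny_control(epochs = 2L))
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$components,
                  c("gat_only", "bilstm_only", "full"))
  expect_equal(length(unique(tab$split_hash)), 1)
  expect_true(all(tab$acc >= 0 & tab$acc <= 1))
})

test_that("the head sweep reproduces the base configuration at its head count", {
  ws <- tiny_fixture(n_per_class = 6)
  ctl <- tiny_control(epochs = 2L)
  folds <- cstgat:::fixture_as_folds(ws, ctl$seed)
  sweep <- head_sweep(folds, c(2, 4), ctl)
  expect_equal(nrow(sweep), 2)
  expect_true(all(sweep$acc >= 0 & sweep$acc <= 1))
  base <- cstgat:::run_variant(folds, ctl)
  expect_equal(sweep$acc[sweep$heads == 2], base$metrics$acc)
})

test_that("run manifests capture seed and config for reproduction", {
  f <- tempfile(fileext = ".json")
  ctl <- tiny_control()
  write_manifest(f, ctl, extra = list(stage = "test"))
  m <- jsonlite::read_json(f)
  expect_equal(m$seed, ctl$seed)
  expect_equal(m$config$epochs, 3)
  expect_equal(m$stage, "test")
})
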