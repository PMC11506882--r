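# Independent oracles, deliberately written in the most literal style
# possible so they share no code path with the package implementation.

# Brute-force transfer entropy: enumerate every observed
# (x_{i+1}, x-history, y-history) tuple with nested string-keyed count
# tables and evaluate the defining sum directly.
brute_force_te <- function(source, target, k = 1, l = 1, lag = 1) {
  n <- length(target)
  key <- function(...) paste(unlist(list(...)), collapse = ",")
  c_xyx <- new.env(); c_xy <- new.env(); c_xx <- new.env(); c_x <- new.env()
  bump <- function(env, kk) assign(kk, (if (is.null(env[[kk]])) 0 else env[[kk]]) + 1, envir = env)
  first <- max(k, lag + l - 1) + 1
  n_obs <- 0
  for (i in seq(first, n)) {
    xh <- key(target[(i - 1):(i - k)])
    yh <- key(source[(i - lag):(i - lag - l + 1)])
    xp <- as.character(target[i])
    bump(c_xyx, key(xp, xh, yh))
    bump(c_xy, key(xh, yh))
    bump(c_xx, key(xp, xh))
    bump(c_x, xh)
    n_obs <- n_obs + 1
  }
  te <- 0
  for (kk in ls(c_xyx)) {
    parts <- strsplit(kk, ",", fixed = TRUE)[[1]]
    xp <- parts[1]
    xh <- paste(parts[2:(1 + k)], collapse = ",")
    yh <- paste(parts[(2 + k):(1 + k + l)], collapse = ",")
    n_xyx <- c_xyx[[kk]]
    p_joint <- n_xyx / n_obs
    p_cond_full <- n_xyx / c_xy[[key(xh, yh)]]
    p_cond_restricted <- c_xx[[key(xp, xh)]] / c_x[[xh]]
    te <- te + p_joint * log2(p_cond_full / p_cond_restricted)
  }
  te
}

# Independent confusion-metric oracle: plain arithmetic, no shared helper.
oracle_metrics <- function(tp, fp, tn, fn) {
  tot <- tp + fp + tn + fn
  sen <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spe <- if (tn + fp == 0) 0 else tn / (tn + fp)
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (sen + pre == 0) 0 else 2 * sen * pre / (sen + pre)
  list(acc = (tp + tn) / tot, sen = sen, spe = spe, pre = pre, f1 = f1)
}

# Scalar LSTM hand-oracle: literal transcription of the gate equations
# for H = D = 1.
scalar_lstm_step <- function(m, h_prev, c_prev, w = 0.5, b = 0) {
  s <- function(x) 1 / (1 + exp(-x))
  f <- s(w * m + w * h_prev + b)
  i <- s(w * m + w * h_prev + b)
  g <- tanh(w * m + w * h_prev + b)
  o <- s(w * m + w * h_prev + b)
  c_new <- f * c_prev + i * g
  list(h = o * tanh(c_new), c = c_new)
}

# Numeric gradient of the model loss by central differences.
numeric_model_gradient <- function(params, feats, adj, label, eps = 1e-6) {
  up <- cstgat:::unclass_params(params)
  flat <- cstgat:::flatten_params(up)
  lossfun <- function(v) {
    np <- cstgat:::unflatten_params(v, up)
    attr(np, "meta") <- attr(params, "meta")
    class(np) <- class(params)
    cstgat:::model_forward(np, feats, adj, label = label)$loss
  }
  vapply(seq_along(flat), function(i) {
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    (lossfun(vp) - lossfun(vm)) / (2 * eps)
  }, numeric(1))
}
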