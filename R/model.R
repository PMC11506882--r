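## The network: multi-head graph attention over channels, bidirectional
## LSTM over sub-windows, softmax classifier. Forward and backward passes
## are written out explicitly so every stage is unit-testable and the
## whole model gradient-checks against finite differences.
##
## Attention, per head: for node i with in-neighbourhood G_i (channels
## whose directed edge points at i, plus i itself when self-loops are
## present),
##   e_ij  = LeakyReLU( a^T [W v_i || W v_j] ),  j in G_i
##   alpha_ij = exp(e_ij) / sum_{l in G_i} exp(e_il)
## and the fused multi-head output averages the K heads before the
## activation:
##   v'_i = sigma( (1/K) sum_k sum_{j in G_i} alpha_ij^k W^k v_j ).
##
## LSTM gates, per time step (logistic sigmoid s, elementwise product o):
##   f_t = s(W_fm m_t + W_fh h_{t-1} + b_f)
##   i_t = s(W_im m_t + W_ih h_{t-1} + b_i)
##   g_t = tanh(W_cm m_t + W_ch h_{t-1} + b_c)
##   o_t = s(W_om m_t + W_oh h_{t-1} + b_o)
##   c_t = f_t o c_{t-1} + i_t o g_t ;  h_t = o_t o tanh(c_t)

sigmoid <- function(x) 1 / (1 + exp(-x))
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))
leaky_relu <- function(x, slope) ifelse(x >= 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x >= 0, 1, slope)

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

new_lstm_params <- function(hidden, input_dim) {
  list(Wf_m = glorot(hidden, input_dim), Wi_m = glorot(hidden, input_dim),
       Wc_m = glorot(hidden, input_dim), Wo_m = glorot(hidden, input_dim),
       Wf_h = glorot(hidden, hidden), Wi_h = glorot(hidden, hidden),
       Wc_h = glorot(hidden, hidden), Wo_h = glorot(hidden, hidden),
       bf = numeric(hidden), bi = numeric(hidden),
       bc = numeric(hidden), bo = numeric(hidden))
}

#' Initialize model parameters
#'
#' Glorot-uniform initialization of all learnable weights, seeded for
#' reproducibility.
#'
#' @param n_channels Number of graph nodes (channels), N.
#' @param feat_dim Per-node feature size F fed to each attention call
#'   (the sub-window length).
#' @param heads Number of attention heads K.
#' @param out_dim Attention output size F' per node.
#' @param hidden LSTM hidden size H.
#' @param sub_windows Number of temporal sub-windows S.
#' @param variant `"full"`, `"gat_only"` (attention + sequence mean
#'   pooling, no recurrence) or `"bilstm_only"` (raw flattened features
#'   into the recurrent encoder, no attention).
#' @param pooling How per-node attention embeddings become one vector per
#'   sub-window: `"mean"` averages over nodes (permutation-invariant) or
#'   `"flatten"` concatenates them (keeps node identity, so per-channel
#'   aggregation patterns remain visible downstream).
#' @param leaky_slope Negative slope of the attention LeakyReLU.
#' @param seed Integer seed.
#' @return A `"cstgat_params"` nested list of numeric arrays, with the
#'   architecture recorded in `attr(, "meta")`.
#' @export
init_params <- function(n_channels, feat_dim, heads = 8L, out_dim = 8L,
                        hidden = 192L, sub_windows = 8L,
                        variant = c("full", "gat_only", "bilstm_only"),
                        pooling = c("mean", "flatten"),
                        leaky_slope = 0.2, seed = 1L) {
  variant <- match.arg(variant)
  pooling <- match.arg(pooling)
  with_seed(seed, {
    p <- list()
    if (variant != "bilstm_only") {
      p$gat <- list(heads = lapply(seq_len(heads), function(k)
        list(W = glorot(out_dim, feat_dim),
             a = stats::runif(2L * out_dim, -0.3, 0.3))))
    }
    gat_out_len <- if (pooling == "mean") out_dim else
      n_channels * out_dim
    lstm_input <- switch(variant,
      full = gat_out_len,
      bilstm_only = n_channels * feat_dim,
      gat_only = NA_integer_)
    if (variant != "gat_only") {
      p$lstm_fwd <- new_lstm_params(hidden, lstm_input)
      p$lstm_bwd <- new_lstm_params(hidden, lstm_input)
    }
    clf_in <- if (variant == "gat_only") gat_out_len else 2L * hidden
    p$classifier <- list(W = glorot(2L, clf_in), b = numeric(2L))
    attr(p, "meta") <- list(n_channels = n_channels, feat_dim = feat_dim,
                            heads = heads, out_dim = out_dim,
                            hidden = hidden, sub_windows = sub_windows,
                            variant = variant, pooling = pooling,
                            leaky_slope = leaky_slope)
    class(p) <- c("cstgat_params", "list")
    p
  })
}

# In-neighbourhood mask: row i marks nodes j with a directed edge j -> i
# (adjacency convention: entry (s, t) = 1 means edge s -> t).
support_mask <- function(adjacency) {
  m <- t(adjacency) != 0
  iso <- which(rowSums(m) == 0)
  if (length(iso) > 0)
    stopf("node %d has no in-neighbours (add self-loops or densify the graph)",
          iso[1])
  m
}

#' Attention coefficients of one head
#'
#' Computes the softmax-normalized attention matrix: `alpha[i, j]` is the
#' weight node `i` places on in-neighbour `j`; rows sum to 1 over each
#' node's in-neighbourhood and are exactly zero elsewhere.
#'
#' @param node_features N x F numeric matrix.
#' @param adjacency N x N binary matrix, entry `(s, t) = 1` for a
#'   directed edge `s -> t`; self-loops count as in-neighbours.
#' @param head List with `W` (F' x F) and `a` (length 2F').
#' @param leaky_slope LeakyReLU negative slope (default 0.2).
#' @return N x N matrix of attention coefficients.
#' @export
attention_coefficients <- function(node_features, adjacency, head,
                                   leaky_slope = 0.2) {
  att_head_forward(node_features, adjacency, head, leaky_slope)$alpha
}

att_head_forward <- function(V, adjacency, head, leaky_slope,
                             mask = NULL) {
  if (is.null(mask)) mask <- support_mask(adjacency)
  n <- nrow(V)
  fp <- nrow(head$W)
  Z <- V %*% t(head$W)
  a1 <- head$a[seq_len(fp)]
  a2 <- head$a[fp + seq_len(fp)]
  u <- drop(Z %*% a1)
  w <- drop(Z %*% a2)
  Eraw <- outer(u, rep(1, n)) + outer(rep(1, n), w)
  E <- leaky_relu(Eraw, leaky_slope)
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- which(mask[i, ])
    e <- E[i, j]
    e <- exp(e - max(e))
    alpha[i, j] <- e / sum(e)
  }
  list(alpha = alpha, Z = Z, Eraw = Eraw, u = u, w = w, mask = mask)
}

#' One multi-head graph-attention layer
#'
#' Aggregates each node's in-neighbour features with per-head attention
#' weights, averages the heads, and applies the activation (ELU).
#'
#' @param node_features N x F matrix.
#' @param adjacency N x N binary adjacency (directed, self-loops allowed).
#' @param gat List with element `heads`: list of per-head parameter lists
#'   (`W`, `a`), e.g. the `gat` component of [init_params()].
#' @param leaky_slope LeakyReLU negative slope.
#' @return N x F' matrix of fused node embeddings.
#' @export
gat_forward <- function(node_features, adjacency, gat, leaky_slope = 0.2) {
  gat_layer_forward(node_features, adjacency, gat, leaky_slope)$out
}

gat_layer_forward <- function(V, adjacency, gat, leaky_slope,
                              drop_masks = NULL) {
  mask <- support_mask(adjacency)
  K <- length(gat$heads)
  n <- nrow(V)
  fp <- nrow(gat$heads[[1]]$W)
  Hsum <- matrix(0, n, fp)
  caches <- vector("list", K)
  for (k in seq_len(K)) {
    hc <- att_head_forward(V, adjacency, gat$heads[[k]], leaky_slope, mask)
    alpha_used <- hc$alpha
    if (!is.null(drop_masks)) alpha_used <- alpha_used * drop_masks[[k]]
    hc$alpha_used <- alpha_used
    Hsum <- Hsum + alpha_used %*% hc$Z
    caches[[k]] <- hc
  }
  pre <- Hsum / K
  list(out = elu(pre), pre = pre, caches = caches, V = V, mask = mask)
}

# Backward through one GAT layer. dOut: N x F'. Returns per-head
# gradients (dW, da); input gradients are not needed (features are data).
gat_layer_backward <- function(dOut, fwd, gat, leaky_slope,
                               drop_masks = NULL) {
  K <- length(gat$heads)
  dHbar <- dOut * elu_grad(fwd$pre)
  grads <- vector("list", K)
  for (k in seq_len(K)) {
    hc <- fwd$caches[[k]]
    head <- gat$heads[[k]]
    fp <- nrow(head$W)
    a1 <- head$a[seq_len(fp)]
    a2 <- head$a[fp + seq_len(fp)]
    dHk <- dHbar / K
    dAlphaUsed <- dHk %*% t(hc$Z)
    dZ <- t(hc$alpha_used) %*% dHk
    dAlpha <- if (is.null(drop_masks)) dAlphaUsed else
      dAlphaUsed * drop_masks[[k]]
    # softmax backward, row-wise on the support
    dE <- matrix(0, nrow(dAlpha), ncol(dAlpha))
    for (i in seq_len(nrow(dAlpha))) {
      j <- which(hc$mask[i, ])
      ai <- hc$alpha[i, j]
      dai <- dAlpha[i, j]
      dE[i, j] <- ai * (dai - sum(ai * dai))
    }
    dEraw <- dE * leaky_relu_grad(hc$Eraw, leaky_slope)
    du <- rowSums(dEraw)
    dw <- colSums(dEraw)
    dZ <- dZ + outer(du, a1) + outer(dw, a2)
    grads[[k]] <- list(W = t(dZ) %*% fwd$V,
                       a = c(drop(t(hc$Z) %*% du), drop(t(hc$Z) %*% dw)))
  }
  list(heads = grads)
}

#' One LSTM cell step
#'
#' Evaluates the gate equations for a single time step.
#'
#' @param m_t Input vector (length D).
#' @param h_prev,c_prev Previous hidden and cell state (length H).
#' @param params LSTM parameter list (see [init_params()]): input weights
#'   `W*_m` (H x D), recurrent weights `W*_h` (H x H) and biases `b*`
#'   for the forget/input/candidate/output gates.
#' @return List with `h` and `c`, the new hidden and cell state.
#' @export
lstm_step <- function(m_t, h_prev, c_prev, params) {
  st <- lstm_step_cached(m_t, h_prev, c_prev, params)
  list(h = st$h, c = st$c)
}

lstm_step_cached <- function(m_t, h_prev, c_prev, p) {
  f <- sigmoid(drop(p$Wf_m %*% m_t + p$Wf_h %*% h_prev) + p$bf)
  i <- sigmoid(drop(p$Wi_m %*% m_t + p$Wi_h %*% h_prev) + p$bi)
  g <- tanh(drop(p$Wc_m %*% m_t + p$Wc_h %*% h_prev) + p$bc)
  o <- sigmoid(drop(p$Wo_m %*% m_t + p$Wo_h %*% h_prev) + p$bo)
  c_new <- f * c_prev + i * g
  h <- o * tanh(c_new)
  list(h = h, c = c_new, f = f, i = i, g = g, o = o,
       tanh_c = tanh(c_new), m = m_t, h_prev = h_prev, c_prev = c_prev)
}

lstm_run <- function(X, p, hidden) {
  S <- nrow(X)
  h <- numeric(hidden); cc <- numeric(hidden)
  steps <- vector("list", S)
  for (t in seq_len(S)) {
    st <- lstm_step_cached(X[t, ], h, cc, p)
    h <- st$h; cc <- st$c
    steps[[t]] <- st
  }
  list(h_final = h, steps = steps)
}

# BPTT from a gradient on the final hidden state only.
lstm_backward <- function(dh_final, run, p) {
  S <- length(run$steps)
  g <- zeros_like(p)
  dX <- matrix(0, S, length(run$steps[[1]]$m))
  dh <- dh_final
  dc <- numeric(length(dh_final))
  for (t in rev(seq_len(S))) {
    st <- run$steps[[t]]
    dzo <- dh * st$tanh_c * st$o * (1 - st$o)
    dc <- dc + dh * st$o * (1 - st$tanh_c^2)
    dzf <- dc * st$c_prev * st$f * (1 - st$f)
    dzi <- dc * st$g * st$i * (1 - st$i)
    dzc <- dc * st$i * (1 - st$g^2)
    g$Wf_m <- g$Wf_m + outer(dzf, st$m)
    g$Wi_m <- g$Wi_m + outer(dzi, st$m)
    g$Wc_m <- g$Wc_m + outer(dzc, st$m)
    g$Wo_m <- g$Wo_m + outer(dzo, st$m)
    g$Wf_h <- g$Wf_h + outer(dzf, st$h_prev)
    g$Wi_h <- g$Wi_h + outer(dzi, st$h_prev)
    g$Wc_h <- g$Wc_h + outer(dzc, st$h_prev)
    g$Wo_h <- g$Wo_h + outer(dzo, st$h_prev)
    g$bf <- g$bf + dzf; g$bi <- g$bi + dzi
    g$bc <- g$bc + dzc; g$bo <- g$bo + dzo
    dX[t, ] <- drop(crossprod(p$Wf_m, dzf) + crossprod(p$Wi_m, dzi) +
                      crossprod(p$Wc_m, dzc) + crossprod(p$Wo_m, dzo))
    dh <- drop(crossprod(p$Wf_h, dzf) + crossprod(p$Wi_h, dzi) +
                 crossprod(p$Wc_h, dzc) + crossprod(p$Wo_h, dzo))
    dc <- dc * st$f
  }
  list(grads = g, dX = dX)
}

#' Bidirectional LSTM encoding of a sequence
#'
#' Runs one LSTM forward over `t = 1..S` and a second one over the
#' reversed sequence, and concatenates the two final hidden states.
#'
#' @param sequence S x D numeric matrix, one row per time step.
#' @param fwd,bwd LSTM parameter lists for the two directions.
#' @return Numeric vector of length 2H: `[h_forward, h_backward]`.
#' @export
bilstm_forward <- function(sequence, fwd, bwd) {
  if (!is.matrix(sequence) || nrow(sequence) < 1L)
    stopf("sequence must be a non-empty S x D matrix")
  hidden <- length(fwd$bf)
  rf <- lstm_run(sequence, fwd, hidden)
  rb <- lstm_run(sequence[rev(seq_len(nrow(sequence))), , drop = FALSE],
                 bwd, hidden)
  c(rf$h_final, rb$h_final)
}

# Full model forward with cache. drop = NULL (eval mode) or a list of
# pregenerated dropout masks (train mode).
model_forward <- function(params, features, adjacency, label = NULL,
                          dropm = NULL) {
  meta <- attr(params, "meta")
  S <- meta$sub_windows
  n <- nrow(features)
  Ftot <- ncol(features)
  if (Ftot %% S != 0)
    stopf("window length %d not divisible by sub_windows = %d; use S in {%s}",
          Ftot, S, paste(Filter(function(s) Ftot %% s == 0,
                                seq_len(min(Ftot, 64L))), collapse = ", "))
  fsub <- Ftot %/% S
  variant <- meta$variant
  sub <- lapply(seq_len(S), function(t)
    features[, (t - 1L) * fsub + seq_len(fsub), drop = FALSE])
  cache <- list(sub = sub, meta = meta)

  if (variant == "bilstm_only") {
    X <- t(vapply(sub, as.vector, numeric(n * fsub)))
  } else {
    gf <- lapply(seq_len(S), function(t)
      gat_layer_forward(sub[[t]], adjacency, params$gat, meta$leaky_slope,
                        drop_masks = if (is.null(dropm)) NULL else
                          dropm$att[[t]]))
    cache$gat <- gf
    X <- if (identical(meta$pooling, "flatten"))
      t(vapply(gf, function(g) as.vector(g$out),
               numeric(n * meta$out_dim)))
    else
      t(vapply(gf, function(g) colMeans(g$out), numeric(meta$out_dim)))
  }
  cache$X <- X

  if (variant == "gat_only") {
    feat <- colMeans(X)
  } else {
    hidden <- meta$hidden
    rf <- lstm_run(X, params$lstm_fwd, hidden)
    rb <- lstm_run(X[rev(seq_len(S)), , drop = FALSE], params$lstm_bwd,
                   hidden)
    cache$rf <- rf; cache$rb <- rb
    feat <- c(rf$h_final, rb$h_final)
  }
  feat_used <- if (is.null(dropm)) feat else feat * dropm$out
  cache$feat <- feat; cache$feat_used <- feat_used

  logits <- drop(params$classifier$W %*% feat_used) + params$classifier$b
  logits <- logits - max(logits)
  prob <- exp(logits) / sum(exp(logits))
  cache$prob <- prob
  if (!is.null(label)) cache$loss <- -log(max(prob[label + 1L], 1e-300))
  cache
}

model_backward <- function(params, cache, label, dropm = NULL) {
  meta <- cache$meta
  variant <- meta$variant
  g <- zeros_like(unclass_params(params))
  dlogit <- cache$prob
  dlogit[label + 1L] <- dlogit[label + 1L] - 1
  g$classifier$W <- outer(dlogit, cache$feat_used)
  g$classifier$b <- dlogit
  dfeat <- drop(crossprod(params$classifier$W, dlogit))
  if (!is.null(dropm)) dfeat <- dfeat * dropm$out

  S <- length(cache$sub)
  if (variant == "gat_only") {
    dX <- matrix(rep(dfeat / S, each = S), S, length(dfeat))
  } else {
    hidden <- meta$hidden
    bf <- lstm_backward(dfeat[seq_len(hidden)], cache$rf, params$lstm_fwd)
    bb <- lstm_backward(dfeat[hidden + seq_len(hidden)], cache$rb,
                        params$lstm_bwd)
    g$lstm_fwd <- bf$grads
    g$lstm_bwd <- bb$grads
    dX <- bf$dX + bb$dX[rev(seq_len(S)), , drop = FALSE]
  }

  if (variant != "bilstm_only") {
    n <- meta$n_channels
    for (t in seq_len(S)) {
      dOut <- if (identical(meta$pooling, "flatten"))
        matrix(dX[t, ], n, meta$out_dim)
      else
        matrix(rep(dX[t, ] / n, each = n), n, ncol(dX))
      gb <- gat_layer_backward(dOut, cache$gat[[t]], params$gat,
                               meta$leaky_slope,
                               drop_masks = if (is.null(dropm)) NULL else
                                 dropm$att[[t]])
      for (k in seq_along(gb$heads)) {
        g$gat$heads[[k]]$W <- g$gat$heads[[k]]$W + gb$heads[[k]]$W
        g$gat$heads[[k]]$a <- g$gat$heads[[k]]$a + gb$heads[[k]]$a
      }
    }
  }
  g
}

unclass_params <- function(p) {
  meta <- attr(p, "meta")
  p <- unclass(p)
  attr(p, "meta") <- NULL
  p
}

#' Full network forward pass for one window
#'
#' Splits each node's samples into `S` consecutive sub-windows, encodes
#' each sub-window with the attention layer (variant-dependent), pools
#' node embeddings, runs the bidirectional LSTM over the `S`-step
#' sequence, and applies the softmax classifier.
#'
#' @param features N x F numeric matrix (channels x window samples).
#' @param adjacency N x N binary adjacency for this window.
#' @param params A `"cstgat_params"` object from [init_params()].
#' @param train_mode If `TRUE`, dropout is applied to attention
#'   coefficients and to the pre-classifier feature vector (stochastic;
#'   uses the current RNG stream).
#' @param dropout_rate Dropout probability used when `train_mode`.
#' @return Numeric vector of two class probabilities
#'   `(pre-seizure, seizure)`, summing to 1.
#' @export
cstgat_forward <- function(features, adjacency, params,
                           train_mode = FALSE, dropout_rate = 0.2) {
  dropm <- if (train_mode && dropout_rate > 0)
    make_dropout_masks(params, dropout_rate) else NULL
  model_forward(params, features, adjacency, dropm = dropm)$prob
}

make_dropout_masks <- function(params, rate) {
  meta <- attr(params, "meta")
  n <- meta$n_channels
  keep <- 1 - rate
  att <- NULL
  if (meta$variant != "bilstm_only") {
    att <- lapply(seq_len(meta$sub_windows), function(t)
      lapply(seq_len(meta$heads), function(k)
        matrix(stats::rbinom(n * n, 1L, keep), n, n) / keep))
  }
  out_len <- if (meta$variant == "gat_only") {
    if (identical(meta$pooling, "flatten")) n * meta$out_dim else
      meta$out_dim
  } else 2L * meta$hidden
  list(att = att,
       out = stats::rbinom(out_len, 1L, keep) / keep)
}

#' Save / load model parameters
#'
#' The checkpoint is an RDS file holding the full parameter pytree
#' (bit-exact round-trip) plus a human-readable JSON sidecar
#' (`<path>.json`) with the architecture hyperparameters.
#'
#' @param params A `"cstgat_params"`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the `"cstgat_params"`.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "cstgat_params"))
  saveRDS(params, path)
  jsonlite::write_json(attr(params, "meta"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  readRDS(path)
}
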