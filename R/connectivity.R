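## Directed and undirected channel-channel dependence measures.
##
## The causal graph that feeds the attention network is built from
## transfer entropy (TE): the information the source channel's recent past
## carries about the target's next sample beyond the target's own history,
##
##   TE(Y -> X) = sum p(x_{i+1}, x_i^(k), y_i^(l))
##                  log2 [ p(x_{i+1} | x_i^(k), y_i^(l)) /
##                         p(x_{i+1} | x_i^(k)) ]
##
## estimated by the plug-in rule: continuous series are discretized into
## symbols, joint probabilities are the empirical tuple frequencies, and
## the sum runs over observed tuples. Granger causality, mutual
## information and absolute Pearson correlation are provided as the
## standard comparison graph builders.

#' Transfer-entropy estimator parameters
#'
#' @param k Target history length (>= 1).
#' @param l Source history length (>= 1).
#' @param lag Samples between the most recent source-history sample and
#'   the predicted target sample (>= 1; `lag = 1` is the usual
#'   one-step-ahead convention).
#' @param n_bins Number of discretization bins (>= 2).
#' @param strategy Binning strategy: `"width"` (equal-width over the
#'   series range) or `"frequency"` (equal-count by rank).
#' @return A list of class `"te_params"`.
#' @export
te_params <- function(k = 1L, l = 1L, lag = 1L, n_bins = 8L,
                      strategy = c("width", "frequency")) {
  strategy <- match.arg(strategy)
  if (!is_count(k) || !is_count(l) || !is_count(lag))
    stopf("k, l and lag must be positive integers")
  if (!is_count(n_bins) || n_bins < 2) stopf("n_bins must be >= 2")
  structure(list(k = as.integer(k), l = as.integer(l), lag = as.integer(lag),
                 n_bins = as.integer(n_bins), strategy = strategy),
            class = "te_params")
}

#' Discretize a continuous series into integer symbols
#'
#' Equal-width binning spans `[min, max]` of the series with values lying
#' exactly on an interior bin edge assigned to the lower bin; equal-
#' frequency binning assigns by rank so bin counts differ by at most one.
#' A constant series maps to the single symbol 0 (for equal-frequency
#' binning this degenerate fallback is reported via a message).
#'
#' @param series Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @param strategy `"width"` or `"frequency"`.
#' @return Integer vector of symbols in `[0, n_bins)`.
#' @examples
#' discretize(c(0, 1, 2, 3), n_bins = 2)  # 0 0 1 1
#' @export
discretize <- function(series, n_bins = 8L,
                       strategy = c("width", "frequency")) {
  strategy <- match.arg(strategy)
  if (!is.numeric(series) || length(series) == 0L)
    stopf("series must be a non-empty numeric vector")
  rng <- range(series)
  if (rng[1] == rng[2]) {
    if (strategy == "frequency")
      message("constant series: equal-frequency binning degenerates to one symbol")
    return(integer(length(series)))
  }
  if (strategy == "width") {
    w <- (rng[2] - rng[1]) / n_bins
    pmax(0L, as.integer(ceiling((series - rng[1]) / w)) - 1L)
  } else {
    if (length(series) < n_bins)
      stopf("equal-frequency binning needs length >= n_bins")
    r <- rank(series, ties.method = "first")
    as.integer(floor((r - 1) * n_bins / length(series)))
  }
}

#' Shannon entropy of a symbol sequence (plug-in, bits)
#'
#' @param symbols Integer (or factor-like) vector of observed symbols.
#' @return Entropy in bits of the empirical symbol distribution.
#' @examples
#' shannon_entropy(c(0, 1, 0, 1))  # 1 bit
#' @export
shannon_entropy <- function(symbols) {
  if (length(symbols) == 0L) stopf("symbols must be non-empty")
  p <- tabulate(match(symbols, unique(symbols)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

# Encode history tuples as integers: columns t..t-(len-1) of lagged copies.
# Returns an integer vector of codes in [0, base^len) aligned so element i
# codes (x[i], x[i-1], ..., x[i-len+1]); the first len-1 elements are NA.
encode_history <- function(sym, len, base) {
  n <- length(sym)
  code <- numeric(n)
  for (j in seq_len(len)) {
    shifted <- c(rep(NA_integer_, j - 1L), sym[seq_len(n - j + 1L)])
    code <- code + as.numeric(shifted) * base^(j - 1L)
  }
  code
}

#' Plug-in transfer entropy between two symbol or continuous series
#'
#' Estimates the directed information flow from `source` to `target` in
#' bits. Continuous inputs are discretized with the parameters in
#' `params`; integer inputs with fewer than `n_bins` distinct values are
#' used as symbols directly. The estimate is the empirical-tuple
#' transcription of the TE definition and is clamped at 0 against
#' floating-point `-0` artifacts.
#'
#' @param source,target Equal-length numeric vectors; direction measured
#'   is `source -> target`.
#' @param params A [te_params()].
#' @return Transfer entropy in bits (>= 0).
#' @export
transfer_entropy <- function(source, target, params = te_params()) {
  stopifnot(inherits(params, "te_params"))
  if (length(source) != length(target))
    stopf("source and target must have equal length")
  n <- length(target)
  if (n <= params$k + params$l + params$lag)
    stopf("series too short for k=%d, l=%d, lag=%d",
          params$k, params$l, params$lag)
  sx <- as_symbols(target, params)
  sy <- as_symbols(source, params)
  te_from_symbols(sy, sx, params$k, params$l, params$lag)
}

as_symbols <- function(x, params) {
  if (all(x == round(x)) && length(unique(x)) <= params$n_bins) {
    m <- match(x, sort(unique(x))) - 1L
    as.integer(m)
  } else {
    discretize(x, params$n_bins, params$strategy)
  }
}

# Core plug-in computation on integer symbol vectors (0-based).
te_from_symbols <- function(sy, sx, k, l, lag) {
  base <- max(sx, sy) + 1L
  n <- length(sx)
  # histories ending at index i: target x_i^(k), source y_{i-lag+1}^(l)
  xk <- encode_history(sx, k, base)          # aligned at i
  yl <- encode_history(sy, l, base)          # aligned at i
  # predict x_{i+1} from xk at i and yl at i-lag+1
  i <- seq.int(max(k, lag + l - 1L), n - 1L)
  xp <- as.numeric(sx[i + 1L])
  hx <- xk[i]
  hy <- yl[i - lag + 1L]
  bk <- base^k
  bl <- base^l
  c_xyx <- xp + base * (hx + bk * hy)   # (x+, xk, yl)
  c_xy  <- hx + bk * hy                 # (xk, yl)
  c_xx  <- xp + base * hx               # (x+, xk)
  # counts via factor tabulation on observed codes
  cnt <- function(code) {
    f <- match(code, unique(code))
    tabulate(f)[f]
  }
  n_obs <- length(i)
  N_xyx <- cnt(c_xyx)
  N_xy  <- cnt(c_xy)
  N_xx  <- cnt(c_xx)
  N_x   <- cnt(hx)
  te <- sum(log2((N_xyx * N_x) / (N_xy * N_xx))) / n_obs
  max(te, 0)
}

#' Pairwise transfer-entropy matrix over channels
#'
#' @param window Channels x samples numeric matrix.
#' @param params A [te_params()].
#' @return A `"causal_matrix"`: entry `(s, t)` is the transfer entropy
#'   from channel `s` to channel `t`; zero diagonal; asymmetric in
#'   general.
#' @export
te_matrix <- function(window, params = te_params()) {
  connectivity_matrix(window, method = "te", params = params)
}

#' Granger causality from residual-variance reduction
#'
#' Fits two nested ordinary-least-squares autoregressions of the target:
#' restricted (its own `order` lags plus intercept) and full (adding the
#' source's `order` lags), and returns `log(RSS_restricted / RSS_full)`.
#' Nonnegative up to numerical tolerance by OLS nesting. Constant
#' regressor columns are dropped; a rank-deficient design falls back to a
#' tiny ridge regularizer (reported via a message).
#'
#' @param source,target Equal-length numeric vectors; direction measured
#'   is `source -> target`.
#' @param order Number of lags in each block (default 2).
#' @return Nonnegative scalar Granger-causality statistic.
#' @export
granger_causality <- function(source, target, order = 2L) {
  if (length(source) != length(target))
    stopf("source and target must have equal length")
  if (!is_count(order)) stopf("order must be a positive integer")
  n <- length(target)
  if (n <= 10L * order) stopf("series too short: need length > 10*order")
  idx <- seq.int(order + 1L, n)
  y <- target[idx]
  lag_block <- function(v) {
    sapply(seq_len(order), function(j) v[idx - j])
  }
  Xr <- cbind(1, lag_block(target))
  Xf <- cbind(Xr, lag_block(source))
  rss <- function(X) {
    keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L,
                          function(col) stats::var(col) > 0))
    X <- X[, keep, drop = FALSE]
    fit <- stats::lm.fit(X, y)
    if (anyNA(fit$coefficients)) {
      message("rank-deficient design: using ridge fallback")
      XtX <- crossprod(X) + diag(1e-8, ncol(X))
      beta <- solve(XtX, crossprod(X, y))
      sum((y - X %*% beta)^2)
    } else sum(fit$residuals^2)
  }
  max(log(rss(Xr) / rss(Xf)), 0)
}

#' Plug-in mutual information between two series (bits)
#'
#' `H(X) + H(Y) - H(X, Y)` on discretized series; symmetric and
#' nonnegative.
#'
#' @param x,y Equal-length numeric vectors.
#' @param params A [te_params()] (its `n_bins`/`strategy` are used).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, params = te_params()) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  sx <- as_symbols(x, params)
  sy <- as_symbols(y, params)
  base <- max(sx, sy) + 1L
  hxy <- shannon_entropy(sx + base * sy)
  max(shannon_entropy(sx) + shannon_entropy(sy) - hxy, 0)
}

#' Functional connectivity as absolute Pearson correlation
#'
#' @param x,y Equal-length numeric vectors.
#' @return `|cor(x, y)|` in `[0, 1]`; 0 with a warning if either series
#'   has zero variance.
#' @export
functional_connectivity <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warnf("zero-variance series: functional connectivity set to 0")
    return(0)
  }
  abs(stats::cor(x, y))
}

#' Channel-channel connectivity matrix by any supported method
#'
#' @param window Channels x samples numeric matrix (>= 2 channels).
#' @param method `"te"` (transfer entropy), `"gc"` (Granger causality),
#'   `"fc"` (absolute Pearson correlation) or `"mi"` (mutual
#'   information).
#' @param params A [te_params()] (used by te/mi).
#' @param gc_order Lag order for Granger causality.
#' @return A `"causal_matrix"`: list with `values` (N x N, zero
#'   diagonal; entry `(s, t)` = flow from channel `s` to channel `t`),
#'   `method`, and `symmetric` (`TRUE` for fc/mi).
#' @export
connectivity_matrix <- function(window, method = c("te", "gc", "fc", "mi"),
                                params = te_params(), gc_order = 2L) {
  method <- match.arg(method)
  if (!is.matrix(window) || nrow(window) < 2L)
    stopf("window must be a matrix with >= 2 channels")
  n <- nrow(window)
  vals <- matrix(0, n, n)
  symmetric <- method %in% c("fc", "mi")
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || (symmetric && s > t)) next
      vals[s, t] <- switch(method,
        te = transfer_entropy(window[s, ], window[t, ], params),
        gc = granger_causality(window[s, ], window[t, ], gc_order),
        mi = mutual_information(window[s, ], window[t, ], params),
        fc = functional_connectivity(window[s, ], window[t, ]))
      if (symmetric) vals[t, s] <- vals[s, t]
    }
  }
  structure(list(values = vals, method = toupper(method),
                 symmetric = symmetric),
            class = "causal_matrix")
}

#' @export
print.causal_matrix <- function(x, ...) {
  cat(sprintf("%s connectivity matrix (%d channels, %s)\n", x$method,
              nrow(x$values), if (x$symmetric) "symmetric" else "directed"))
  print(round(x$values, 4))
  invisible(x)
}

#' Sparsify a connectivity matrix into a graph
#'
#' Converts a `"causal_matrix"` into the adjacency used by the attention
#' layer. `"top_k_in"` keeps the `parameter` largest incoming weights per
#' target node (guaranteeing no isolated nodes), `"threshold"` keeps
#' entries strictly above `parameter`, `"density"` keeps the
#' `ceiling(parameter * N * (N-1))` globally largest off-diagonal
#' entries. Ties break toward the smaller source index, then the smaller
#' target index. Self-loops (recommended for attention, whose softmax
#' needs a non-empty neighbourhood) are added afterwards when requested.
#'
#' @param matrix A `"causal_matrix"` (or plain numeric matrix).
#' @param sparsify One of `"top_k_in"`, `"threshold"`, `"density"`.
#' @param parameter Rule parameter: k, threshold, or density in `(0, 1]`.
#' @param self_loops Add self-loops after sparsification (default `TRUE`).
#' @return A `"graph_spec"`: list with binary `adjacency` (entry
#'   `(s, t) = 1` means a directed edge `s -> t`) and `edge_weights`
#'   (original weights on kept edges, 0 elsewhere; self-loop weight 0).
#' @export
build_graph <- function(matrix, sparsify = c("top_k_in", "threshold",
                                             "density"),
                        parameter = 3, self_loops = TRUE) {
  sparsify <- match.arg(sparsify)
  vals <- if (inherits(matrix, "causal_matrix")) matrix$values else matrix
  n <- nrow(vals)
  adj <- matrix(0L, n, n)
  off <- which(row(vals) != col(vals))
  if (sparsify == "top_k_in") {
    k <- as.integer(parameter)
    if (k >= n) stopf("top_k_in requires k < n_channels")
    for (t in seq_len(n)) {
      w <- vals[, t]
      src <- setdiff(seq_len(n), t)
      ord <- src[order(-w[src], src)]
      adj[ord[seq_len(k)], t] <- 1L
    }
  } else if (sparsify == "threshold") {
    adj[off][vals[off] > parameter] <- 1L
  } else {
    if (parameter > 1 || parameter <= 0)
      stopf("density must lie in (0, 1]")
    m <- ceiling(parameter * n * (n - 1))
    ord <- off[order(-vals[off], (off - 1) %% n, (off - 1) %/% n)]
    adj[ord[seq_len(min(m, length(ord)))]] <- 1L
  }
  weights <- vals * adj
  if (self_loops) diag(adj) <- 1L
  structure(list(adjacency = adj, edge_weights = weights,
                 sparsify = sparsify, parameter = parameter,
                 self_loops = self_loops),
            class = "graph_spec")
}

#' Per-window connectivity graphs for a window set
#'
#' @param ws A `"window_set"`.
#' @param method Connectivity method passed to [connectivity_matrix()].
#' @param params A [te_params()].
#' @param sparsify,parameter,self_loops Passed to [build_graph()].
#' @param gc_order Lag order for Granger causality.
#' @return List of `"graph_spec"`, one per window.
#' @export
window_graphs <- function(ws, method = "te", params = te_params(),
                          sparsify = "top_k_in", parameter = 3,
                          self_loops = TRUE, gc_order = 2L) {
  stopifnot(inherits(ws, "window_set"))
  parameter <- min(parameter, ws$n_channels - 1L)
  lapply(ws$windows, function(w)
    build_graph(connectivity_matrix(w, method, params, gc_order),
                sparsify, parameter, self_loops))
}

#' Write / read a connectivity matrix as TSV
#'
#' @param cm A `"causal_matrix"`.
#' @param path Output file; header row holds channel names.
#' @param channel_names Optional channel names.
#' @return `write_causal_matrix` returns `path` invisibly;
#'   `read_causal_matrix` the numeric matrix.
#' @export
write_causal_matrix <- function(cm, path, channel_names = NULL) {
  vals <- if (inherits(cm, "causal_matrix")) cm$values else cm
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(vals)))
  colnames(vals) <- channel_names
  utils::write.table(format(vals, digits = 17, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_causal_matrix
#' @export
read_causal_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write a graph as a weighted edge-list TSV
#'
#' Columns `source`, `target`, `weight` with 0-based node indices.
#'
#' @param graph A `"graph_spec"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "graph_spec"))
  idx <- which(graph$adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(source = idx[, 1L] - 1L, target = idx[, 2L] - 1L,
                   weight = graph$edge_weights[idx])
  df <- df[order(df$source, df$target), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
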