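random_graph_adj <- function(n, p = 0.4, seed = 1) {
  cstgat:::with_seed(seed, {
    a <- matrix(rbinom(n * n, 1, p), n, n)
    diag(a) <- 1L
    a
  })
}

test_that("attention rows are probability vectors supported on in-neighbourhoods", {
  set.seed(20)
  for (trial in 1:20) {
    n <- sample(3:8, 1)
    adj <- random_graph_adj(n, seed = 600 + trial)
    head <- list(W = matrix(rnorm(3 * 5), 3, 5), a = rnorm(6))
    V <- matrix(rnorm(n * 5), n, 5)
    alpha <- attention_coefficients(V, adj, head)
    expect_equal(rowSums(alpha), rep(1, n), tolerance = 1e-12)
    support <- t(adj) != 0
    expect_true(all(alpha[!support] == 0))
    expect_true(all(alpha[support] > 0))
  }
})

test_that("single-neighbour and identical-feature attention degenerate correctly", {
  head <- list(W = diag(2), a = c(1, -1, 0.5, 0.5))
  # node 2 has only a self-loop
  adj <- matrix(c(1, 0, 0, 1), 2, 2)
  V <- matrix(rnorm(4), 2, 2)
  alpha <- attention_coefficients(V, adj, head)
  expect_equal(diag(alpha), c(1, 1))
  # identical features across nodes -> uniform rows over the support
  adjf <- matrix(1L, 3, 3)
  Vf <- matrix(rep(c(1, 2), each = 3), 3, 2)
  af <- attention_coefficients(Vf, adjf, head)
  expect_equal(af, matrix(1 / 3, 3, 3))
})

test_that("two-node attention matches a hand-evaluated softmax", {
  W <- matrix(c(1, 0, 0, 1), 2, 2)
  a <- c(0.5, -0.25, 1, 2)
  head <- list(W = W, a = a)
  V <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  adj <- matrix(1L, 2, 2)
  # z_i = v_i; e_ij = leakyrelu(a1.z_i + a2.z_j)
  lr <- function(x) ifelse(x >= 0, x, 0.2 * x)
  z <- V
  e <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    e[i, j] <- lr(sum(a[1:2] * z[i, ]) + sum(a[3:4] * z[j, ]))
  expected <- t(apply(e, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(attention_coefficients(V, adj, head), expected,
               tolerance = 1e-12)
})

test_that("isolated nodes are rejected by name", {
  adj <- matrix(0L, 3, 3); adj[1, 2] <- 1L; adj[2, 3] <- 1L
  head <- list(W = diag(2), a = rep(1, 4))
  expect_error(attention_coefficients(matrix(0, 3, 2), adj, head),
               "node 1")
})

test_that("multi-head fusion averages heads and reduces to sigma(Wv) for one node", {
  W <- matrix(rnorm(6), 2, 3)
  head <- list(W = W, a = rnorm(4))
  v <- matrix(rnorm(3), 1, 3)
  out <- gat_forward(v, matrix(1L, 1, 1), list(heads = list(head)))
  expect_equal(drop(out), ifelse(W %*% t(v) > 0, W %*% t(v),
                                 exp(W %*% t(v)) - 1)[, 1],
               tolerance = 1e-12)
  # identical heads average to the single-head output
  adj <- random_graph_adj(4, seed = 33)
  V <- matrix(rnorm(12), 4, 3)
  one <- gat_forward(V, adj, list(heads = list(head)))
  three <- gat_forward(V, adj, list(heads = list(head, head, head)))
  expect_equal(one, three, tolerance = 1e-12)
})

test_that("the attention layer is equivariant to node permutations", {
  set.seed(40)
  n <- 5
  adj <- random_graph_adj(n, seed = 41)
  V <- matrix(rnorm(n * 4), n, 4)
  gat <- list(heads = lapply(1:3, function(k)
    list(W = matrix(rnorm(8), 2, 4), a = rnorm(4))))
  out <- gat_forward(V, adj, gat)
  perm <- sample(n)
  out_p <- gat_forward(V[perm, ], adj[perm, perm], gat)
  expect_equal(out_p, out[perm, ], tolerance = 1e-12)
})

test_that("LSTM gate algebra matches closed forms at zero weights", {
  H <- 3
  p <- lapply(cstgat:::new_lstm_params(H, 2), function(x) x * 0)
  st <- lstm_step(c(1, -1), numeric(H), numeric(H), p)
  expect_equal(st$h, numeric(H))
  expect_equal(st$c, numeric(H))
  cc <- c(0.4, -0.2, 1)
  st2 <- lstm_step(c(1, -1), numeric(H), cc, p)
  expect_equal(st2$c, 0.5 * cc)
  expect_equal(st2$h, 0.5 * tanh(0.5 * cc))
})

test_that("scalar LSTM matches the exact hand evaluation, single and chained", {
  p <- lapply(cstgat:::new_lstm_params(1, 1), function(x) x * 0 + 0.5)
  p$bf <- p$bi <- p$bc <- p$bo <- 0
  st <- lstm_step(1, 0, 0, p)
  g <- 1 / (1 + exp(-0.5))
  expect_equal(st$c, g * tanh(0.5), tolerance = 1e-12)
  expect_equal(st$h, g * tanh(g * tanh(0.5)), tolerance = 1e-12)
  expect_equal(st$h, 0.174270, tolerance = 1e-5)
  # three chained steps against the scalar oracle
  seq_in <- c(1, 0.5, -1)
  h <- 0; cc <- 0
  for (m in seq_in) {
    o <- scalar_lstm_step(m, h, cc)
    st <- lstm_step(m, h, cc, p)
    expect_equal(st$h, o$h, tolerance = 1e-12)
    expect_equal(st$c, o$c, tolerance = 1e-12)
    h <- o$h; cc <- o$c
  }
  # bilstm on the 3-step scalar sequence reproduces both directions
  out <- bilstm_forward(matrix(seq_in, 3, 1), p, p)
  hf <- 0; cf <- 0
  for (m in seq_in) {s <- scalar_lstm_step(m, hf, cf); hf <- s$h; cf <- s$c}
  hb <- 0; cb <- 0
  for (m in rev(seq_in)) {s <- scalar_lstm_step(m, hb, cb); hb <- s$h; cb <- s$c}
  expect_equal(out, c(hf, hb), tolerance = 1e-12)
})

test_that("gate activations stay in (0,1) and cell growth is bounded", {
  set.seed(50)
  p <- cstgat:::new_lstm_params(4, 3)
  h <- rnorm(4); cc <- rnorm(4)
  for (t in 1:20) {
    st <- cstgat:::lstm_step_cached(rnorm(3), h, cc, p)
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$c) <= abs(cc) + 1 + 1e-12))
    h <- st$h; cc <- st$c
  }
})

test_that("bidirectional encoding handles length-1 and palindromic sequences", {
  set.seed(51)
  p <- cstgat:::new_lstm_params(3, 2)
  x1 <- matrix(rnorm(2), 1, 2)
  out <- bilstm_forward(x1, p, p)
  st <- lstm_step(x1[1, ], numeric(3), numeric(3), p)
  expect_equal(out, c(st$h, st$h))
  pal <- rbind(c(1, 2), c(0, 0), c(1, 2))
  outp <- bilstm_forward(pal, p, p)
  expect_equal(outp[1:3], outp[4:6])
  expect_error(bilstm_forward(matrix(nrow = 0, ncol = 2), p, p),
               "non-empty")
})

test_that("full forward pass yields proper probabilities, deterministically in eval mode", {
  set.seed(60)
  p <- init_params(4, 8, heads = 3, out_dim = 4, hidden = 5,
                   sub_windows = 2, seed = 61)
  feats <- matrix(rnorm(4 * 16), 4, 16)
  adj <- random_graph_adj(4, seed = 62)
  pr <- cstgat_forward(feats, adj, p)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr > 0 & pr < 1))
  expect_identical(pr, cstgat_forward(feats, adj, p))
  # tied classifier rows give exactly 0.5/0.5
  p$classifier$W[2, ] <- p$classifier$W[1, ]
  p$classifier$b[2] <- p$classifier$b[1]
  expect_equal(cstgat_forward(feats, adj, p), c(0.5, 0.5))
  # indivisible sub-window split is rejected with a suggestion
  p2 <- init_params(4, 5, heads = 2, out_dim = 4, hidden = 5,
                    sub_windows = 3, seed = 63)
  expect_error(cstgat_forward(matrix(rnorm(4 * 16), 4, 16), adj, p2),
               "divisible")
})

test_that("analytic gradients match central finite differences for all variants", {
  feats <- cstgat:::with_seed(70, matrix(rnorm(3 * 8), 3, 8))
  adj <- random_graph_adj(3, seed = 71)
  for (v in c("full", "gat_only", "bilstm_only")) {
    p <- init_params(3, 4, heads = 2, out_dim = 3, hidden = 4,
                     sub_windows = 2, variant = v, seed = 72)
    fwd <- cstgat:::model_forward(p, feats, adj, label = 1L)
    ana <- cstgat:::flatten_params(cstgat:::model_backward(p, fwd, 1L))
    num <- numeric_model_gradient(p, feats, adj, 1L)
    rel <- sqrt(sum((num - ana)^2)) / max(sqrt(sum(num^2)), 1e-12)
    expect_lt(rel, 1e-4)
  }
})

test_that("checkpoints round-trip bit-exactly with a JSON sidecar", {
  p <- init_params(3, 4, heads = 2, out_dim = 3, hidden = 4,
                   sub_windows = 2, seed = 80)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(p, f)
  back <- load_checkpoint(f)
  expect_identical(back, p)
  expect_true(file.exists(paste0(f, ".json")))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$heads, 2)
  expect_error(load_checkpoint(tempfile()), "not found")
})
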