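test_that("equal-width discretization splits at bin edges toward the lower bin", {
  expect_equal(discretize(c(0, 1, 2, 3), 2), c(0L, 0L, 1L, 1L))
  expect_equal(discretize(rep(5, 10), 4), integer(10))
  # interior edge value goes to the lower bin
  expect_equal(discretize(c(0, 2, 4), 2), c(0L, 0L, 1L))
})

test_that("equal-frequency discretization balances bin counts exactly", {
  x <- local({set.seed(99); rnorm(1000)})
  sym <- discretize(x, 4, "frequency")
  expect_equal(as.vector(table(sym)), rep(250L, 4))
  expect_message(discretize(rep(1, 50), 4, "frequency"), "constant")
  expect_error(discretize(c(1, 2), 4, "frequency"), "length")
})

test_that("plug-in entropy matches hand-computed values", {
  expect_equal(shannon_entropy(rep(3, 10)), 0)
  expect_equal(shannon_entropy(c(0, 1, 0, 1)), 1)
  expect_equal(shannon_entropy(c(0, 0, 0, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
})

test_that("transfer entropy equals the brute-force counting oracle on small cases", {
  set.seed(101)
  for (trial in 1:12) {
    n <- sample(100:800, 1)
    alphabet <- sample(2:3, 1)
    k <- sample(1:2, 1); l <- sample(1:2, 1)
    src <- sample(0:(alphabet - 1), n, replace = TRUE)
    tgt <- sample(0:(alphabet - 1), n, replace = TRUE)
    # add some coupling half the time so nontrivial values are covered
    if (trial %% 2 == 0) tgt <- c(tgt[1], src[-n])
    est <- transfer_entropy(src, tgt, te_params(k = k, l = l))
    expect_equal(est, brute_force_te(src, tgt, k, l), tolerance = 1e-12)
  }
})

test_that("deterministic copy chain carries exactly one bit forward and none back", {
  set.seed(7)
  n <- 40000
  src <- sample(0:1, n, replace = TRUE)
  tgt <- c(0L, src[-n])
  expect_equal(transfer_entropy(src, tgt), 1.0, tolerance = 0.02)
  expect_lt(transfer_entropy(tgt, src), 0.02)
})

test_that("transfer entropy on a constant target is exactly zero", {
  set.seed(8)
  src <- sample(0:2, 500, replace = TRUE)
  expect_equal(transfer_entropy(src, rep(1, 500)), 0)
})

test_that("mismatched or too-short inputs are rejected", {
  expect_error(transfer_entropy(1:10, 1:9), "equal length")
  expect_error(transfer_entropy(1:3, 1:3), "too short")
})

test_that("TE matrix is computed pairwise with a zero diagonal", {
  x <- simulate_var(two_channel_spec(), 2048, seed = 2)
  cm <- te_matrix(x)
  expect_s3_class(cm, "causal_matrix")
  expect_equal(diag(cm$values), c(0, 0))
  expect_equal(cm$values[1, 2], transfer_entropy(x[1, ], x[2, ]))
  expect_equal(cm$values[2, 1], transfer_entropy(x[2, ], x[1, ]))
  expect_false(cm$symmetric)
  # constant channels give a zero matrix
  cm0 <- te_matrix(matrix(1, 2, 300))
  expect_equal(cm0$values, matrix(0, 2, 2))
})

test_that("permuting channels permutes the connectivity matrix conformably", {
  x <- simulate_var(coupling_spec(3, data.frame(source = 0, target = 1,
                                                strength = 0.5)),
                    1024, seed = 4)
  perm <- c(3, 1, 2)
  for (m in c("te", "mi", "fc")) {
    cm <- connectivity_matrix(x, m)
    cmp <- connectivity_matrix(x[perm, ], m)
    expect_equal(cmp$values, cm$values[perm, perm], tolerance = 1e-12)
  }
})

test_that("Granger causality recovers direction and vanishes for white noise", {
  set.seed(12)
  n <- 4096
  src <- rnorm(n)
  noise_tgt <- rnorm(n)
  expect_lt(granger_causality(src, noise_tgt, order = 2), 0.01)
  tgt <- c(0, 0.9 * src[-n]) + rnorm(n, sd = 0.3)
  expect_gt(granger_causality(src, tgt), granger_causality(tgt, src))
  # constant source adds no information
  expect_equal(granger_causality(rep(2, n), tgt), 0, tolerance = 1e-10)
})

test_that("mutual information is symmetric, small for independent series, H(X) for identity", {
  set.seed(13)
  x <- rnorm(5000)
  y <- rnorm(5000)
  expect_lt(mutual_information(x, y), 0.02)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  sym <- discretize(x, 8)
  expect_equal(mutual_information(x, x), shannon_entropy(sym))
})

test_that("functional connectivity is absolute correlation with degenerate fallback", {
  x <- rnorm(100)
  expect_equal(functional_connectivity(x, 2 * x + 3), 1.0)
  expect_equal(functional_connectivity(x, -x), 1.0)
  set.seed(14)
  expect_lt(functional_connectivity(rnorm(10000), rnorm(10000)), 0.05)
  expect_warning(v <- functional_connectivity(rep(1, 50), rnorm(50)),
                 "zero-variance")
  expect_equal(v, 0)
})

test_that("graph sparsification rules keep the intended edges", {
  m <- matrix(c(0, 0.5, 0.1,
                0.2, 0, 0.4,
                0.3, 0.6, 0), 3, 3, byrow = TRUE)
  g <- build_graph(m, "top_k_in", 1, self_loops = FALSE)
  kept <- which(g$adjacency == 1L, arr.ind = TRUE)
  kept <- kept[order(kept[, 1], kept[, 2]), ]
  expect_equal(unname(kept), cbind(c(2, 3, 3), c(3, 1, 2)))
  expect_equal(g$edge_weights[3, 2], 0.6)
  # threshold above the maximum leaves an empty graph
  g2 <- build_graph(m, "threshold", 0.9, self_loops = FALSE)
  expect_equal(sum(g2$adjacency), 0)
  # density 1 keeps all off-diagonal edges
  g3 <- build_graph(m, "density", 1, self_loops = FALSE)
  expect_equal(sum(g3$adjacency), 6)
  expect_error(build_graph(m, "top_k_in", 3), "k <")
  # self-loops appear on the diagonal only
  g4 <- build_graph(m, "top_k_in", 1, self_loops = TRUE)
  expect_equal(diag(g4$adjacency), rep(1L, 3))
})

test_that("matrix and edge-list serialization round-trips", {
  x <- simulate_var(two_channel_spec(), 1024, seed = 6)
  cm <- te_matrix(x)
  f <- tempfile(fileext = ".tsv")
  write_causal_matrix(cm, f)
  expect_equal(read_causal_matrix(f), cm$values, tolerance = 1e-12)
  g <- build_graph(cm, "top_k_in", 1)
  f2 <- tempfile(fileext = ".tsv")
  write_edge_list(g, f2)
  el <- read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(el), sum(g$adjacency))
})

test_that("injected noise on the source never increases mean transfer entropy", {
  sp <- two_channel_spec()
  sds <- c(0, 0.5, 1, 2, 4)
  mean_te <- vapply(sds, function(sd) {
    mean(vapply(1:20, function(s) {
      x <- simulate_var(sp, 1024, seed = 300 + s)
      noisy <- x[1, ] + cstgat:::with_seed(500 + s, rnorm(1024, sd = sd))
      transfer_entropy(noisy, x[2, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_te) <= 0.005))
  expect_lt(mean_te[length(sds)], mean_te[1])
})
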