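test_that("hop counts match breadth-first search on chains and random graphs", {
  chain <- edge_list(c("A", "B"), c("B", "C"))
  d <- ppin_shortest_paths(chain, c("A", "B", "C"))
  expect_equal(d["A", "C"], 2)
  expect_equal(d["A", "B"], 1)
  expect_equal(unname(diag(d)), rep(0, 3))

  two <- edge_list(c("A", "C"), c("B", "D"))
  d2 <- ppin_shortest_paths(two, c("A", "B", "C", "D"))
  expect_equal(d2["A", "C"], Inf)
  expect_equal(d2["B", "D"], Inf)

  # empty graph: all off-diagonals infinite, no error
  d0 <- ppin_shortest_paths(edge_list(), c("A", "B"))
  expect_equal(d0["A", "B"], Inf)

  # Erdos-Renyi graph vs BFS oracle on every pair
  set.seed(21)
  genes <- paste0("n", 1:50)
  pairs <- which(upper.tri(diag(50)), arr.ind = TRUE)
  on <- pairs[runif(nrow(pairs)) < 0.08, , drop = FALSE]
  er <- edge_list(genes[on[, 1]], genes[on[, 2]])
  expect_equal(ppin_shortest_paths(er, genes), bfs_distances(er, genes))
})

test_that("global scope walks through intermediates outside the target set", {
  # A - X - B where X is not a target gene
  e <- edge_list(c("A", "X"), c("X", "B"))
  expect_message(d_sub <- ppin_shortest_paths(e, c("A", "B"), scope = "subnet"),
                 "dropped")
  d_glob <- ppin_shortest_paths(e, c("A", "B"), scope = "global")
  expect_equal(d_sub["A", "B"], Inf)
  expect_equal(d_glob["A", "B"], 2)
})

test_that("the path-extension probability solves the geometric-series constraint", {
  z <- solve_zeta()
  expect_equal(z / (1 - z), 1, tolerance = 1e-12)
  expect_equal(z, 0.5)
  # bisection oracle
  lo <- 1e-9; hi <- 1 - 1e-9
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (mid / (1 - mid) - 1 > 0) hi <- mid else lo <- mid
  }
  expect_equal(z, (lo + hi) / 2, tolerance = 1e-10)
})

test_that("path confidences follow the geometric ladder", {
  expect_equal(path_confidence(1), 1)
  expect_equal(path_confidence(2:4), c(0.5, 0.25, 0.125))
  expect_equal(path_confidence(Inf), 0)
  expect_error(path_confidence(0), "self-pairs")
  # partial sums of c_d over d >= 2 approach 1 from below
  partial <- cumsum(path_confidence(2:40))
  expect_true(all(diff(partial) > 0))
  expect_true(all(partial <= 1))
  expect_equal(partial[length(partial)], 1, tolerance = 1e-9)
})

test_that("W adds the correlation and the path-confidence terms", {
  X <- random_expression(6, 12, seed = 22)
  genes <- rownames(X)
  ppin <- edge_list(genes[c(1, 2, 3, 4)], genes[c(2, 3, 4, 5)])  # chain g1..g5
  D <- ppin_shortest_paths(ppin, genes)
  W <- as.matrix(combine_correlation(X, D))

  # hand-written Pearson formula oracle + c lookup
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  for (i in 1:5) for (j in (i + 1):6) {
    cd <- if (is.finite(D[i, j])) 0.5^(D[i, j] - 1) else 0
    expect_equal(W[i, j], pearson(X[i, ], X[j, ]) + cd, tolerance = 1e-10)
  }
  # disconnected pair gets only the correlation term (g6 is isolated)
  expect_equal(W[1, 6], pearson(X[1, ], X[6, ]), tolerance = 1e-10)
  expect_equal(unname(diag(W)), rep(0, 6))
})

test_that("zero-variance genes get zero correlation with a warning", {
  X <- random_expression(3, 8, seed = 23)
  X[2, ] <- 5
  D <- matrix(Inf, 3, 3); diag(D) <- 0; dimnames(D) <- list(rownames(X), rownames(X))
  expect_warning(W <- combine_correlation(X, D), "zero-variance")
  expect_equal(as.matrix(W)[2, 1], 0)
})

test_that("transition matrix is the damped row-normalized positive part", {
  W2 <- scored_network(matrix(c(0, 1, 1, 0), 2, 2), score_range = c(0, 1))
  Tm <- build_transition(W2, damping = 0.85)$T
  expect_equal(unname(Tm), matrix(c(0.075, 0.925, 0.925, 0.075), 2, 2))

  z <- scored_network(matrix(0, 3, 3), score_range = c(0, 1))
  expect_equal(unname(build_transition(z, 0.85)$T), matrix(1 / 3, 3, 3))

  Wr <- random_network(7, seed = 24, lo = -1, hi = 1)
  Tr <- build_transition(Wr, 0.9)$T
  expect_lt(max(abs(rowSums(Tr) - 1)), 1e-12)
  expect_true(all(Tr >= 0))
  # analytic decomposition: damped share plus teleport share
  Wp <- pmax(as.matrix(Wr), 0)
  i <- 1
  expect_equal(Tr[i, ], 0.9 * Wp[i, ] / sum(Wp[i, ]) + 0.1 / 7,
               tolerance = 1e-12)

  expect_error(build_transition(Wr, 0.4), "damping")
  expect_error(build_transition(Wr, 1), "damping")
})

test_that("repeated squaring reaches the stationary distribution", {
  un <- matrix(1 / 4, 4, 4)
  expect_equal(unname(as.matrix(converge_walk(un))), un)

  set.seed(25)
  Tm <- matrix(runif(9, 0.05, 1), 3, 3)
  Tm <- Tm / rowSums(Tm)
  T_hat <- as.matrix(converge_walk(Tm, tol = 1e-12))
  # eigen-decomposition oracle: leading left eigenvector
  ev <- eigen(t(Tm))
  pi_vec <- Re(ev$vectors[, which.max(Re(ev$values))])
  pi_vec <- pi_vec / sum(pi_vec)
  for (r in 1:3) expect_equal(unname(T_hat[r, ]), pi_vec, tolerance = 1e-9)
  # stationarity
  expect_lt(max(abs(T_hat %*% Tm - T_hat)), 1e-9)

  expect_error(converge_walk(matrix(c(0, 1, 0, 0), 2, 2)), "stochastic")
})

test_that("confidence scores combine direct and propagated evidence", {
  W <- random_network(6, seed = 26, lo = -0.5, hi = 1.5)
  Wm <- as.matrix(W)
  I6 <- diag(6)
  # identity walk: C reduces to normalized W
  C_id <- confidence_scores(W, I6)
  expect_equal(as.matrix(C_id), as.matrix(minmax_normalize(W)),
               tolerance = 1e-12)

  # random walk matrix: product term vs triple-loop brute force
  Tm <- build_transition(W, 0.85)$T
  T_hat <- as.matrix(converge_walk(Tm))
  C <- as.matrix(confidence_scores(W, T_hat))
  raw <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    acc <- 0
    for (k in 1:6) acc <- acc + Wm[i, k] * T_hat[k, j]
    raw[i, j] <- 0.5 * Wm[i, j] + 0.5 * acc
  }
  raw <- (raw + t(raw)) / 2
  diag(raw) <- 0
  off <- row(raw) != col(raw)
  expected <- (raw - min(raw[off])) / (max(raw[off]) - min(raw[off]))
  diag(expected) <- 0
  expect_equal(unname(C), unname(expected), tolerance = 1e-10)
  expect_equal(range(C), c(0, 1))
})

test_that("confidence scores are equivariant under gene reordering", {
  X <- random_expression(8, 10, seed = 27)
  genes <- rownames(X)
  ppin <- edge_list(genes[c(1, 2, 3, 5, 6)], genes[c(2, 3, 4, 6, 7)])
  C1 <- as.matrix(extend_ppin_scores(X, ppin)$C)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  C2 <- as.matrix(extend_ppin_scores(X[perm, ], ppin)$C)
  expect_equal(C2, C1[perm, perm], tolerance = 1e-9)
})

test_that("extended PPIN is the thresholded confidence network", {
  C <- minmax_normalize(random_network(9, seed = 28))
  expect_equal(nrow(extend_ppin(C, 1 + 1e-9)), 0)
  got <- extend_ppin(C, 0.5)
  s <- as.matrix(C)
  cnt <- sum(s[upper.tri(s)] >= 0.5)
  expect_equal(nrow(got), cnt)
  expect_true(all(got$weight >= 0.5))
})

test_that("extension recovers held-out edges better than a degree-matched baseline", {
  scn <- synthetic_scenario(I = 30, J = 40, L = 4, overlap_fraction = 0,
                            ppin_retention = 1, ppin_noise = 0, seed = 9)
  ge <- generate_expression(scn)
  nets <- generate_truth_and_ppin(scn, ge$membership)
  rec <- suppressMessages(
    edge_holdout_recovery(ge$X, nets$ppin, folds = 10, repeats = 10, seed = 5))
  expect_equal(nrow(rec), 10)
  expect_gt(mean(rec$recovery - rec$baseline_recovery), 0)
})
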