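test_that("experiment clustering selects and recovers column components", {
  X <- random_expression(5, 12, seed = 51)
  m1 <- cluster_experiments(X, K_max = 1)
  expect_equal(m1$K, 1L)
  expect_equal(m1$weights, 1)
  expect_equal(unname(m1$assignment), rep(1L, 12))

  # columns from two well-separated Gaussians
  set.seed(52)
  I <- 6; J <- 60
  lab <- rep(1:2, each = 30)
  mu <- rbind(rnorm(I, -3), rnorm(I, 3))
  Xc <- sapply(seq_len(J), function(j) mu[lab[j], ] + rnorm(I))
  dimnames(Xc) <- list(paste0("g", 1:I), paste0("e", 1:J))
  m2 <- cluster_experiments(Xc, K_max = 4, seed = 2)
  expect_equal(m2$K, 2L)
  expect_equal(sum(m2$weights), 1)
  expect_equal(unname(m2$weights), unname(lengths(m2$partitions) / J))
  # partition matches generation labels
  tab <- table(m2$assignment, lab)
  expect_equal(sum(apply(tab, 1, max)), J)
})

test_that("parent candidates respect pathways and the top-k cap", {
  # disjoint hard pathways: candidates never cross blocks
  tau <- matrix(0, 6, 2, dimnames = list(paste0("g", 1:6), NULL))
  tau[1:3, 1] <- 1; tau[4:6, 2] <- 1
  R <- random_network(6, seed = 53)
  cands <- parent_candidates(tau, R, k = 5)
  for (i in 1:3) expect_true(all(cands[[i]] %in% paste0("g", 1:3)))
  for (i in 4:6) expect_true(all(cands[[i]] %in% paste0("g", 4:6)))
  expect_false(any(vapply(seq_along(cands),
                          function(i) names(cands)[i] %in% cands[[i]], TRUE)))

  # one shared pathway, no truncation: everyone else is a candidate
  tau1 <- matrix(1, 6, 1, dimnames = list(paste0("g", 1:6), NULL))
  c_all <- parent_candidates(tau1, R, k = 5)
  for (i in 1:6) expect_setequal(c_all[[i]], setdiff(paste0("g", 1:6),
                                                     paste0("g", i)))

  # random memberships: brute-force set construction oracle
  set.seed(54)
  tau_r <- matrix(runif(8 * 3), 8, 3, dimnames = list(paste0("g", 1:8), NULL))
  tau_r <- tau_r / rowSums(tau_r)
  Rr <- random_network(8, seed = 55)
  k <- 3
  got <- parent_candidates(tau_r, Rr, k = k, membership_cutoff = 0.1)
  Rm <- as.matrix(Rr)
  member <- tau_r >= 0.1
  for (i in 1:8) {
    share <- vapply(1:8, function(j) j != i && any(member[i, ] & member[j, ]),
                    TRUE)
    js <- which(share)
    if (length(js) > k) js <- js[order(-Rm[js, i], js)][1:k]
    expect_setequal(got[[i]], paste0("g", sort(js)))
  }
})

test_that("the empty-parent local score matches numeric quadrature", {
  set.seed(56)
  y <- rnorm(5)
  X <- rbind(y, rnorm(5))
  rownames(X) <- c("child", "other")
  colnames(X) <- paste0("e", 1:5)
  mix <- cluster_experiments(X, K_max = 1)
  got <- local_score(X, mix, "child", character())
  # quadrature over (mean, variance) of the conjugate model
  inner <- function(s2) {
    vapply(s2, function(v) {
      f <- function(b0) {
        vapply(b0, function(m)
          dnorm(m, 0, sqrt(v)) * prod(dnorm(y, m, sqrt(v))), 0)
      }
      stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value *
        (1 / gamma(1)) * v^(-2) * exp(-1 / v)   # InvGamma(1, 1) density
    }, 0)
  }
  oracle <- stats::integrate(inner, 0, Inf, rel.tol = 1e-9)$value
  expect_equal(got, log(oracle), tolerance = 1e-6)
})

test_that("local scores are exchangeable within partitions and detect dependence", {
  set.seed(57)
  n <- 40
  parent <- rnorm(n)
  child <- 0.9 * parent + rnorm(n, 0, 0.3)
  X <- rbind(parent = parent, child = child)
  colnames(X) <- paste0("e", 1:n)
  mix <- cluster_experiments(X, K_max = 1)
  s_dep <- local_score(X, mix, "child", "parent")
  s_ind <- local_score(X, mix, "child", character())
  expect_gt(s_dep, s_ind)

  # permuting experiments within a partition leaves the score unchanged
  perm <- sample(n)
  Xp <- X[, perm]
  mixp <- cluster_experiments(Xp, K_max = 1)
  expect_equal(local_score(Xp, mixp, "child", "parent"), s_dep,
               tolerance = 1e-10)

  expect_error(local_score(X, mix, "child", "child"), "own parent")
})

test_that("prior-dominated partitions warn and caching is consistent", {
  X <- random_expression(6, 4, seed = 58)
  mix <- cluster_experiments(X, K_max = 1)
  expect_warning(local_score(X, mix, 1, 2:6), "prior-dominated")
  cache <- new.env()
  a <- local_score(X, mix, 1, c(3, 2), cache = cache)
  b <- local_score(X, mix, 1, c(2, 3), cache = cache)  # order-insensitive key
  expect_identical(a, b)
  expect_equal(length(ls(cache)), 1L)
})

test_that("the structure prior penalizes missing high-confidence edges", {
  R <- random_network(5, seed = 59)
  Rm <- as.matrix(R)
  full <- matrix(1, 5, 5); diag(full) <- 0
  expect_equal(structure_log_prior(full, R), 0)
  empty <- matrix(0, 5, 5)
  off <- row(empty) != col(empty)
  expect_equal(structure_log_prior(empty, R), -sum(Rm[off]))
  set.seed(60)
  A <- matrix(rbinom(25, 1, 0.4), 5, 5); diag(A) <- 0
  acc <- 0
  for (u in 1:5) for (v in 1:5) if (u != v) acc <- acc - Rm[u, v] * (1 - A[u, v])
  expect_equal(structure_log_prior(A, R), acc, tolerance = 1e-12)
})

test_that("MCMC respects the DAG constraint and candidate sets", {
  set.seed(61)
  X <- random_expression(5, 15, seed = 61)
  mix <- cluster_experiments(X, K_max = 1)
  genes <- rownames(X)
  cands <- full_candidates(genes)
  samp <- mcmc_run(X, mix, cands, n_iter = 400, seed = 7, burn_in = 0,
                   thin = 1)
  is_acyclic <- function(A) {
    M <- A
    for (k in seq_len(nrow(A))) M <- ((M %*% A + M) > 0) * 1
    sum(diag(M)) == 0
  }
  expect_true(all(vapply(samp$draws, is_acyclic, TRUE)))

  # empty candidate sets: chain never leaves the empty graph
  none <- structure(lapply(genes, function(g) character()), names = genes)
  s0 <- mcmc_run(X, mix, none, n_iter = 50, seed = 8, burn_in = 0, thin = 1)
  expect_equal(max(s0$edge_freq), 0)
  expect_equal(s0$acceptance_rate, 0)

  # restricted candidates: edges only ever come from candidate parents
  some <- structure(list(character(), "g1", "g2", character(), "g1"),
                    names = genes)
  s1 <- mcmc_run(X, mix, some, n_iter = 400, seed = 9, burn_in = 0, thin = 1)
  allowed <- matrix(0, 5, 5, dimnames = list(genes, genes))
  allowed["g1", "g2"] <- allowed["g2", "g3"] <- allowed["g1", "g5"] <- 1
  expect_true(all(s1$edge_freq[allowed == 0] == 0))
})

test_that("edge frequencies equal the counting oracle over full draws", {
  X <- random_expression(4, 12, seed = 62)
  mix <- cluster_experiments(X, K_max = 1)
  samp <- mcmc_run(X, mix, full_candidates(rownames(X)), n_iter = 300,
                   seed = 10, burn_in = 0, thin = 1)
  expect_equal(length(samp$draws), 300)
  expect_equal(samp$edge_freq, Reduce(`+`, samp$draws) / 300)
})

test_that("chain marginals match the exhaustive 3-gene posterior", {
  set.seed(63)
  X <- matrix(rnorm(3 * 20), 3, 20,
              dimnames = list(c("A", "B", "C"), paste0("e", 1:20)))
  X["B", ] <- 0.9 * X["A", ] + rnorm(20, 0, 0.3)
  mix <- cluster_experiments(X, K_max = 1)
  exact <- exact_3node_marginals(X, mix)
  expect_equal(exact$n_dags, 25)
  samp <- mcmc_run(X, mix, full_candidates(rownames(X)), n_iter = 50000,
                   seed = 3)
  expect_lt(max(abs(samp$edge_freq - exact$marginals)), 0.05)
})

test_that("the DAG score decomposes into local scores plus the prior", {
  X <- random_expression(6, 20, seed = 64)
  mix <- cluster_experiments(X, K_max = 1)
  R <- random_network(6, seed = 65)
  samp <- mcmc_run(X, mix, full_candidates(rownames(X)), R = R,
                   n_iter = 200, seed = 11, burn_in = 0, thin = 50)
  for (A in samp$draws) {
    total <- sum(vapply(1:6, function(v)
      local_score(X, mix, v, which(A[, v] == 1)), 0)) +
      structure_log_prior(A, R)
    expect_true(is.finite(total))
    # decomposability: deleting one edge changes only that child's term
    idx <- which(A == 1, arr.ind = TRUE)
    if (nrow(idx)) {
      u <- idx[1, 1]; v <- idx[1, 2]
      A2 <- A; A2[u, v] <- 0
      total2 <- sum(vapply(1:6, function(g)
        local_score(X, mix, g, which(A2[, g] == 1)), 0)) +
        structure_log_prior(A2, R)
      delta_local <- local_score(X, mix, v, which(A2[, v] == 1)) -
        local_score(X, mix, v, which(A[, v] == 1))
      expect_equal(total2 - total, delta_local - as.matrix(R)[u, v],
                   tolerance = 1e-10)
    }
  }
})

test_that("an informative structure prior never hurts skeleton recovery", {
  res <- t(vapply(1:5, function(s) {
    d <- generate_dag_data(I = 10, n = 40, edge_prob = 0.25, seed = s + 20)
    mix <- cluster_experiments(d$X, K_max = 1)
    genes <- rownames(d$X)
    cands <- full_candidates(genes)
    Rt <- matrix(0, 10, 10, dimnames = list(genes, genes))
    idx <- which(d$adj == 1, arr.ind = TRUE)
    Rt[idx] <- 1
    Rt <- pmax(Rt, t(Rt))
    f1_of <- function(R) {
      ch <- lapply(1:3, function(m)
        mcmc_run(d$X, mix, cands, R = R, n_iter = 1500, seed = s * 31 + m))
      avg <- model_average(ch, 0.5)
      suppressWarnings(
        evaluate_network(directed_to_undirected(avg$edges), d$truth))$f1
    }
    c(flat = f1_of(NULL),
      informed = f1_of(scored_network(Rt, score_range = c(0, 1))))
  }, c(flat = 0, informed = 0)))
  expect_true(all(res[, "informed"] >= res[, "flat"] - 1e-12))
})

test_that("model averaging pools chains by retained length", {
  X <- random_expression(4, 12, seed = 66)
  mix <- cluster_experiments(X, K_max = 1)
  cands <- full_candidates(rownames(X))
  ch <- lapply(1:3, function(m)
    mcmc_run(X, mix, cands, n_iter = 200, seed = m, burn_in = 0, thin = 1))
  avg <- model_average(ch, threshold = 0.5)
  pooled <- Reduce(`+`, lapply(ch, function(s) s$edge_freq * s$n_counted)) /
    sum(vapply(ch, `[[`, 0L, "n_counted"))
  expect_equal(as.matrix(avg$scores), pooled)
  expect_true(all(avg$edges$confidence >= 0.5))
  # all draws identical -> confidence 1 for present edges
  one <- ch[[1]]
  one$draws <- list(one$draws[[1]])
  one$edge_freq <- one$draws[[1]]
  one$n_counted <- 1L
  avg1 <- model_average(one)
  expect_true(all(avg1$edges$confidence == 1))
})
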