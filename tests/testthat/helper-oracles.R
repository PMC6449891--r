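# Independent oracles and small fixture builders shared across tests.

# Hand-written breadth-first search hop counts over an undirected edge list.
bfs_distances <- function(edges, genes) {
  n <- length(genes)
  adj <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(edges))) {
    a <- match(edges$gene_a[r], genes); b <- match(edges$gene_b[r], genes)
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, n, n, dimnames = list(genes, genes))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

# Cluster purity of argmax labels against generating labels.
purity <- function(tau, truth_labels) {
  lab <- apply(tau, 1, which.max)
  sum(apply(table(lab, truth_labels), 1, max)) / length(lab)
}

# Direct (non-log) multivariate normal density with diagonal covariance.
dens_diag <- function(x, mu, v) {
  prod(exp(-(x - mu)^2 / (2 * v)) / sqrt(2 * pi * v))
}

# Random symmetric score network over n genes.
random_network <- function(n, seed, lo = 0, hi = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, lo, hi), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  scored_network(m, symmetric = TRUE, score_range = c(lo, hi))
}

# Random expression matrix.
random_expression <- function(I, J, seed) {
  set.seed(seed)
  matrix(stats::rnorm(I * J), I, J,
         dimnames = list(paste0("g", seq_len(I)), paste0("e", seq_len(J))))
}

# All-pairs candidate sets over a gene vector.
full_candidates <- function(genes) {
  structure(lapply(genes, function(g) setdiff(genes, g)), names = genes)
}

# Exhaustive enumeration of all DAGs on 3 labelled nodes with their
# decomposable scores; returns exact posterior edge marginals.
exact_3node_marginals <- function(X, mix, R = NULL) {
  genes <- rownames(X)
  edges6 <- which(diag(3) == 0, arr.ind = TRUE)
  is_acyclic <- function(A) {
    M <- A
    for (k in 1:3) M <- ((M %*% A + M) > 0) * 1
    sum(diag(M)) == 0
  }
  adjs <- list(); scores <- c()
  for (mask in 0:63) {
    A <- matrix(0, 3, 3, dimnames = list(genes, genes))
    A[cbind(edges6[, 1], edges6[, 2])] <- as.integer(intToBits(mask))[1:6]
    if (!is_acyclic(A)) next
    sc <- sum(vapply(1:3, function(v)
      local_score(X, mix, v, which(A[, v] == 1)), 0))
    if (!is.null(R)) sc <- sc + structure_log_prior(A, R)
    adjs[[length(adjs) + 1]] <- A
    scores <- c(scores, sc)
  }
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  list(marginals = Reduce(`+`, Map(`*`, adjs, w)), n_dags = length(adjs))
}
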