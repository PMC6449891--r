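# Extension of sparse protein-protein interaction networks.
#
# A missing interaction between proteins i and i' is scored from the shortest
# path between them in the known PPIN: a d-hop path gets confidence
# c_d = zeta^(d-1), where zeta solves sum_{d>=1} zeta^d = zeta/(1-zeta) = 1
# (i.e. zeta = 1/2), so c_1 = 1 and confidence halves per extra hop. The path
# confidence is added to the Pearson expression correlation to give the
# evidence graph W; a damped random walk on W contributes topological
# connectivity; the final confidence is C = 0.5 W + 0.5 W T-hat, symmetrized
# and min-max normalized.

#' Hop-count shortest paths between genes in a PPIN
#'
#' The PPIN is treated as unweighted and undirected. Distances may be computed
#' on a larger global network and then projected onto the target gene set
#' (`scope = "global"`), or on the subgraph induced by the target genes
#' (`scope = "subnet"`, the default).
#'
#' @param ppin an [edge_list()].
#' @param genes character vector: the target gene set (row/column order of the
#'   result). Genes absent from the PPIN are isolated vertices.
#' @param scope `"subnet"` restricts the graph to `genes` before computing
#'   paths; `"global"` walks through intermediate genes outside the target set.
#' @return symmetric matrix of hop counts with `Inf` for disconnected pairs
#'   and 0 on the diagonal.
#' @export
ppin_shortest_paths <- function(ppin, genes, scope = c("subnet", "global")) {
  scope <- match.arg(scope)
  if (scope == "subnet") ppin <- restrict_edges(ppin, genes)
  verts <- union(genes, union(ppin$gene_a, ppin$gene_b))
  if (nrow(ppin)) {
    g <- igraph::graph_from_data_frame(
      ppin[, c("gene_a", "gene_b")], directed = FALSE,
      vertices = data.frame(name = verts))
    d <- igraph::distances(g, v = genes, to = genes, weights = NA)
  } else {
    d <- matrix(Inf, length(genes), length(genes),
                dimnames = list(genes, genes))
    diag(d) <- 0
  }
  d[genes, genes, drop = FALSE]
}

#' Per-hop path-extension probability zeta
#'
#' Solves `sum_{d=1..Inf} zeta^d = zeta / (1 - zeta) = 1` on (0, 1) by
#' root-finding; the root is 1/2.
#'
#' @return the solution zeta.
#' @export
solve_zeta <- function() {
  stats::uniroot(function(z) z / (1 - z) - 1, c(1e-12, 1 - 1e-12),
                 tol = .Machine$double.eps)$root
}

#' Confidence of a transitive interaction from its path length
#'
#' `c_d = zeta^(d - 1)`: 1 for direct (1-hop) interactions, decaying
#' geometrically per extra hop, 0 for disconnected pairs (`d = Inf`).
#'
#' @param d hop count(s), `>= 1` or `Inf`.
#' @param zeta per-hop extension probability (default [solve_zeta()]).
#' @return numeric vector of confidences in `[0, 1]`.
#' @export
path_confidence <- function(d, zeta = solve_zeta()) {
  if (any(d <= 0 & is.finite(d)))
    stop("path_confidence: d must be >= 1 (self-pairs are excluded)")
  out <- zeta^(d - 1)
  out[is.infinite(d)] <- 0
  out
}

#' Combine expression correlation with transitive path confidence (graph W)
#'
#' `W[i, j] = rho[i, j] + c_{d[i, j]}` where rho is the Pearson correlation of
#' the two genes' expression profiles across experiments and c is the
#' geometric path confidence. Genes with zero expression variance get rho = 0
#' with a warning. The diagonal is zeroed.
#'
#' @param X genes x experiments expression matrix.
#' @param D hop-count matrix from [ppin_shortest_paths()] (same gene order).
#' @param zeta per-hop extension probability.
#' @return a symmetric [scored_network()] (entries in `[-1, 2]`).
#' @export
combine_correlation <- function(X, D, zeta = solve_zeta()) {
  stopifnot(nrow(X) == nrow(D), nrow(D) == ncol(D))
  if (!is.null(rownames(X)) && !is.null(rownames(D)) &&
      !identical(rownames(X), rownames(D)))
    stop("combine_correlation: gene orders of X and D differ")
  sds <- apply(X, 1, stats::sd)
  rho <- suppressWarnings(stats::cor(t(X)))
  if (any(sds == 0)) {
    warning(sprintf("combine_correlation: %d zero-variance gene(s); their correlations set to 0",
                    sum(sds == 0)))
  }
  rho[!is.finite(rho)] <- 0
  cmat <- matrix(path_confidence(pmax(D, 1), zeta), nrow(D), ncol(D))
  W <- rho + cmat
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- dimnames(D)
  if (is.null(rownames(W))) dimnames(W) <- list(rownames(X), rownames(X))
  scored_network(W, symmetric = TRUE, score_range = c(-1, 2))
}

#' Damped random-walk transition matrix on the evidence graph
#'
#' `T[i, j] = damping * W+[i, j] / sum_j W+[i, j] + (1 - damping) / I`, where
#' `W+` is W clipped at 0 (transition mass must be nonnegative; the signed W
#' is kept for the confidence combination itself). Rows with no positive mass
#' become uniform (the standard dangling-node fix). Rows sum to 1.
#'
#' @param W a symmetric [scored_network()].
#' @param damping damping factor in (0.5, 1); default 0.85.
#' @return list with the row-stochastic matrix `T` and `damping`, class
#'   `transition_matrix`.
#' @export
build_transition <- function(W, damping = 0.85) {
  if (damping <= 0.5 || damping >= 1)
    stop("build_transition: damping must lie in (0.5, 1)")
  Wm <- pmax(as.matrix(W), 0)
  I <- nrow(Wm)
  rs <- rowSums(Wm)
  Tm <- matrix((1 - damping) / I, I, I, dimnames = dimnames(Wm))
  pos <- rs > 0
  if (any(pos))
    Tm[pos, ] <- damping * Wm[pos, , drop = FALSE] / rs[pos] + (1 - damping) / I
  if (any(!pos)) Tm[!pos, ] <- 1 / I
  structure(list(T = Tm, damping = damping), class = "transition_matrix")
}

#' Random-walk equilibrium by repeated squaring
#'
#' Computes `T-hat = lim_k T^k` by squaring the transition matrix until
#' successive powers agree within `tol` (the power sequence of a damped walk
#' converges quadratically).
#'
#' @param trans a `transition_matrix` from [build_transition()] (or a plain
#'   row-stochastic matrix).
#' @param tol max absolute difference between successive powers (default 1e-9).
#' @param max_iter maximum number of squarings (default 64).
#' @return the equilibrium matrix as a [scored_network()] (`symmetric = FALSE`;
#'   rows sum to 1).
#' @export
converge_walk <- function(trans, tol = 1e-9, max_iter = 64) {
  Tm <- if (inherits(trans, "transition_matrix")) trans$T else trans
  if (max(abs(rowSums(Tm) - 1)) > 1e-6)
    stop("converge_walk: transition matrix is not row-stochastic")
  cur <- Tm
  for (k in seq_len(max_iter)) {
    nxt <- cur %*% cur
    delta <- max(abs(nxt - cur))
    cur <- nxt
    if (delta < tol)
      return(scored_network(cur, symmetric = FALSE, score_range = c(0, 1)))
  }
  stop(sprintf("converge_walk: no convergence in %d squarings (last delta %.3g)",
               max_iter, delta))
}

#' Final extended-PPIN confidence scores C
#'
#' `C[i, j] = 0.5 * W[i, j] + 0.5 * sum_k W[i, k] T-hat[k, j]`: the direct
#' evidence plus the random-walk-propagated evidence. The product term is
#' asymmetric, so C is symmetrized as `(C + t(C)) / 2` (all downstream uses
#' are undirected) and min-max normalized to `[0, 1]` with zero diagonal.
#'
#' @param W evidence graph from [combine_correlation()].
#' @param T_hat equilibrium matrix from [converge_walk()].
#' @return a symmetric, normalized [scored_network()].
#' @export
confidence_scores <- function(W, T_hat) {
  Wm <- as.matrix(W); Th <- as.matrix(T_hat)
  stopifnot(nrow(Wm) == nrow(Th), ncol(Wm) == ncol(Th))
  C <- 0.5 * Wm + 0.5 * (Wm %*% Th)
  C <- (C + t(C)) / 2
  diag(C) <- 0
  minmax_normalize(scored_network(C, symmetric = TRUE,
                                  score_range = range(C)))
}

#' Threshold confidence scores into the extended PPIN
#'
#' @param C normalized confidence network from [confidence_scores()].
#' @param cutoff minimum C score (default 0.5, the conventional trade-off
#'   between precision and recall).
#' @return an [edge_list()] of the extended PPIN.
#' @export
extend_ppin <- function(C, cutoff = 0.5) {
  threshold_network(C, cutoff)
}

#' Run the whole PPIN-extension stage
#'
#' Shortest paths -> W (correlation + path confidence) -> damped random walk
#' -> confidence C, in one call.
#'
#' @param X genes x experiments expression matrix (defines the gene universe).
#' @param ppin an [edge_list()] of known interactions.
#' @param damping random-walk damping factor (default 0.85).
#' @param zeta per-hop extension probability.
#' @param scope `"subnet"` or `"global"` (see [ppin_shortest_paths()]).
#' @param tol,max_iter convergence controls for [converge_walk()].
#' @return list with `D` (hop counts), `W`, `T_hat` and `C`.
#' @export
extend_ppin_scores <- function(X, ppin, damping = 0.85, zeta = solve_zeta(),
                               scope = c("subnet", "global"), tol = 1e-9,
                               max_iter = 64) {
  scope <- match.arg(scope)
  genes <- rownames(X)
  D <- ppin_shortest_paths(ppin, genes, scope)
  W <- combine_correlation(X, D, zeta)
  Tm <- build_transition(W, damping)
  T_hat <- converge_walk(Tm, tol, max_iter)
  C <- confidence_scores(W, T_hat)
  list(D = D, W = W, T_hat = T_hat, C = C)
}
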