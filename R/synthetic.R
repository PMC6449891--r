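# Synthetic data with the statistical structure the method assumes: pathway
# expression is multivariate Gaussian with known memberships; the true
# regulatory network is the co-membership graph; the observed PPIN is the
# truth subsampled (edges kept with probability `ppin_retention`) plus
# spurious edges (each non-truth pair included with probability `ppin_noise`).
# A separate linear-Gaussian DAG generator supports directed-structure
# recovery tests.

#' Describe a synthetic benchmark scenario
#'
#' Defaults emulate a small curated benchmark: 30 genes, 40 experiments, 4
#' regulatory pathways, 20% of genes in two pathways, 60% of true
#' co-membership edges observed in the PPIN plus a 5% spurious-edge rate.
#' `separation` is the per-coordinate spacing of pathway means in units of the
#' within-pathway standard deviation `noise_sd` (mean coordinates are drawn
#' `N(0, separation^2 / 2)` so two pathways differ by about `separation` per
#' coordinate).
#'
#' @param I,J,L gene, experiment and pathway counts.
#' @param overlap_fraction fraction of genes belonging to two pathways.
#' @param ppin_retention probability a truth edge is observed in the PPIN.
#' @param ppin_noise probability a non-truth pair appears as a spurious edge.
#' @param separation between-pathway mean separation (per coordinate, in
#'   standard-deviation units).
#' @param noise_sd within-pathway expression standard deviation.
#' @param seed RNG seed making the whole scenario reproducible.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(I = 30, J = 40, L = 4, overlap_fraction = 0.2,
                               ppin_retention = 0.6, ppin_noise = 0.05,
                               separation = 3, noise_sd = 1, seed = 1) {
  stopifnot(L <= I, overlap_fraction >= 0, overlap_fraction <= 1,
            ppin_retention >= 0, ppin_retention <= 1,
            ppin_noise >= 0, ppin_noise <= 1)
  structure(list(I = I, J = J, L = L, overlap_fraction = overlap_fraction,
                 ppin_retention = ppin_retention, ppin_noise = ppin_noise,
                 separation = separation, noise_sd = noise_sd, seed = seed),
            class = "synthetic_scenario")
}

#' Generate pathway-structured expression data
#'
#' Genes are assigned round-robin to the L pathways; a fraction
#' `overlap_fraction` additionally receive a second pathway. Each gene's
#' profile is drawn from the (equal-weight) mixture of its pathways'
#' multivariate Gaussians (diagonal covariance `noise_sd^2 I`).
#'
#' @param scn a [synthetic_scenario()].
#' @return list with `X` (genes x experiments matrix), `membership` (list of
#'   pathway index vectors per gene), `primary` (integer vector: the pathway
#'   each profile was actually drawn from) and `pathway_means` (L x J).
#' @export
generate_expression <- function(scn) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed)
  I <- scn$I; J <- scn$J; L <- scn$L
  genes <- sprintf("G%02d", seq_len(I))
  mu <- matrix(stats::rnorm(L * J, 0, scn$separation * scn$noise_sd / sqrt(2)),
               L, J)
  membership <- lapply(rep_len(seq_len(L), I), function(l) l)
  if (scn$overlap_fraction > 0 && L > 1) {
    n_overlap <- round(scn$overlap_fraction * I)
    if (n_overlap > 0) {
      ov <- sample(I, n_overlap)
      for (i in ov) {
        extra <- sample(setdiff(seq_len(L), membership[[i]]), 1)
        membership[[i]] <- sort(c(membership[[i]], extra))
      }
    }
  }
  drawn <- integer(I)
  X <- matrix(0, I, J, dimnames = list(genes, sprintf("E%02d", seq_len(J))))
  for (i in seq_len(I)) {
    l <- if (length(membership[[i]]) == 1) membership[[i]]
         else sample(membership[[i]], 1)
    drawn[i] <- l
    X[i, ] <- mu[l, ] + stats::rnorm(J, 0, scn$noise_sd)
  }
  names(membership) <- genes
  list(X = X, membership = membership, primary = stats::setNames(drawn, genes),
       pathway_means = mu)
}

#' Generate the ground-truth network and an observed PPIN
#'
#' Truth = every unordered pair of genes sharing a pathway. The PPIN keeps
#' each truth edge with probability `ppin_retention` and adds each non-truth
#' pair with probability `ppin_noise` (noise edges never coincide with truth
#' edges). With retention 1 and noise 0 the PPIN equals the truth.
#'
#' @param scn a [synthetic_scenario()].
#' @param membership per-gene pathway membership list from
#'   [generate_expression()].
#' @return list with `truth` and `ppin` ([edge_list()]s).
#' @export
generate_truth_and_ppin <- function(scn, membership) {
  set.seed(scn$seed + 10007L)
  genes <- names(membership)
  I <- length(genes)
  pairs <- which(upper.tri(matrix(0, I, I)), arr.ind = TRUE)
  share <- vapply(seq_len(nrow(pairs)), function(r) {
    length(intersect(membership[[pairs[r, 1]]],
                     membership[[pairs[r, 2]]])) > 0
  }, TRUE)
  truth <- edge_list(genes[pairs[share, 1]], genes[pairs[share, 2]])
  keep <- stats::runif(nrow(truth)) < scn$ppin_retention
  noise_rows <- which(!share)
  spur <- noise_rows[stats::runif(length(noise_rows)) < scn$ppin_noise]
  ppin <- edge_list(c(truth$gene_a[keep], genes[pairs[spur, 1]]),
                    c(truth$gene_b[keep], genes[pairs[spur, 2]]))
  list(truth = truth, ppin = ppin)
}

#' Generate a linear-Gaussian DAG and observations from it
#'
#' A random DAG over `I` genes (edges follow a random topological order,
#' each admissible pair drawn with probability `edge_prob`), with edge
#' weights of magnitude `weight` and random sign, root variance 1 and
#' observation noise `sigma`; `n` i.i.d. experiments are generated.
#'
#' @param I gene count.
#' @param n experiment count.
#' @param edge_prob probability of each forward edge (default 0.2).
#' @param weight edge-weight magnitude (default 0.8).
#' @param sigma noise standard deviation (default 0.3).
#' @param seed RNG seed.
#' @return list with `X` (I x n matrix), `adj` (directed adjacency matrix)
#'   and `truth` (undirected [edge_list()] of the skeleton).
#' @export
generate_dag_data <- function(I = 10, n = 60, edge_prob = 0.2, weight = 0.8,
                              sigma = 0.3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(I))
  ord <- sample(I)
  adj <- matrix(0, I, I, dimnames = list(genes, genes))
  for (a in seq_len(I - 1)) for (b in seq((a + 1), I)) {
    if (stats::runif(1) < edge_prob) adj[ord[a], ord[b]] <- 1
  }
  w <- adj * weight * sign(stats::rnorm(I * I))
  X <- matrix(0, I, n, dimnames = list(genes, sprintf("E%03d", seq_len(n))))
  for (a in ord) {
    pa <- which(adj[, a] == 1)
    base <- if (length(pa)) colSums(X[pa, , drop = FALSE] * w[pa, a]) else 0
    noise_sd <- if (length(pa)) sigma else 1
    X[a, ] <- base + stats::rnorm(n, 0, noise_sd)
  }
  idx <- which(adj == 1, arr.ind = TRUE)
  truth <- edge_list(genes[idx[, 1]], genes[idx[, 2]])
  list(X = X, adj = adj, truth = truth)
}

#' Partition PPIN edges into cross-validation folds
#'
#' Per repeat, edges are randomly partitioned into `folds` folds of sizes
#' differing by at most one; the holdout harness removes one fold, extends
#' the PPIN from the remainder and scores recovery of the held-out fold.
#'
#' @param ppin an [edge_list()].
#' @param folds number of folds (>= 2, default 10).
#' @param repeats number of repeated partitions (default 1).
#' @param seed RNG seed; folds are reproducible.
#' @return list (one element per repeat) of integer fold labels per edge row.
#' @export
edge_holdout_cv <- function(ppin, folds = 10, repeats = 1, seed = 1) {
  stopifnot(folds >= 2)
  m <- nrow(ppin)
  if (m < folds) stop("edge_holdout_cv: fewer edges than folds")
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    sample(rep_len(seq_len(folds), m))
  })
}

#' Held-out edge recovery of the extended PPIN vs a degree-matched baseline
#'
#' For each repeat, one fold of edges is removed, the confidence scores C are
#' recomputed from the remaining edges and the expression data, and the
#' extension's predictions (new pairs with `C >= cutoff`) are scored for how
#' many held-out edges they recover. A degree-matched random baseline predicts
#' the same number of new pairs, sampled with probability proportional to the
#' product of endpoint degrees in the remaining graph.
#'
#' @param X genes x experiments expression matrix.
#' @param ppin an [edge_list()] over the genes of `X`.
#' @param folds folds per repeat (default 10; one fold is held out per
#'   repeat).
#' @param repeats number of repeats (default 10).
#' @param cutoff C-score threshold for a predicted interaction (default 0.5).
#' @param damping random-walk damping factor.
#' @param seed RNG seed.
#' @return data frame with one row per repeat: `recovered`, `held_out`,
#'   `recovery` (extension) and `baseline_recovery`.
#' @export
edge_holdout_recovery <- function(X, ppin, folds = 10, repeats = 10,
                                  cutoff = 0.5, damping = 0.85, seed = 1) {
  genes <- rownames(X)
  ppin <- restrict_edges(ppin, genes)
  assignments <- edge_holdout_cv(ppin, folds, repeats, seed)
  set.seed(seed + 65537L)
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    hold <- assignments[[r]] == 1L
    held <- ppin[hold, , drop = FALSE]
    rest <- structure(ppin[!hold, , drop = FALSE],
                      class = c("edge_list", "data.frame"))
    sc <- extend_ppin_scores(X, rest, damping = damping)
    pred <- extend_ppin(sc$C, cutoff)
    rest_keys <- canonical_pairs(rest)
    new_keys <- setdiff(canonical_pairs(pred), rest_keys)
    held_keys <- canonical_pairs(held)
    recovered <- length(intersect(new_keys, held_keys))
    # degree-matched baseline over the same candidate universe
    deg <- table(factor(c(rest$gene_a, rest$gene_b), levels = genes))
    I <- length(genes)
    pr <- which(upper.tri(matrix(0, I, I)), arr.ind = TRUE)
    keys <- paste(pmin(genes[pr[, 1]], genes[pr[, 2]]),
                  pmax(genes[pr[, 1]], genes[pr[, 2]]), sep = "\r")
    cand <- !(keys %in% rest_keys)
    wts <- as.numeric(deg[pr[, 1]] * deg[pr[, 2]])[cand]
    n_pick <- min(length(new_keys), sum(cand))
    base_rec <- 0L
    if (n_pick > 0) {
      if (all(wts == 0)) wts <- rep(1, length(wts))
      picked <- sample(keys[cand], n_pick, prob = wts + 1e-12)
      base_rec <- length(intersect(picked, held_keys))
    }
    out[[r]] <- data.frame(
      recovered = recovered, held_out = nrow(held),
      recovery = recovered / max(nrow(held), 1L),
      baseline_recovery = base_rec / max(nrow(held), 1L))
  }
  do.call(rbind, out)
}
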