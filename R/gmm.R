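# Soft-clustering of genes into regulatory pathways.
#
# Each pathway l is a multivariate Gaussian N(mu_l, Sigma_l) over the J
# experiments; gene profiles are drawn from the L-component mixture with
# weights theta_l. Fitting is by component-wise EM: starting from L_max
# components, EM runs to convergence, the minimum-message-length (MML)
# criterion is recorded, the smallest component is annihilated, and the loop
# repeats; the parameter set minimizing MML over visited L is returned.
# Components whose weight drops below 1/I during EM are annihilated on the
# spot (smallest first).

#' Construct Gaussian mixture parameters
#'
#' @param weights length-L nonnegative vector summing to 1 (pathway weights
#'   theta_l).
#' @param means L x J matrix of component means mu_l.
#' @param covariances list of L covariances: length-J variance vectors when
#'   `cov_type = "diagonal"`, J x J matrices when `"full"`.
#' @param cov_type `"diagonal"` (default) or `"full"`.
#' @param dirichlet_alphas Dirichlet prior weights on theta (uniform alpha = 1
#'   by default; kept for completeness, no effective smoothing is applied).
#' @return object of class `gmm_parameters` with element `L`.
#' @export
gmm_parameters <- function(weights, means, covariances,
                           cov_type = c("diagonal", "full"),
                           dirichlet_alphas = rep(1, length(weights))) {
  cov_type <- match.arg(cov_type)
  weights <- as.numeric(weights)
  if (!is.matrix(means)) means <- matrix(means, nrow = length(weights))
  L <- length(weights)
  stopifnot(L >= 1, nrow(means) == L, length(covariances) == L)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("gmm_parameters: weights must sum to 1")
  for (l in seq_len(L)) {
    d <- if (cov_type == "diagonal") covariances[[l]] else diag(covariances[[l]])
    if (any(d <= 0))
      stop("gmm_parameters: covariance ", l, " has a non-positive diagonal")
  }
  structure(list(L = L, weights = weights, means = means,
                 covariances = covariances, cov_type = cov_type,
                 dirichlet_alphas = dirichlet_alphas),
            class = "gmm_parameters")
}

#' @export
print.gmm_parameters <- function(x, ...) {
  cat(sprintf("gmm_parameters: L = %d components, J = %d dims, %s covariance\n",
              x$L, ncol(x$means), x$cov_type))
  invisible(x)
}

# I x L matrix of per-component Gaussian log-densities log N(x_i; mu_l, Sigma_l).
component_log_density <- function(X, params) {
  I <- nrow(X); J <- ncol(X); L <- params$L
  ld <- matrix(0, I, L)
  for (l in seq_len(L)) {
    mu <- params$means[l, ]
    if (params$cov_type == "diagonal") {
      v <- params$covariances[[l]]
      if (any(v <= 0))
        stop("singular covariance in component ", l,
             ": regularize (variance floor / shrinkage) before the E-step")
      xc <- sweep(X, 2, mu)
      ld[, l] <- -0.5 * (J * log(2 * pi) + sum(log(v)) +
                           colSums(t(xc^2) / v))
    } else {
      S <- params$covariances[[l]]
      ch <- tryCatch(chol(S), error = function(e)
        stop("singular covariance in component ", l,
             ": regularize (add shrinkage lambda*I) before the E-step"))
      xc <- sweep(X, 2, mu)
      z <- backsolve(ch, t(xc), transpose = TRUE)
      ld[, l] <- -0.5 * (J * log(2 * pi) + 2 * sum(log(diag(ch))) +
                           colSums(z^2))
    }
  }
  ld
}

row_log_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' E-step: posterior pathway memberships
#'
#' Computes `tau[i, l] = theta_l N(x_i; mu_l, Sigma_l) / sum_l' theta_l'
#' N(x_i; mu_l', Sigma_l')` in log-space (never underflows).
#'
#' @param X genes x experiments expression matrix.
#' @param params a [gmm_parameters()] object.
#' @return I x L membership matrix whose rows sum to 1, with gene rownames and
#'   pathway colnames, plus attribute `"log_likelihood"` (observed-data
#'   log-likelihood).
#' @export
gmm_e_step <- function(X, params) {
  stopifnot(ncol(X) == ncol(params$means))
  lw <- log(params$weights)
  lw[params$weights == 0] <- -Inf
  lp <- sweep(component_log_density(X, params), 2, lw, `+`)
  norm <- row_log_sum_exp(lp)
  tau <- exp(lp - norm)
  dimnames(tau) <- list(rownames(X), paste0("pathway", seq_len(params$L)))
  attr(tau, "log_likelihood") <- sum(norm)
  tau
}

#' M-step: re-estimate mixture parameters from memberships
#'
#' `theta_l = mean_i tau[i,l]`, `mu_l` is the tau-weighted mean profile and
#' `Sigma_l` the tau-weighted scatter (diagonal by default, with a variance
#' floor; full covariance gets additive shrinkage `lambda * I`).
#'
#' Components with zero responsibility mass are not turned into NaNs: their
#' weight is set to 0 (flagging them for annihilation) and their mean and
#' covariance fall back to the global ones.
#'
#' @param X genes x experiments expression matrix.
#' @param tau I x L membership matrix with rows summing to 1.
#' @param cov_type `"diagonal"` (default) or `"full"`.
#' @param var_floor lower bound for diagonal variances (default 1e-6).
#' @param shrinkage additive ridge `lambda` for full covariances (default 1e-3).
#' @return a [gmm_parameters()] object.
#' @export
gmm_m_step <- function(X, tau, cov_type = c("diagonal", "full"),
                       var_floor = 1e-6, shrinkage = 1e-3) {
  cov_type <- match.arg(cov_type)
  I <- nrow(X); J <- ncol(X); L <- ncol(tau)
  n_l <- colSums(tau)
  weights <- n_l / I
  global_mu <- colMeans(X)
  global_v <- pmax(apply(X, 2, stats::var), var_floor)
  means <- matrix(0, L, J)
  covs <- vector("list", L)
  for (l in seq_len(L)) {
    if (n_l[l] <= 0) {
      means[l, ] <- global_mu
      covs[[l]] <- if (cov_type == "diagonal") global_v else diag(global_v, J)
      next
    }
    w <- tau[, l]
    mu <- colSums(X * w) / n_l[l]
    means[l, ] <- mu
    xc <- sweep(X, 2, mu)
    if (cov_type == "diagonal") {
      covs[[l]] <- pmax(colSums(xc^2 * w) / n_l[l], var_floor)
    } else {
      S <- crossprod(xc * sqrt(w)) / n_l[l]
      covs[[l]] <- S + diag(shrinkage, J)
    }
  }
  gmm_parameters(weights / sum(weights) * sum(weights), means, covs, cov_type)
}

# Free parameters per component: mean + covariance terms.
params_per_component <- function(J, cov_type) {
  if (cov_type == "diagonal") 2 * J else J + J * (J + 1) / 2
}

# Minimum-message-length criterion (component-wise EM form): data code length
# plus parameter code length. Smaller is better.
mml_criterion <- function(log_lik, weights, I, J, cov_type) {
  w <- weights[weights > 0]
  L <- length(w)
  P <- params_per_component(J, cov_type)
  -log_lik + (P / 2) * sum(log(I * w / 12)) + (L / 2) * log(I / 12) +
    L * (P + 1) / 2
}

# Seeded k-means++-style initialization: the first mean is a random data row,
# each further mean a row sampled with probability proportional to its squared
# distance from the nearest mean chosen so far; pooled diagonal variance,
# uniform weights.
init_mixture <- function(X, L, seed, cov_type, var_floor = 1e-6,
                         shrinkage = 1e-3) {
  set.seed(seed)
  idx <- integer(L)
  idx[1] <- sample(nrow(X), 1)
  if (L > 1) {
    d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
    for (l in 2:L) {
      idx[l] <- if (sum(d2) > 0) sample(nrow(X), 1, prob = d2)
                else sample(nrow(X), 1)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[l], ])^2))
    }
  }
  means <- X[idx, , drop = FALSE]
  v <- pmax(apply(X, 2, stats::var), var_floor)
  covs <- lapply(seq_len(L), function(l)
    if (cov_type == "diagonal") v else diag(v + shrinkage, ncol(X)))
  gmm_parameters(rep(1 / L, L), means, covs, cov_type)
}

# Remove component `drop` from a parameter set (and matching tau columns).
drop_component <- function(params, tau_prev, drop) {
  keep <- setdiff(seq_len(params$L), drop)
  p <- gmm_parameters(params$weights[keep] / sum(params$weights[keep]),
                      params$means[keep, , drop = FALSE],
                      params$covariances[keep], params$cov_type)
  if (!is.null(tau_prev)) {
    tau_prev <- tau_prev[, keep, drop = FALSE]
    tau_prev <- tau_prev / pmax(rowSums(tau_prev), .Machine$double.xmin)
  }
  list(params = p, tau_prev = tau_prev)
}

# Shared component-wise-EM engine for the plain GMM and the field-regularized
# GHMM (field_C = NULL gives the plain model). Returns the MML-best snapshot.
fit_mixture_cem <- function(X, L_max, L_min = 1, seed = 1, tol = 1e-6,
                            cov_type = "diagonal", field_C = NULL,
                            max_em_iter = 200, var_floor = 1e-6,
                            shrinkage = 1e-3) {
  validate_expression(X)
  I <- nrow(X); J <- ncol(X)
  if (L_min < 1 || L_max < L_min) stop("need 1 <= L_min <= L_max")
  if (I < L_min) stop("fewer genes than L_min components")
  L_max <- min(L_max, I)
  params <- init_mixture(X, L_max, seed, cov_type, var_floor, shrinkage)
  tau_prev <- if (!is.null(field_C))
    matrix(1 / params$L, I, params$L) else NULL

  e_step <- function(params, tau_prev) {
    if (is.null(field_C)) gmm_e_step(X, params)
    else ghmm_e_step(X, params, field_C, tau_prev)
  }
  P <- params_per_component(J, cov_type)

  # One component-wise EM sweep: for each component in turn, recompute the
  # responsibilities, update that component's weight with the MML support
  # correction max(0, n_l - P/2) (which drives under-supported components to
  # zero), renormalize, and either annihilate the component or refresh its
  # mean and covariance. Sequential updates let surviving components absorb
  # an annihilated component's mass before they are themselves judged.
  cem_sweep <- function(params, tau_prev) {
    m <- 1L
    while (m <= params$L) {
      tau <- e_step(params, tau_prev)
      if (!is.null(field_C)) tau_prev <- tau
      n_l <- colSums(tau)
      supp <- pmax(0, n_l - P / 2)
      w <- params$weights
      w[m] <- if (sum(supp) > 0) supp[m] / sum(supp) else n_l[m] / I
      annihilate <- (w[m] < 1 / I || w[m] == 0) && params$L > L_min
      if (annihilate) {
        d <- drop_component(
          gmm_parameters(pmax(w, 1e-300) / sum(pmax(w, 1e-300)),
                         params$means, params$covariances, cov_type),
          tau_prev, m)
        params <- d$params
        tau_prev <- d$tau_prev
        next  # same index m now names the next component
      }
      params$weights <- w / sum(w)
      if (n_l[m] > 0) {
        wt <- tau[, m]
        mu <- colSums(X * wt) / n_l[m]
        params$means[m, ] <- mu
        xc <- sweep(X, 2, mu)
        params$covariances[[m]] <-
          if (cov_type == "diagonal") pmax(colSums(xc^2 * wt) / n_l[m], var_floor)
          else crossprod(xc * sqrt(wt)) / n_l[m] + diag(shrinkage, J)
      }
      m <- m + 1L
    }
    list(params = params, tau_prev = tau_prev)
  }

  trace <- list()
  best <- NULL
  mml_prev <- NA_real_
  repeat {
    # component-wise EM to convergence at the current component count
    ll_prev <- -Inf
    for (it in seq_len(max_em_iter)) {
      L_before <- params$L
      sw <- cem_sweep(params, tau_prev)
      params <- sw$params
      tau_prev <- sw$tau_prev
      tau <- e_step(params, tau_prev)
      ll <- attr(tau, "log_likelihood")
      if (!is.null(field_C)) tau_prev <- tau
      if (params$L == L_before && is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * (1 + abs(ll_prev)))
        break
      ll_prev <- ll
    }
    tau <- e_step(params, tau_prev)
    ll <- attr(tau, "log_likelihood")
    mml <- mml_criterion(ll, params$weights, I, J, cov_type)
    trace[[length(trace) + 1]] <-
      data.frame(L = params$L, mml = mml, log_likelihood = ll)
    if (is.null(best) || mml < best$mml)
      best <- list(params = params, tau = tau, mml = mml)
    converged <- is.finite(mml_prev) &&
      abs(mml - mml_prev) < tol * (1 + abs(mml_prev))
    mml_prev <- mml
    if (params$L <= L_min || converged) break
    # outer step: force-annihilate the smallest component and refit
    d <- drop_component(params, tau_prev, which.min(params$weights))
    params <- d$params
    if (!is.null(field_C)) tau_prev <- d$tau_prev
  }
  trace <- do.call(rbind, trace)
  list(params = best$params, tau = best$tau, trace = trace, mml = best$mml,
       seed = seed)
}

#' Fit a Gaussian mixture of pathways by component-wise EM under MML
#'
#' Starts from `L_max` components, runs EM to convergence, records the MML
#' criterion, annihilates the smallest component and repeats down to `L_min`
#' (or until the MML stabilizes); returns the MML-minimizing fit. Deterministic
#' for a fixed `seed` (initial means are seeded samples of data rows).
#'
#' @param X genes x experiments expression matrix with gene rownames.
#' @param L_max,L_min bounds on the pathway count (defaults
#'   `min(nrow(X), 15)` and 1).
#' @param seed integer RNG seed controlling initialization.
#' @param tol relative convergence tolerance for the log-likelihood (inner EM)
#'   and the MML sequence (outer loop).
#' @param cov_type `"diagonal"` (default) or `"full"` covariances.
#' @return list with `params` ([gmm_parameters()]), `tau` (membership matrix,
#'   rows sum to 1), `trace` (data frame of `(L, mml, log_likelihood)` per
#'   outer iteration), `mml` and `seed`.
#' @export
fit_gmm_cem <- function(X, L_max = min(nrow(X), 15), L_min = 1, seed = 1,
                        tol = 1e-6, cov_type = c("diagonal", "full")) {
  cov_type <- match.arg(cov_type)
  fit_mixture_cem(X, L_max, L_min, seed, tol, cov_type, field_C = NULL)
}

#' Pathway co-membership network G
#'
#' `G = tau %*% t(tau)`, i.e. `G[i, i'] = sum_l tau[i,l] tau[i',l]`: the
#' probability that genes i and i' fall in the same pathway. Entries lie in
#' `[0, 1]`; the diagonal is zeroed for all network uses.
#'
#' @param tau membership matrix (rows sum to 1).
#' @param zero_diagonal zero the diagonal (default `TRUE`).
#' @return a symmetric [scored_network()] with `score_range = c(0, 1)`.
#' @export
co_membership <- function(tau, zero_diagonal = TRUE) {
  G <- tcrossprod(tau)
  G <- (G + t(G)) / 2  # exact symmetry against rounding
  if (zero_diagonal) diag(G) <- 0
  if (is.null(rownames(G)))
    dimnames(G) <- list(paste0("g", seq_len(nrow(G))),
                        paste0("g", seq_len(nrow(G))))
  scored_network(G, symmetric = TRUE, score_range = c(0, 1))
}
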