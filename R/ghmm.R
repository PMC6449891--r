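# Fusion of expression clustering with PPIN evidence.
#
# The extended-PPIN confidence C acts as a hidden-Markov-random-field
# neighborhood prior on the pathway assignments: the Gibbs prior
# p(Gamma | C) ~ exp(sum_{i, j != i} -C_ij * [gamma_j != gamma_i]) rewards
# assignments in which strongly interacting genes share a pathway. The E-step
# multiplies the plain GMM posterior by the soft field term
# exp(sum_{j != i} -C_ij (1 - tau_jl)), using the previous iteration's
# memberships on the right-hand side (mean-field update), and renormalizes
# rows. M-step and MML-driven component annihilation are shared with the
# plain GMM.

#' Field-regularized E-step (GHMM)
#'
#' Computes the unnormalized posterior `u[i, l] = tau_gmm[i, l] *
#' exp(sum_{j != i} -C[i, j] (1 - tau_prev[j, l]))` in log-space, then
#' renormalizes rows so tau remains a probability matrix.
#'
#' @param X genes x experiments expression matrix.
#' @param params a [gmm_parameters()] object.
#' @param C symmetric neighborhood-constraint network (entries in `[0, 1]`,
#'   zero diagonal); a [scored_network()] or matrix.
#' @param tau_prev memberships from the previous iteration (I x L, rows sum
#'   to 1).
#' @return I x L membership matrix with rows summing to 1 and attribute
#'   `"log_likelihood"` (the GMM observed-data log-likelihood component, used
#'   for convergence monitoring).
#' @export
ghmm_e_step <- function(X, params, C, tau_prev) {
  Cm <- as.matrix(C)
  stopifnot(nrow(Cm) == nrow(X), ncol(tau_prev) == params$L,
            nrow(tau_prev) == nrow(X))
  diag(Cm) <- 0
  lw <- log(params$weights)
  lw[params$weights == 0] <- -Inf
  lp <- sweep(component_log_density(X, params), 2, lw, `+`)
  ll <- sum(row_log_sum_exp(lp))
  field <- -(Cm %*% (1 - tau_prev))  # [i, l] = sum_{j != i} -C_ij (1 - tau_prev[j, l])
  lu <- lp + field
  tau <- exp(lu - row_log_sum_exp(lu))
  dimnames(tau) <- list(rownames(X), paste0("pathway", seq_len(params$L)))
  attr(tau, "log_likelihood") <- ll
  tau
}

#' Fit the GHMM: mixture of pathways with a PPIN field prior
#'
#' Same component-wise EM / MML machinery as [fit_gmm_cem()], with the E-step
#' replaced by [ghmm_e_step()]. With an all-zero `C` the field term is 1 and
#' the fit coincides with the plain GMM at the same seed.
#'
#' @inheritParams fit_gmm_cem
#' @param C neighborhood-constraint network ([scored_network()] or matrix),
#'   symmetric with entries in `[0, 1]`.
#' @return as [fit_gmm_cem()]: list with `params`, `tau`, `trace`, `mml`,
#'   `seed`.
#' @export
fit_ghmm <- function(X, C, L_max = min(nrow(X), 15), L_min = 1, seed = 1,
                     tol = 1e-6, cov_type = c("diagonal", "full")) {
  cov_type <- match.arg(cov_type)
  Cm <- as.matrix(C)
  if (nrow(Cm) != nrow(X))
    stop("fit_ghmm: C and X cover different gene sets")
  diag(Cm) <- 0
  fit_mixture_cem(X, L_max, L_min, seed, tol, cov_type, field_C = Cm)
}

#' Refined gene-interaction score R
#'
#' `R = 0.5 * G + 0.5 * C`: the elementwise average of the GHMM co-membership
#' network and the extended-PPIN confidence. Inherits symmetry and the
#' `[0, 1]` range from its inputs.
#'
#' @param G co-membership network from [co_membership()].
#' @param C confidence network from [confidence_scores()].
#' @return a symmetric [scored_network()].
#' @export
refine_scores <- function(G, C) {
  Gm <- as.matrix(G); Cm <- as.matrix(C)
  if (!all(dim(Gm) == dim(Cm)))
    stop("refine_scores: G and C have different dimensions")
  R <- 0.5 * Gm + 0.5 * Cm
  scored_network(R, symmetric = TRUE, score_range = c(0, 1))
}

#' Membership-agreement statistic between two genes
#'
#' The inner product `sum_l tau[i, l] tau[j, l]`, i.e. the probability the two
#' genes share a pathway; exposed so users can quantify how consistent the
#' clustering is with a PPIN.
#'
#' @param tau membership matrix.
#' @param i,j gene indices or names.
#' @return scalar in `[0, 1]`.
#' @export
membership_agreement <- function(tau, i, j) {
  sum(tau[i, ] * tau[j, ])
}
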