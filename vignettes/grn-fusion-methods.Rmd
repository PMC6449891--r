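---
title: "Methods: fusing expression clustering and transitive protein interactions for GRN inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusing expression clustering and transitive protein interactions for GRN inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnfuse)
```

`grnfuse` infers gene regulatory networks by combining two noisy, complementary
evidence sources: a genes × experiments expression matrix and a sparse
protein–protein interaction network (PPIN). This vignette is the package's own
account of the underlying models, the parameters that matter, the synthetic
data used to validate each stage, and the numerical and design choices made
where the method leaves room.

## 1. Pathway model: Gaussian mixture with MML model selection

Each regulatory pathway `l` is modelled as a multivariate Gaussian
`N(mu_l, Sigma_l)` over the `J` experiments, and each gene's profile as a draw
from the `L`-component mixture with weights `theta_l`. Soft memberships
`tau[i, l]` (the E-step posterior) let a gene participate in several pathways,
which is biologically routine. The co-membership network `G = tau %*% t(tau)`
gives the probability that two genes share a pathway.

**Model selection.** `L` is chosen by component-wise EM under the minimum
message length (MML) criterion

```
MML = -loglik + (P/2) * sum_l log(I * theta_l / 12) + (L/2) * log(I/12) + L*(P+1)/2
```

with `P` free parameters per component (`2J` for diagonal covariances). The
fitter starts at `L_max`, runs component-wise EM sweeps to convergence, records
the MML, force-annihilates the smallest component and repeats, returning the
MML-minimizing fit.

**Why component-wise sweeps.** Each sweep updates one component at a time: the
responsibilities are recomputed, the component's weight is set with the
support correction `max(0, n_l - P/2)` (its responsibility mass minus the code
length its parameters cost), the weight vector is renormalized, and only then
is the next component visited. The sequential order matters: when a component
dies, its mass is redistributed and absorbed by surviving components *before*
they are themselves judged. A simultaneous correction annihilates every
component in the first iteration whenever initial responsibilities are spread
thin, and without the correction the raw MML formula prefers `L = L_max` at
small `I` (the `log(I*theta/12)` term turns negative when a component's
expected support drops below 12). Components also die whenever their weight
falls below `1/I`, smallest first.

**Degenerate regime.** When `I <= P/2` no component can ever reach support
`P/2` (e.g. 30 genes over 40 experiments with diagonal covariance). The
support correction is then inactive and only the `1/I` rule prunes; model
selection in this regime is weakly identified and `L_max` should be set to a
biologically plausible cap (the pipeline default is 8 for a ~30-gene module).

**Parameters.**

| parameter | default | meaning |
|---|---|---|
| `L_max`, `L_min` | `min(I, 15)`, 1 | bracket for the pathway count |
| `cov_type` | `"diagonal"` | diagonal avoids singular `J x J` covariances when `I < J`; `"full"` adds shrinkage `lambda*I` |
| `var_floor` | 1e-6 | lower bound on diagonal variances |
| `shrinkage` | 1e-3 | ridge for full covariances |
| `tol` | 1e-6 | relative log-likelihood / MML convergence |
| `seed` | — | all stochasticity (k-means++-style seeding of means from data rows) flows from this one integer |

The Dirichlet prior on the weights is uniform (`alpha = 1`): no smoothing
beyond the MML penalty. Expression values are taken as-is — the loader applies
no log-scaling or centering, because preprocessing conventions differ between
platforms and should be the caller's explicit decision.

## 2. PPIN extension: transitive paths, correlation, random walk

Sparse PPINs miss many true interactions. A candidate interaction at
shortest-path distance `d` (unweighted hops, computed with igraph; `subnet`
scope restricts to the target genes, `global` walks through outside
intermediates) receives confidence `c_d = zeta^(d-1)`, where the per-hop
extension probability solves `sum_{d>=1} zeta^d = zeta/(1-zeta) = 1`, i.e.
`zeta = 1/2`: `c_1 = 1`, `c_2 = 0.5`, `c_3 = 0.25`, `c_4 = 0.125`. This makes
implicit interactions strictly weaker than observed ones and geometrically
discounts intermediaries.

The evidence graph `W[i, j] = rho[i, j] + c_d[i, j]` adds the Pearson
correlation of the two genes' profiles. A damped random walk on `W` then
contributes topology: `T = damping * W+ / rowsum + (1-damping)/I` with
`W+ = max(W, 0)`, and the equilibrium `T_hat = lim T^k` is computed by
repeated squaring. The final confidence is

```
C = 0.5 * W + 0.5 * W %*% T_hat
```

symmetrized as `(C + t(C))/2` and min–max normalized to `[0, 1]`. The extended
PPIN is `C >= cutoff` (default 0.5, the conventional precision/recall
trade-off point for scores normalized to the unit interval).

**Design choices here.**

- *Negative correlations*: transition mass must be nonnegative, so `W` is
  clipped at zero **only** inside the walk; the signed `W` is kept in the
  direct and product terms of `C`, preserving anticorrelation information.
- *Dangling rows*: rows of `W+` with no positive mass become uniform rows
  (the standard dangling-node fix), keeping `T` row-stochastic.
- *Convergence*: plain power convergence of `T^k` (tol 1e-9, up to 64
  squarings), not the Markov-clustering expansion/inflation alternation —
  the limit itself is the stated quantity.
- *Symmetrization and normalization order*: the product term is asymmetric;
  `C` is averaged with its transpose because downstream uses are undirected,
  and normalization is applied to the final combined `C` (the method does not
  specify the order; this choice is documented rather than load-bearing).
- *Damping*: 0.85, the customary PageRank-style value; must lie in (0.5, 1).

## 3. Fusion: hidden-Markov-random-field regularized mixture

The confidence network `C` becomes a Gibbs neighborhood prior on pathway
assignments: assignments where strongly interacting genes occupy different
pathways are penalized through the soft field term

```
u[i, l] = tau_gmm[i, l] * exp(sum_{j != i} -C[i, j] * (1 - tau_prev[j, l]))
```

The E-step uses the *previous* iteration's memberships on the right-hand side
(a mean-field/ICM-style fixed-point treatment of the self-referential posterior)
and renormalizes rows so `tau` stays a probability matrix — renormalization is
required for the M-step weights and for `G` to stay in `[0, 1]`. With `C = 0`
the fit reduces exactly to the plain GMM at the same seed (verified in tests).
The exact Gibbs normalizer over all assignments is intractable and never
needed. The refined interaction score is `R = 0.5*G + 0.5*C`.

The package exposes `membership_agreement()` (the inner product of two genes'
membership rows) so users can quantify how consistent a clustering is with a
PPIN; no single canonical consistency metric is imposed.

## 4. Directed structure: Bayesian network over mixture observations

Experiments (columns) are hard-clustered into `K` components by the same
MML machinery on the transposed matrix (`K_max` default 3; with i.i.d.
experiments the criterion typically returns `K = 1`, which is then simply an
unpartitioned marginal). The marginal likelihood of gene `i` with parents
`pi_i` mixes the conjugate normal-inverse-gamma linear-regression marginal
over the partitions:

```
local_score(i, pi_i) = log sum_k theta_k * Psi(D^(k), x_i, pi_i)
```

`Psi` is the closed-form marginal of `x_i ~ N(intercept + beta' x_parents,
sigma^2)` with prior `beta ~ N(0, sigma^2 I)`, `sigma^2 ~ InvGamma(1, 1)` —
zero prior mean, prior precision 1, shape 1, scale 1. Any conjugate choice
yields an analytic integral; these are the standard defaults and are
configurable. Partitions smaller than the coefficient count are handled by the
prior (with a logged warning) rather than failing.

**Candidate constraints.** Parents must share at least one pathway with the
child (`tau >= 0.1` counts as membership) and be among its top-`k = 5`
neighbours by `R` (ties broken by gene order). Per-gene top-k is the default;
a global top-N can be emulated by thresholding `R` upstream. Both cut-offs are
empirical dials, deliberately configurable.

**Sampler.** Metropolis–Hastings over single-edge moves (add / delete /
reverse), proposed uniformly over the *currently admissible* moves — those
respecting candidacy and acyclicity — with a Hastings correction for the
changing move count. Acyclicity is checked via boolean transitive closure by
repeated matrix squaring; a reverse is admissible iff no length-≥2 path
connects the endpoints (for a DAG this is exact). Scores are decomposable, so
each move re-evaluates only the affected child(ren), with per-(gene, parent
set) memoization. The first 20% of each chain is discarded as burn-in; edge
frequencies are accumulated over every retained iteration. Defaults: 10
chains × 1000 iterations, averaged; edges at pooled frequency ≥ 0.5 form the
final network. Chain length, burn-in and thinning are standard defaults, not
derived quantities; the exactness of the sampler is verified against the
exhaustive 25-DAG posterior on 3-gene problems.

## 5. Evaluation conventions

Matching is on unordered pairs — a predicted edge counts if the reference
contains it in either direction, which is how undirected and directed
predictions are compared on the same footing. The negative universe for
AUROC/AUPR is every unordered gene pair absent from the reference (self-pairs
excluded; an exclusion list is supported). AUROC uses the Mann–Whitney rank
form with midrank tie correction — thresholded score matrices tie heavily at
zero, and midranks make the statistic well-defined there. AUPR is the
step-interpolated area (average precision), ties broken by stable pair order.
Significance grouping follows the convention of pooling the best methods while
the classic pooled-variance unpaired t-test cannot separate them at 0.05.

## 6. Synthetic data: what it does and does not emulate

`synthetic_scenario()` defaults describe a small curated benchmark:
`I = 30` genes, `J = 40` experiments, `L = 4` pathways, 20% of genes in two
pathways, 60% of true edges observed in the PPIN, 5% spurious-edge rate,
within-pathway standard deviation 1 and per-coordinate pathway-mean separation
3 (mean coordinates drawn `N(0, separation^2/2)` so two pathway means differ
by about `separation` standard deviations per coordinate). The ground-truth
network is the co-membership graph — every stage of the method models
co-pathway structure, so that is the recoverable signal. A separate
linear-Gaussian DAG generator (edge magnitude 0.8 with random sign, noise
s.d. 0.3) supports directed-recovery tests.

What this emulates: mixture-distributed profiles, overlapping memberships,
a PPIN that is a corrupted subsample of the truth. What it does not: technical
microarray noise models, time-course autocorrelation between experiments,
scale-free PPIN topology, or direction-informative expression asymmetries.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative value of fusion under the model's own assumptions — not
performance on any particular real organism.

Problem sizes used by the test suite are deliberate: mixture recovery at
`I = 60, J = 10` and `I = 200, J = 10` (where MML support is well-defined),
the exact-posterior MCMC check at 3 genes × 50,000 iterations, DAG recovery
at 10 genes × 60 experiments over 5 seeds, the fused-vs-expression-only
comparison at the default scenario over 5 paired seeds, and 10-fold
edge-holdout at 30 genes over 10 repeats.

## 7. Known limitations

- MML model selection is weakly identified when `I <= P/2` (few genes, many
  experiments, see §1); the pathway count then leans on `L_max`.
- The GHMM field prior is a mean-field approximation with no convergence
  guarantee on the coupled fixed point; in practice it tracks EM convergence.
- A strong *adversarial* (not merely random) prior can distort pathway
  recovery; the package does not attempt to detect misspecified priors.
- Structure learning is limited by the candidate cap `k`; true parents outside
  the top-k `R` neighbours are unreachable by construction.
- Runtime scales as O(iterations × I²) for the sampler's move enumeration;
  the implementation targets tens-to-hundreds of genes, not genome scale.
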