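# grnfuse

Inference of gene regulatory networks (GRNs) by fusing gene-expression data
with sparse protein–protein interaction networks (PPINs).

## The problem

Reverse-engineering regulatory interactions from expression data alone is
noisy and under-determined, while curated PPINs are informative but sparse:
many real interactions are simply missing from the databases. `grnfuse`
implements a four-stage probabilistic framework that combines both sources,
for systems biologists who have a genes × experiments expression matrix, an
edge-list PPIN, and (optionally) a reference network to benchmark against.

## The model

1. **Pathway clustering (GMM).** Gene profiles x_i over J experiments are
   modelled as an L-component Gaussian mixture; soft memberships
   τ_il = θ_l N(x_i; μ_l, Σ_l) / Σ_l′ θ_l′ N(x_i; μ_l′, Σ_l′) allow genes in
   several pathways. L is selected by component-wise EM under the minimum
   message length (MML) criterion, annihilating under-supported components.
   The co-membership network is G = ττᵀ.
2. **PPIN extension.** A missing interaction at shortest-path distance d gets
   confidence c_d = ζ^(d−1), with ζ solving Σ_{d≥1} ζ^d = ζ/(1−ζ) = 1
   (ζ = 1/2, so c_2 = 0.5, c_3 = 0.25, c_4 = 0.125). Evidence graph
   W_ij = ρ_ij + c_{d_ij} (Pearson correlation plus path confidence) feeds a
   damped random walk T; the final confidence is
   C = 0.5 W + 0.5 W T̂ (T̂ = lim T^k), symmetrized and min–max normalized.
3. **Fusion (GHMM).** C acts as a hidden-Markov-random-field prior on the
   pathway assignments: the E-step multiplies the GMM posterior by
   exp(Σ_{j≠i} −C_ij (1 − τ_jl)) and renormalizes, so strongly interacting
   genes are pulled into shared pathways. The refined interaction score is
   R = 0.5 G + 0.5 C.
4. **Directed structure (BGM).** A Bayesian network with Gaussian-mixture
   observations is sampled by Metropolis–Hastings over single-edge moves,
   restricted to parent candidates from shared pathways and top-k R
   neighbours, with the Gibbs structure prior
   log p(𝒢 | R) ∝ −Σ_{u≠v} R_uv (1 − 𝒢_uv). Edge confidence is the
   model-averaged frequency over sampled DAGs, thresholded at 0.5.

Evaluation utilities score predictions against a reference with undirected
matching (TP/FP/FN, precision/recall/F1), midrank-corrected AUROC,
step-interpolated AUPR, and unpaired-t-test significance grouping.

## Worked example

```r
library(grnfuse)

scn  <- synthetic_scenario(I = 30, J = 40, L = 4, seed = 1)  # benchmark-like
ge   <- generate_expression(scn)
nets <- generate_truth_and_ppin(scn, ge$membership)

cfg <- pipeline_config(ge$X, nets$ppin, nets$truth, seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
[cluster] GMM: L = 7, MML = 1052.55
[extend-ppin] 118 edges at C >= 0.50
[ghmm] L = 8, MML = 472.89
[bgm] experiment mixture: K = 3
[bgm] 10 chains x 1000 iters, mean acceptance 61.5%
pipeline_result (fused): 30 genes, 30 predicted edges
TP 30  FP 0  FN 116 | precision 1.0000  recall 0.2055  F1 0.3409 | AUROC 0.7158  AUPR 0.6832
```

The log lines report each stage's dials: the pathway count L chosen by MML,
the number of extended-PPIN edges at the confidence cut-off, the experiment
mixture size K, and the MCMC acceptance rate. The report compares the final
directed network (direction-blind) with the ground truth: here all 30
predicted edges are true interactions (precision 1.0) covering 21% of the
145-edge truth network; the AUROC/AUPR rank the full confidence matrix. On
the same data, the expression-only pipeline
(`pipeline_config(..., mode = "ge_only")`) reaches F1 0.20 — the PPIN
evidence roughly doubles F1, the qualitative benefit the framework is built
around.

A command-line interface with per-stage subcommands
(`simulate`, `cluster`, `extend-ppin`, `ghmm`, `bgm`, `eval`, `run`) lives at
`inst/scripts/grnfuse.R`.

## Vignette

`vignettes/grn-fusion-methods.Rmd` documents the model assumptions, every
tunable parameter with its default and rationale, the synthetic-data
generators, numerical choices, and known limitations.
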