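---
title: "Overlapping group screening for gene-environment interactions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlapping group screening for gene-environment interactions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In survival genomics one often wants to know not only which genes and
which clinical/environmental variables drive prognosis, but which
*gene-environment (G-E) interactions* do.  With `q` environmental
covariates and `p` expression covariates the joint Cox model

$$\lambda(t \mid e, x, u) \;=\; \lambda_0(t)\,
  \exp(e'\alpha + x'\beta + u'\eta)$$

carries `q + p + qp` coefficients, where `u` stacks all elementwise
products `e_j x_k`.  At realistic scale (thousands of genes) direct
penalized regression over this space has little power for the
interaction block.  `ogscreen` implements a four-step screening
procedure that exploits pathway structure — genes grouped into
*possibly overlapping* gene sets — to cut the interaction search space
down before the final penalized fit.

## The latent-effect expansion

Overlap is handled by decomposing the gene coefficient vector into a
sum of group-specific latent vectors, `beta = S %*% gamma`, where the
binary matrix `S` (`p × d`, `d` = sum of group sizes) assigns one
latent coefficient to every (group, gene) membership.  Equivalently,
the columns of overlapping genes are duplicated in the design, after
which the groups are disjoint and an ordinary group-lasso penalty on
`gamma` penalizes each pathway as one block.  A gene's fitted effect is
the sum of the latent effects of every group that contains it
(`collapse_latent()`).  The expansion is deliberately
over-parameterized; the group penalty is what makes it identifiable in
practice.

## The four steps

1. **Candidate pathways.**  `fit_overlap_group_cox()` fits the Cox
   model with the environmental block unpenalized plus the expanded
   gene design under a group-lasso penalty (group weights
   `sqrt(group size)`).  The penalty level is chosen by k-fold
   cross-validated partial-likelihood deviance (Verweij-van
   Houwelingen), minimum rule.  Groups with a nonzero latent block form
   the candidate set `M_main` of size `A`.  Interaction columns do not
   enter this step.
2. **Group-level interaction tests.**  For each candidate pathway the
   `q × (pathway size)` interaction columns form one block `R`, tested
   jointly with the SKAT variance-component statistic
   `Q = m'RWWR'm`, where `m` are martingale residuals from the null
   Cox fit on `E` alone and `W` is a diagonal weight matrix with
   `sqrt(W_ii)` the Beta(1, 25) density at column `i`'s share of the
   block's total sample variance.  Under the null `Q` is distributed as
   a weighted sum of 1-df chi-squares with weights the eigenvalues of
   `Sigma = W R'(V - VE(E'VE)^{-1}E'V) R W`; tail probabilities come
   from numerical inversion of the characteristic function (see
   *Numerical choices*).
3. **Permutation threshold.**  To decide which group p-values are small
   enough, covariate rows (E and X together, outcomes fixed) are
   permuted `I = 30` times; each permutation refits the null model and
   recomputes all `A` p-values, and its minimum is recorded.  The
   cutoff `C_int` is the median of the `I` minima, and
   `M_int = {b : p_b < C_int}` (strict).  Using the *minimum* makes the
   threshold a family-wise guard: on null data the original p-values
   rarely beat it.
4. **Final model.**  A Ridge- or Lasso-penalized Cox model
   (`glmnet`, CV-min, event-stratified folds) is fitted on all
   environmental columns, the deduplicated genes of `M_main`, and the
   interaction columns of the groups in `M_int`.  Its linear predictor
   on test data is the prognostic index (PI) used by all prediction
   metrics.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `I` | 30 | permutation replicates behind `C_int` |
| `folds` | 10 | CV folds, event-stratified, steps 1 and 4 |
| `nlambda` / `lambda_min_ratio` | 100 / 1e-3 | step-1 path resolution |
| step-4 path ratio | 1e-2 | glmnet default for the final fit |
| group weights | `sqrt(size)` | conventional group-lasso scaling |
| `penalize_environment` | `TRUE` | step 4 penalizes E uniformly; set `FALSE` to exempt it |
| Beta weight parameters | (1, 25) | unsupervised variance-share weights |
| prescreen `k` | 2000 | genes kept by IPCW Kendall's tau in the real-data path |

Design choices that were genuinely open, and how we resolved them:

* **Ties.**  Breslow approximation throughout — it is the baseline the
  SKAT `P` matrix is built from, so using it everywhere keeps the null
  machinery internally consistent.
* **Step 1 scope.**  The candidate-pathway model contains E
  (unpenalized) and gene main effects only.  Interactions are screened
  in steps 2-3; including them in step 1 would double-count the
  search and is not what the procedure describes.
* **Step 4 penalization.**  All columns, including E, are penalized
  uniformly by default; an unpenalized-E option is exposed because
  some analysts prefer forced-in clinical covariates.
* **Gene main effects in step 4** enter once each (original `beta`
  scale), not as latent duplicates: the final model is a prediction
  model, not a group-selection device.
* **Single-interaction groups.**  The Beta(1, 25) density is zero at
  `v = 1`, which would make an `l = 1` block untestable; the weight
  falls back to 1 (logged).  A zero weight cannot be the intent of a
  power-improving weighting scheme.
* **Selection cutoff** is the strict inequality `p_b < C_int`; a
  p-value exactly at the cutoff is excluded.

## Numerical choices

* **Weighted chi-square tails.**  `weighted_chisq_tail()` integrates
  the Imhof characteristic-function inversion integrand by composite
  Simpson quadrature with a step tied to the integrand's oscillation
  frequency and an integration limit from an analytic tail bound
  (including a van der Corput-type bound for few-eigenvalue spectra);
  a doubled-resolution pass must agree within 1e-6 or the routine
  falls back to Liu-type four-moment matching (`method_used` records
  which path was taken).  Eigenvalues are computed from the
  symmetrized `Sigma`, truncated below `1e-10 * max` for rank, and
  additionally below `1e-6 * max` inside the tail routine (an O(1e-6)
  perturbation of p) to keep wide blocks cheap.  p-values are clipped
  to `[1e-14, 1]`.  Accuracy is tested against closed-form chi-square
  cases (1e-4) and a 1e5-draw Monte-Carlo oracle (3 SEs).
* **Group-lasso solver.**  Step 1 uses an accelerated proximal
  gradient (FISTA) path solver written in C++ (RcppArmadillo) with
  backtracking line search, adaptive restart and warm starts along a
  log-spaced path from `lambda_max`.  Columns are standardized
  internally and coefficients returned on the original scale.
  Linear predictors are max-shifted before exponentiation so extreme
  risk scores cannot overflow.
* **Degenerate inputs.**  All-constant design columns are dropped with
  a warning; an empty step-1 selection terminates the pipeline with an
  E-only model and an `early_stop` flag; null-model refit failures
  inside a permutation replicate are redrawn (at most 5 retries,
  logged).

## The simulation world

`sim_config()` encodes the benchmark design this package tests itself
against: 300 training and 100 test subjects; 5 environmental variables
with effects `(1.5, 2.25, 3, -1.5, 0)` and AR(1) correlation `0.3^|j-k|`;
500 genes with AR(1) correlation `0.5^|j-k|`, independent of E,
organized into 25 chain-overlapping groups (sizes
3,3,3,6,6,6,9,9,9,15,15,15,24,24,24,36,36,36,45,45,45,60,60,60,38;
consecutive overlaps 1,1,0,2,2,0,3,3,0,5,5,0,8,8,0,12,12,0,15,15,0,
20,20,0 — 632 latent effects in total).  Groups 1, 7, 13 and 19 carry
constant latent effects 3, 3, 2, -2; the six effective interactions are
`E1:G22, E1:G24, E2:G26` (in group 7) with effects `1.5, 1.5, 2` and
`E2:G78, E3:G83, E3:G88` (in group 13) with effects `-1, -1.5, -2`.
Altogether 91 of 3,005 coefficients are nonzero.  Survival times are
exponential with hazard `10 * exp(linear predictor)` — the printed
constant-baseline reading of the generating model — computed in log
space with times floored at `1e-300`; censoring is `Uniform(0, b)` with
`b` calibrated by Monte Carlo so that `P(C < T)` hits the target rate
(0.30 / 0.50 / 0.70), and the same `b` is reused for the test cohort
(same-mechanism reading; the alternative was not specified).  One
master seed spawns named substreams for covariates, survival times,
censoring, and the test set.

What the generator does *not* emulate: real expression data's
heavy-tailed, contaminated distributions (the motivation for the
rank-based prescreen), missing clinical values (rejected, not imputed),
and pathway databases in which one gene sits in many distant groups
(the chain layout overlaps only neighbours; arbitrary overlap is
representable through `pathway_collection()` but not generated).  The
linear predictor of this design has a standard deviation in the tens,
so survival times span many orders of magnitude — effectively a
rank-deterministic regime.  A green benchmark therefore establishes
that the pipeline recovers strong, pathway-aligned signal under heavy
correlation; it says nothing about weak-signal calibration, which is
what the type-I-error and permutation-calibration tests cover instead.

## Desk-scale evaluation protocol

The reference study aggregates 200 simulation replicates per censoring
level.  The packaged acceptance suite runs 10 replicates per cell with
a 60-point step-1 path (all other settings at their defaults: 10-fold
CV, `I = 30`), which keeps the full suite inside a CI budget while
leaving the Monte-Carlo error of a median of 10 replicates well inside
the ±0.05 acceptance tolerance used for proportions and concordance
indices.  The ungrouped-genes question in the real-data path (drop
them or pool them as one extra group) is exposed as
`filter_pathways(..., ungrouped = c("discard", "pool"))`; the two give
identical final models whenever the pooled group is never selected.

## Known limitations

* The procedure does not enforce main-interaction hierarchy; an
  interaction can be selected without its gene main effect.
* Selection happens at the pathway level in steps 1-3; gene-level and
  pathway-level selection are not performed simultaneously.
* Only Ridge and Lasso penalties are offered for the final model.
* The IPCW Kendall's tau prescreen uses the standard
  censoring-Kaplan-Meier pair weighting (left-continuous evaluation,
  unordered pairs dropped, survivor floored at 0.05); other weighting
  variants exist and differ in small samples.
* `deviance` is reported as `2 (loglik_null - loglik_PI)` from the
  univariate PI Cox model on test data, i.e. negative when PI is
  informative; this reconstruction matches the sign convention
  ("smaller is better") of the benchmark tables it mirrors.
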