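---
title: "Surprisal analysis of expression matrices: model, estimation and design choices"
author: "surprisal package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprisal analysis of expression matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surprisal)
```

# The model

Surprisal analysis treats a transcriptome as a system at a maximal-entropy
*balanced state* deflected by a small number of *constraints*. For gene $i$
and sample $s$ with abundance $X_i(s) > 0$ (FPKM-like units):

$$Y_i(s) \;=\; \ln X_i(s) \;=\; \ln X_i^0 \;+\; \sum_{\alpha=1}^{N_\alpha}
G_{i\alpha}\,\lambda_\alpha(s).$$

The balanced-state term $\ln X_i^0 = G_{i0}\lambda_0$ is common to all
samples; each constraint $\alpha \ge 1$ contributes a gene-weight vector
$G_{\cdot\alpha}$ (the *phenotype*) scaled per sample by a Lagrange
multiplier $\lambda_\alpha(s)$. The working assumptions are:

* abundances are strictly positive after filtering, so the log is defined;
* one component dominates every sample with a common sign (the balanced
  state), i.e. samples are far more alike than different;
* deviations are low-rank: a few constraints capture the systematic
  biology, the residual components are noise.

# Estimation

All quantities come from one singular value decomposition
$Y = U S V^{\mathsf T}$: $G_{\cdot\alpha}$ is column $\alpha$ of $U$
(orthonormal by construction, checked to $10^{-8}$ by the class validity
method) and $\lambda_\alpha(s) = S_{\alpha\alpha} V_{s\alpha}$. Components
are ordered by singular value, so $\alpha = 0$ is the dominant term. With
all components retained the reconstruction is exact; truncating after $k$
constraints gives the best rank-$(k+1)$ approximation, with Frobenius error
equal to the root of the summed squared discarded singular values. The test
suite checks both against an independent eigensolver oracle
(`eigen(crossprod(Y))`).

**Retained constraints.** `surprisalFit()` always computes and stores the
full spectrum; `nConstraints` (default 2) only marks how many constraints
are interpreted. Two is the natural default for a two-factor design — one
axis per experimental factor — and matches what the dominant singular
values justify on data of this kind; any other truncation remains available
afterwards without refitting.

**Sign conventions.** An SVD is unique only up to a joint sign flip per
component, so the package fixes the signs deterministically:

* $\lambda_0(s)$ is forced positive for every sample. If the first
  component's sample loadings have mixed signs, the balanced-state
  assumption does not hold for that matrix and the fit aborts rather than
  returning something uninterpretable.
* For $\alpha \ge 1$ the component is flipped so that the lexicographically
  smallest sample of that constraint's *reference group* has a positive
  multiplier. Declaring the exponential-phase samples the reference for
  constraint 1 and the high-dose samples for constraint 2
  (`referenceGroups()`) yields the conventional orientation — positive
  $\lambda_1$ for exponential growth, positive $\lambda_2$ for high dose.
  Without a declared reference the rule falls back to the smallest sample
  label overall, which is still deterministic but carries no biological
  orientation.

**Abundance floor.** Logs are taken of $\max(X, \mathrm{floor})$ with a
default floor of 0.01 abundance units — two orders of magnitude below a
"present" transcript at FPKM-like scale, so it only guards genes that
slipped through filtering. The floor is recorded in the fitted model. The
recommended pipeline, however, is `filterGenes()` first: the default
`all_positive` policy keeps a gene only when it is strictly positive in
every sample, because the log transform is undefined at zero. The exact
gene count such a filter retains depends on the upstream quantification and
is not something this package tries to standardize; the removed-gene count
is reported on each call.

**Replicates.** `collapseReplicates()` reduces each (concentration, time)
cell to one profile. The default is the arithmetic mean of abundances
(`mean_linear`), i.e. averaging before the log, which treats the replicate
abundances as the measured quantity; the geometric mean (`mean_log`) is
offered for users who prefer averaging in the space the model lives in. The
per-gene per-cell replicate standard deviation (log-space under
`mean_log`) is kept as a `dispersion` assay and feeds the error bounds.

# Error bars on the multipliers

Because $\lambda_\alpha(s) = \sum_i G_{i\alpha} Y_i(s)$ with
$\sum_i G_{i\alpha}^2 = 1$, independent per-gene log-space errors with
standard deviation $\sigma_i(s)$ propagate to a multiplier perturbation of
standard deviation

$$\beta_\alpha(s) \;=\; \Big(\sum_i G_{i\alpha}^2\,
\sigma_i(s)^2\Big)^{1/2}.$$

`lambdaErrorBounds()` returns $n_\sigma \beta_\alpha(s)$. At the default
$n_\sigma = 1$ this is the propagated standard error itself (with constant
dispersion $c$ it equals $c$ exactly, a direct consequence of the unit-norm
weights); at $n_\sigma = 3$ it is an envelope the realized perturbation
respects in over 99% of Gaussian draws, which is the sense in which these
bars function as upper bounds on the actual error. The Monte-Carlo property
tests perturb $Y$ at the stated dispersion 1000 times and verify the
three-sigma envelope's coverage. The bars are exactly zero wherever the
replicates agree perfectly, and monotone in every dispersion entry. A
model-free cross-check, `bootstrapLambda()`, resamples replicates within
each condition cell, recollapses and refits; its per-$\lambda$ standard
deviations should sit near $\beta_\alpha(s)/\sqrt{R}$-scaled agreement with
the propagated values and vanish on noiseless data.

# Gene ranking and the set ratio

Within a phenotype, genes are ranked by $G_{i\alpha}$, descending; the
top and bottom $n = 100$ form the differential lists. Ties are broken by
gene identifier (ascending) so rankings are bit-reproducible; ties have
measure zero on real data, so the rule only matters for degenerate inputs.
Balanced-state *stability* is the sign of $G_{i0}\lambda_0$ — positive
means baseline abundance above one in the log's units; an exactly-zero
term is labeled unstable and flagged.

For a gene set $J$, the positive and negative weights under constraint
$\alpha$ are $P = \sum G_{i\alpha}^2$ over members with positive weight and
$N = \sum G_{i\alpha}^2$ over members with negative weight; the set ratio
is $SR = P/N$. Conventions, chosen once:

* genes with exactly zero weight count toward neither $P$ nor $N$
  (strict inequalities), so deleting a zero-weight member changes only the
  member count;
* $SR = \infty$ when $N = 0 < P$ (an all-positive set — the strongest
  positive call) and $SR = 0$ when $P = 0 < N$; serialization writes the
  token `Inf`, never a numeric sentinel;
* a set whose present members all have zero weight has undefined $SR$: the
  row is kept, flagged `NA`, and excluded from ranking;
* sets with fewer than 10 members *present in the fitted model* are
  omitted — the filter exists for statistical support, so it counts genes
  actually contributing, not nominal set size;
* calls: $SR > 2$ marks the positive pole of the phenotype, $SR < 0.5$ the
  negative pole;
* ranking places the one-sided sets at the extremes: in the positive
  direction $\infty$-ratio sets first (ordered by $P$ descending), then
  finite ratios descending; mirrored for the negative direction.

$SR$ has no null distribution: a set whose members all carry tiny weights
can still show an extreme ratio (the decoy sets in the worked example
illustrate this). The statistic orders pathways by sign coherence of their
weights; it is not a significance test, and the package deliberately
attaches no p-values to it.

# What the synthetic generator emulates

`simulateSurprisalData()` builds data the way the model assumes they arise,
on a 4-concentration × 4-timepoint grid with 3 biological replicates by
default (2000 genes):

* baseline $b_i \sim N(2, 2^2)$ in log space, so both stable
  ($b_i > 0$) and unstable genes exist and `classifyStability()` is
  exercised in both directions;
* two sparse constraint-weight vectors — 20% of genes loaded, loadings
  sign-balanced so both poles of each phenotype are populated, then
  orthogonalized against the baseline direction and each other and
  normalized — sparse so that top-100 lists are meaningful;
* multipliers with the declared sign structure: $\lambda_1$ positive for
  the first half of the timepoints (exponential phase), negative after;
  $\lambda_2$ negative for the lower, positive for the upper half of the
  concentrations. Amplitudes default to 15% and 10% of the baseline norm,
  keeping $\lambda_0$ dominant and nearly constant across samples — the
  regime the method is meant for. Because each profile sums to zero across
  the grid, the three planted directions are mutually orthogonal on both
  sides and noiseless data are identified exactly (up to signs, fixed by
  the conventions above);
* i.i.d. log-normal replicate noise, default sd 0.1 — a realistic
  biological-replicate scatter for well-controlled batch cultures;
* planted gene sets of 30 genes drawn from same-sign loaded genes, one per
  constraint and direction, plus random decoy sets.

All draws come from one seeded stream in fixed order, so equal seeds give
bit-identical experiments.

What it does **not** emulate: read counting and library-size normalization
(inputs are abundances, not reads), gene–gene correlation beyond the
planted components, heteroscedastic or outlying replicates, dropped
libraries leaving unbalanced cells, and any annotation structure. Passing
the recovery tests therefore shows the estimator and enrichment machinery
are correct under the model's own assumptions — not that real data satisfy
those assumptions.

# Validation problem sizes

The simulation studies in the test suite use the default design (2000
genes, $4 \times 4 \times 3$) over 100 seeds for sign-separation and
planted-set recovery, 300-gene versions over 10 seeds per noise level for
the noise-degradation sweep, and 1000 Monte-Carlo perturbations for the
error-bound envelope — sizes at which each study completes in seconds
while keeping the binomial pass criteria (≥ 95/100 runs) meaningful.

# Numerical and degenerate-input choices

* Orthonormality and reconstruction tolerances are $10^{-8}$ — far above
  double-precision SVD error, far below any biological signal.
* Readers are strict: duplicate identifiers, negative or missing values
  and ragged rows are hard errors naming the offending coordinates;
  nothing is imputed silently.
* `clusterGenes()` seeds the RNG internally, z-scores profiles (constant
  genes get a zero profile), sorts genes by identifier before clustering
  (so results are invariant to input row order), retries a bounded number
  of times on empty clusters, and treats $k$ equal to the gene count as
  the exact zero-inertia optimum rather than calling the iterative
  algorithm.
* `doublingsPerDay()` is the closed form
  $\log_2(N_{end}/N_{start}) / (\Delta t / 24)$; it requires recorded
  time points and is validated on analytic cases, since published
  doubling-rate tables are derived from counts not shipped with this
  package.

# Known limitations

* The balanced-state positivity check makes matrices with genuinely
  bimodal sample loadings unfittable by design; such data violate the
  method's premise.
* Time and dose are categorical condition indices; no continuous-time
  modeling is attempted.
* The set ratio carries no significance measure (see above).
* The propagated error bars assume independent per-gene errors; correlated
  replicate error would require the bootstrap route.
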