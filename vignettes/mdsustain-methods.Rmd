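---
title: "Subtype and stage inference with missing biomarker data: model and methods"
author: "mdsustain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype and stage inference with missing biomarker data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsustain)
```

## The model

`mdsustain` fits a mixture of ordered biomarker-progression sequences to a
cross-sectional matrix of Z-scores.  Each *subtype* $c$ is a strict
ordering of $N$ Z-score *events*: biomarker $i$ reaching each of its
thresholds $Z_{i1} < \dots < Z_{iR_i}$ (for example 1, 2 and 3 control
standard deviations of abnormality).  Along a latent timeline
$t \in [0, N+1]$, each biomarker follows a piecewise-linear trajectory
$g_i(t)$ anchored at $(0, 0)$, at $(p_r, Z_{ir})$ for each of its events
(where $p_r$ is the event's position in the subtype's sequence), and at
$(N+1, Z_i^{max})$.  A subject at stage $k$ occupies the timeline interval
$[k, k+1]$; stage 0 means no event has occurred ("normal appearing").

The data likelihood for subject rows $x_j$ is

$$
P(X \mid M) \;=\; \prod_{j=1}^{J} \sum_{c=1}^{C} f_c \sum_{k=0}^{N}
  \int_{k}^{k+1} P(t) \prod_{i=1}^{I} P(x_{ij} \mid t)\, dt ,
$$

with mixture fractions $f_c$, a stage prior $P(t)$ (uniform, $1/(N+1)$,
by default), and

$$
P(x_{ij} \mid t) =
\begin{cases}
\mathcal{N}\!\left(x_{ij};\, g_i(t),\, \sigma_i\right) & x_{ij}
  \text{ observed} \\
1 / Z_i^{max} & x_{ij} \text{ missing.}
\end{cases}
$$

The second branch is the missing-data device at the heart of the package:
an unobserved biomarker is assigned a uniform density over that
biomarker's Z-score range.  Because this factor is a constant in $t$, $c$
and the sequence, a missing entry is *posterior-inert* — it cancels from
every posterior and likelihood-ratio computation, so incomplete subjects
still contribute through their observed biomarkers without biasing the
estimated orderings.  The constant is $1/Z_i^{max}$ with the *configured*
ceiling, independent of the observed data range, and it is used as
written rather than renormalised over an explicit support.  The
alternative strategies (subject deletion, column-mean imputation, KNN
imputation) are provided as data transforms for benchmarking against this
marginalisation.

## Numerical choices

* **Quadrature.** The stage integral is approximated by a midpoint
  evaluation at $t = k + 0.5$ with interval width 1.  On piecewise-linear
  trajectories a single interior point captures the integrand well, and
  the same representative timepoint is used by the synthetic-data
  generator, keeping generator and likelihood consistent.  The reference
  quadrature is deliberately simple and localised in one kernel, so a
  multi-point rule can be swapped in without touching the fitting code.
* **Log space.** All accumulation uses log densities and log-sum-exp;
  natural-scale densities only appear at API edges
  (`observationDensity`, `stageLikelihoods`).
* **Ties.** Arg-max ties in posteriors resolve to the lowest subtype,
  then lowest stage.  Credible sets take cells in decreasing probability
  with ties ordered by subtype then stage, giving a deterministic,
  minimal set; with a uniform posterior over 20 cells and mass 0.95, the
  set has exactly 19 cells.
* **Defaults.** $\sigma_i = 1$ for every biomarker (the inputs are
  control-referenced Z-scores, so unit noise is the natural scale) and a
  uniform stage prior; both are overridable.

## Fitting

Estimation follows the event-based-model family:

1. **Greedy sequence optimisation** (`optimizeSequence`): from each of
   `nStartpoints` random valid orderings, events are repeatedly removed
   and re-inserted at the best position that respects within-biomarker
   level order, until no move improves the (weighted) log likelihood.
2. **EM** (`fitEM`): responsibilities
   $r_{jc} \propto f_c \sum_k P(k) L_c(j,k)$, fraction updates
   $f_c \leftarrow \mathrm{mean}_j\, r_{jc}$, and per-subtype sequence
   re-optimisation under weights $r_{jc}$.  Each step does not decrease
   the marginal likelihood, which the test suite asserts on every run.
   An emptied cluster is re-seeded with a random sequence and a warning.
3. **Hierarchical splitting** (`fitSustain`): the $C$-subtype model is
   initialised from the $(C-1)$-subtype solution by splitting each
   cluster in turn — `nSplitTrials` uniform random bipartitions of its
   ML-assigned subjects, each half fitted separately, a 2-subtype EM
   inside the cluster — and refitting the best candidate by full EM.
4. **MCMC** (`mcmcUncertainty`): Metropolis–Hastings over sequences
   (move one random event of one random subtype to a random valid
   position) jointly with a Gaussian perturb–clip–renormalise proposal on
   the fractions (sd `fracSd = 0.01`), accepted with
   $\min(1, L_{new}/L_{old})$.  The per-subtype event-by-position
   frequency matrices summarise positional uncertainty; if a sampled
   state beats the stored optimum the fit is re-selected to it.  The
   fraction proposal is only approximately symmetric (clipping at zero
   breaks exact symmetry); we accept this bias in the fraction posterior
   as the price of a simple proposal, and document it here rather than
   hide it.

Fitting hyper-parameters (`nStartpoints = 25`, `nMCMC = 1e5`,
`nSplitTrials = 5`, `emTol = 1e-6`, `nEMIterMax = 100`) are package
choices in line with this algorithm family — the underlying method
specification does not pin them down — and every one is exposed in
`sustainOptions()`.  All randomness flows through R's global RNG, so
`set.seed()` (or `sustainOptions(seed=)`) makes whole fits bit-for-bit
reproducible.

## What the synthetic generator emulates

`simulateModel()` / `simulateSubjects()` reproduce the benchmark design
used to validate the missing-data device: 500 subjects × 10 biomarkers,
3 subtypes with mixture fractions
$f_c = (2 + (C-c)) / (2C + \sum_{c'}(C-c'))$ — $(4/9, 3/9, 2/9)$ at
$C=3$ — uniform stages on $\{0..N\}$, event levels $(1,2,3)$ with
$Z^{max} = 5$ and unit observation noise with no cross-biomarker
covariance.  Subjects are generated at the stage-representative midpoint
$t = k + 0.5$ (a continuous-$t$ mode is available behind
`continuousTime = TRUE`; the stage-midpoint convention was chosen because
stages, not times, are the simulated quantity, and it keeps the generator
aligned with the likelihood quadrature).  `injectMissingness()` deletes
exactly $n$ cells uniformly at random (MCAR), e.g. 150 and 2000 cells
(3% and 40%) on the 500 × 10 design.

What this does *not* emulate: correlated biomarkers, informative
(MAR/MNAR) missingness, measurement batch effects, or continuous
calendar time — the model timeline is an arbitrary pseudo-time, not
years.  Passing benchmarks on these simulations therefore demonstrates
correctness of the machinery under the stated design, not robustness to
those real-data features.

## Evaluation conventions

* **Sequence similarity**: $1 - d/\binom{N}{2}$ over discordant event
  pairs (1 = identical, 0 = fully reversed).  The similarity is computed
  per estimated cluster after optimally matching estimated to true
  clusters (enumeration over the $C!$ permutations of the confusion
  matrix), and also averaged.
* **Subtyping accuracy**: percent of scored subjects whose matched
  subtype equals the ground truth.  Subjects whose estimated ML stage is
  0 are excluded by default — a normal-appearing subject is not
  subtypable — and the exclusion is configurable.
* **Staging error**: mean ± sample SD (n−1) of the *absolute*
  stage difference.  A signed mean would hide symmetric errors; the
  absolute reading matches error magnitudes being reported as positive.
* **Longitudinal consistency**: a follow-up is subtype-consistent if it
  keeps the baseline subtype or progresses out of normal appearing, and
  stage-consistent if its ML stage does not regress; credible-set overlap
  between visits is reported alongside.

## Problem sizes used in the shipped checks

The packaged test-suite and the acceptance script exercise the machinery
at reduced scale — e.g. 200 subjects × 5 biomarkers with two subtypes and
three replicates for the strategy comparison, and a few hundred subjects
for parameter recovery — sizes chosen so the whole suite completes on a
single CPU in minutes while leaving the headline comparison — uniform
marginalisation ahead of mean imputation at heavy missingness —
resolvable above Monte-Carlo noise.  One caution about deletion at
reduced scale: with only five biomarkers, 40% cell-wise missingness
still leaves a handful of fully observed subjects, so deletion remains
(barely) fittable and its accuracy is computed on that self-selected
complete subsample, which flatters it relative to strategies scored on
every subject; at the full design (ten biomarkers) essentially no
complete subjects remain and deletion is infeasible.  The full-scale benchmark design
(500 × 10, three subtypes, full MCMC) is reproduced by
`scripts/benchmark_full.R`; it is a multi-hour single-CPU computation and
is not run inside the test suite.

## Known limitations

* Biomarkers are conditionally independent given stage; no covariance
  modelling.
* The stage integral uses one midpoint; posteriors over stages inherit
  that resolution.
* KNN imputation follows the simple per-cell procedure with
  package-chosen conventions where the benchmarked procedure is
  under-specified: neighbours must have the target biomarker observed,
  features use each subject's observed values only, pairwise-complete
  distances are rescaled by $\sqrt{I/n_{shared}}$, ties break to the
  lower subject index, and $K$ defaults to 5.
* Covariate selection in preprocessing uses a single backward pass at
  $\alpha = 0.05$ per coefficient (two-sided t-test), with an iterated
  mode behind a flag; the 95th-percentile ceiling uses the
  linear-interpolation quantile with halves rounded away from zero.
  These conventions are stated because the upstream procedure they
  implement leaves them open.
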