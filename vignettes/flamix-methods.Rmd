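---
title: "Methods behind flamix: the fast Laplace model and single-stage genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind flamix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flamix)
```

This vignette documents the statistical models, the algorithmic and
numerical choices, and the limitations of `flamix`. Everything asserted
here is computed either by the test suite
(`tests/testthat/`) or by `scripts/acceptance.R`; the vignette explains
*why* the package does what it does.

# The whole-genome regression model

`fitFLM()` fits

$$ y = 1\mu + M\beta + \varepsilon, \qquad
   \beta_j \mid \tau_j^2 \sim N(0, \tau_j^2\sigma^2_\varepsilon), \qquad
   \varepsilon \sim N(0, \sigma^2_\varepsilon I), $$

where $M$ is the $n \times p$ matrix of marker codes with
$\{aa, Aa, AA\}$ coded $\{-1, 0, 1\}$, entered raw (no centering or
scaling — the intercept absorbs the mean, and the shrinkage machinery is
defined on the raw cross-products $m_j'm_j$).

Estimation is iterated conditional expectation (coordinate descent): one
*sweep* updates, in this exact order,

1. the intercept, $\mu \leftarrow \mu + n^{-1}\sum_i \varepsilon_i$,
   after which the residuals sum to zero;
2. for each polymorphic marker $j = 1, \dots, p$ (fixed ascending order):
   the effect
   $\beta_j \leftarrow (m_j'\varepsilon + \beta_j\, m_j'm_j)\,/\,(m_j'm_j + \tau_j^{-2})$
   with the residual corrected by $-m_j\,\Delta\beta_j$; then the
   full-conditional effect variance
   $\sigma^2_{\beta j} \leftarrow \beta_j^2 + \sigma^2_\varepsilon/(m_j'm_j + \tau_j^{-2})$;
   then the regularizer (next section);
3. the residual variance
   $\sigma^2_\varepsilon \leftarrow y'\varepsilon/(n-1)$.

Sweeps repeat until $\sum_j (\Delta\beta_j)^2 < $ `tol` (default
$10^{-8}$) or `maxIter` (default 300) sweeps have run. Both defaults are
the package's standing convergence policy; on the simulated scenarios in
the test suite ($n \ge 500$, $p = 500$) fits converge in 40–80 sweeps,
well inside the cap.

## The Laplace regularizer

Each marker has its own regularizer $\tau_j^{-2}$, updated as the
conditional expectation of an inverse-Gaussian density,

$$ \tau_j^{-2} \leftarrow \sqrt{\lambda^2 \sigma^2_\varepsilon \,/\,
   \sigma^2_{\beta j}}, \qquad
   \lambda^2 = \sum_{j=1}^p \sigma^2_{m_j}, $$

which collectively shapes the marker effects into a Laplace
(double-exponential) distribution: markers with a large full-conditional
variance are shrunk gently, background markers strongly. The scale
$\lambda^2$ is the sum of marker variances, a quantity of the data, so
the model is free of tuning parameters.

The square root matters. A multiplicative form without it,
$\tau_j^{-2} \propto \lambda^2\sigma^2_\varepsilon/\sigma^2_{\beta j}$,
is dimensionally inconsistent (it carries units of $m_j'm_j$ squared) and
is degenerate whenever $\lambda^2 > 1$: substituting the null-marker
variance $\sigma^2_{\beta j} \approx \sigma^2_\varepsilon/(m_j'm_j +
\tau_j^{-2})$ gives the fixed-point condition
$\tau_j^{-2} = \lambda^2 (m_j'm_j + \tau_j^{-2})$, which has no finite
solution, so *every* effect — causal or not — runs to infinite shrinkage
and the fit collapses to the intercept. The square-root form has the
finite null fixed point $\tau_j^{-2} \approx \lambda\sqrt{m_j'm_j}$
while leaving a marker of effect size 1 nearly unshrunken; it is the
form under which the solver recovers simulated QTL (see
`test-acceptance.R`).

Initialisation follows the same data-driven logic: all
$\tau_j^{-2} \leftarrow \lambda^2$, $\beta = 0$, $\mu = 0$, and
$\sigma^2_\varepsilon \leftarrow \mathrm{var}(y)$ (an upper bound on the
residual variance, needed before the first step-3 update).

## Numerical guards and degenerate inputs

* $\sigma^2_\varepsilon$ and $\sigma^2_{\beta j}$ are floored at
  $10^{-10}\,\mathrm{var}(y)$ and $\tau_j^{-2}$ capped at $10^{12}$: on
  perfect-fit toy data the multiplicative updates would otherwise
  collapse to exact zeros.
* Monomorphic markers (constant columns, detected once at setup as
  zero column variance) are excluded from the sweep with $\beta_j$ fixed
  at 0: a constant column carries no information, and a constant
  *non-zero* column is collinear with the intercept. An all-monomorphic
  matrix yields an intercept-only fit with a warning.
* Missing phenotypes are rejected at input — the model has no
  missing-data mechanism, and silent imputation would change the
  estimand.
* A constant phenotype vector returns $\mu$ equal to that constant and
  $\beta = 0$ (the variance floor keeps the state positive).
* `fixedTauInv2` freezes the regularizer (a value of 0 gives plain
  coordinate-descent least squares). This test mode is how the solver is
  validated: with a frozen common regularizer $c$ its fixed point is
  exactly the dense system $(M_c'M_c + cI)\beta = M_c'(y - \bar y)$ with
  column-centered $M_c$ — the centering arises from eliminating the
  unpenalized intercept, and the tests compare against this closed form
  at tolerance $10^{-6}$.

Equivalence checks between two iterative paths (e.g. the single-stage
reduction below) are run at much tighter tolerances than the $10^{-8}$
default, because two iterates each stopped at $10^{-8}$ can sit
$\sim\!10^{-4}$ apart even though they share a fixed point.

# The iterative single-stage model

`fitSingleStage()` fits the replicated-trial model

$$ y = Xb + Z(M\beta) + e, \qquad e \sim N(0, R\,\sigma^2_e), $$

with $X$ the environment fixed-effect design (intercept plus treatment
contrasts, first environment dropped — the reduction that makes $X$ full
rank), $Z$ the genotype incidence, and diagonal $R$ (supplied as per
observation weights; dense residual correlation is out of scope).
Nothing ever materialises $ZM$: each outer iteration runs

1. $b \leftarrow (X'R^{-1}X)^{-1}X'R^{-1}(y - Za)$ (a dense solve on the
   small $f \times f$ system);
2. $u_0 \leftarrow (Z'R^{-1}Z)^{-1}Z'R^{-1}(y - Xb)$ — per-genotype
   weighted means, no matrix built;
3. one coordinate-descent sweep (configurable via `innerSweeps`) on
   $u_0 = M\beta + \epsilon$, where $\epsilon$ is genetic signal not
   captured by the markers, with optional genotype weights
   $\omega = \mathrm{diag}(Z'Z)$ (`weighting = "reps"`);
4. $a \leftarrow M\beta$.

The default of one inner sweep makes the scheme fully interleaved
Gauss–Seidel; running the marker step to convergence inside each outer
iteration gives the same fixed point at higher cost. Convergence is
declared when the mean squared change in $a$ drops below `outerTol`
(default $10^{-8}$); non-convergence returns a warning, never an error,
so long pipelines keep their partial state. Genotypes without
observations are excluded from the fit (their $u_0$ is undefined) and
predicted afterwards from $a = M\beta$; the marker step carries no
intercept because $Xb$ absorbs the mean.

With one observation per genotype, identity incidence and intercept-only
$X$, steps 1–4 collapse exactly to the plain FLM — the test suite checks
$\max_j|\Delta\beta_j| < 10^{-6}$ on a 200 × 500 instance.

The marker-step residual variance uses the count-based denominator
$\sigma^2_\epsilon = u_0'\Omega\epsilon/(n_g - 1)$: the weights are
relative precisions, so the number of genotype-level responses, not the
weight sum, sets the degrees of freedom. (A weight-sum denominator
underestimates the genotype-level variance by roughly $n_g/N$ on
unbalanced trials and mis-calibrates the shrinkage.)

## Calibrating the Gaussian prior (RR-SS)

The ridge variant replaces the per-marker regularizer by one shared
$\lambda_r = \sigma^2_e/\sigma^2_\beta$. How to estimate
$\sigma^2_\beta$ is a genuine design choice:

* The *pooled full-conditional (EM) update*,
  $\sigma^2_\beta = \bigl(\beta'\beta + \sigma^2_\epsilon \sum_j (m_j'
  \Omega m_j + \lambda_r)^{-1}\bigr)/p$, is exact for orthogonal
  predictors. Linked markers are far from orthogonal: the diagonal trace
  ignores the off-diagonal posterior covariance, underestimates the
  posterior mass of $\beta$, and the update spirals to a fixed point
  whose $\lambda_r$ can sit an order of magnitude above the REML value —
  costing RR-SS 0.1–0.2 of accuracy under dense architectures (measured
  against the GBLUP oracle during development).
* The package therefore calibrates by *moments* whenever replication
  identifies the residual variance (pure-error degrees of freedom
  $N - n_g \ge 10$): $\sigma^2_e$ from the within-genotype spread of
  $y - Xb - Zu_0$, and
  $\sigma^2_\beta = (\mathrm{var}(u_0) - \sigma^2_e\,\overline{1/\omega})
  \,/\, \lambda^2$
  from the variance decomposition of the genotype means. This is the
  same style of moment approximation the additional-random-effect
  machinery uses for non-orthogonal designs (see
  `updateExtraVariance(mode = "approx")`). With it, RR-SS tracks the
  GBLUP oracle to correlation > 0.99 and to ~0.02 accuracy at both 10
  and 100 QTL.
* On unreplicated data the moment route is unidentifiable and the pooled
  EM update is the fallback.

The Laplace prior keeps its per-marker full-conditional updates
throughout: its heavy tail is exactly the point of the method, and the
per-marker form is robust where the pooled Gaussian one is not.

## Additional random effects

`fitExtraRandomEffect()` adds a term $Wg$, $g \sim N(0, I\sigma^2_g)$,
by conditioning: $(W'R^{-1}W + kI)g = W'R^{-1}(y - Xb - Za)$ with
$k = \sigma^2_e/\sigma^2_g$, solved by per-coefficient Gauss–Seidel (no
inverse materialised). Its variance component uses the full-conditional
estimator
$\sigma^2_g = g'g / \bigl(n_w - k\sum_j (w_j'w_j + k)^{-1}\bigr)$
(`mode = "exact"`), or for non-orthogonal designs the moment form
$\sigma^2_g \approx (y - Xb)'Wg / (n \sum_j \sigma^2_{w_j})$ with $n$
the observation count (`mode = "approx"`). The two agree within 10% on
near-orthogonal designs (tested); the approximation is the one to use
for, e.g., spatial adjacency matrices.

# Reference implementations used as oracles

* **GBLUP oracle** (`gblupOracle`): genomic relationship
  $G = M_cM_c'/c$, $c = 2\sum_j p_j(1 - p_j)$ (VanRaden centered
  cross-product; proportional to the $MM'\sigma^2_\beta$ covariance of
  the marker model). The variance ratio is profiled by restricted
  maximum likelihood on the replicate-weighted adjusted genotype means —
  an eigendecomposition plus a 1-D search, exact for balanced designs —
  and the BLUP step then solves the observation-level mixed-model
  equations exactly through the equivalent marker model $a = M_c\alpha$,
  $\alpha \sim N(0, I\sigma^2_a/c)$, a dense $(f + p)$ system. This
  sidesteps inverting $G$, which is singular whenever $p < n_g$; a
  direct dense MME solve with a jittered $G^{-1}$ cross-checks it in the
  tests at small scale. Dense decompositions limit the oracle to a few
  thousand genotypes — it is a yardstick, not a production path.
* **Two-stage baseline** (`twoStageBaseline`): stage 1 fits genotype as
  fixed and environment as random with *moment* variance estimates
  (between-environment variance of the environment means, average
  within-environment spread), iterating shrunken environment effects and
  genotype means; stage 2 runs the FLM on the stage-1 means with
  per-genotype information weights $S = \mathrm{diag}(Z'V^{-1}Z)$, $V =
  XX'\sigma^2_{env} + I\sigma^2_e$ (closed form per environment block).
  This is a deliberately simplified stand-in for pipelines that carry
  the full first-stage covariance forward; its weights are diagonal by
  construction, and the moment estimates are crude when most genotypes
  are unreplicated. It is labelled accordingly and used only for
  comparison.

# The simulators

`simulatePopulation()` emulates a bi-parental breeding pool: two fully
homozygous, maximally divergent founders (so the F2 segregates at every
marker — founder genotypes are a free choice and this one maximises
information), an F2 of 1000, then five cycles of (sample 250 without
replacement → random union of gametes back to 1000). Selfing is allowed
in the random-mating step (parents drawn independently); with 250
parents its effect is negligible and excluding it would complicate the
draw order. Meiosis has no crossover interference: the package simulates
the exactly equivalent Markov process along each chromosome — start
haplotype Bernoulli(½), phase switch between adjacent markers with
probability $r = \tfrac12(1 - e^{-2d/100})$ for map distance $d$ cM
(Haldane) — which is marginally identical to Poisson crossover counts
with uniform breakpoints and vectorises cleanly. The default genome is
10 chromosomes × 100 cM at 0.5 marker/cM (500 markers at 2 cM spacing).
Five bottleneck cycles generate drift and linkage disequilibrium;
resulting allele frequencies typically span ~0.3–0.7.

`assignQTL()` places causal markers at the chromosome centers (one QTL
per chromosome) or evenly spaced within chromosomes (denser
architectures), with effects alternating $+1, -1, \dots$ starting at
$+1$ and continuing across chromosomes; denser placements are a package
convention, stated here because only the one-per-chromosome case has a
canonical position. QTL markers stay in the marker panel passed to the
predictors by default (prediction from a panel that excludes the causal
loci is a different, harder problem; exclude them by subsetting the
`GenotypeMatrix` if that is the target).

`simulatePhenotype()` adds $N(0, \mathrm{var(tbv)}(1 - h^2)/h^2)$ noise,
so the realised heritability is centred on the target (±0.08 at
$n = 1000$, tested over 20 seeds).

`simulateTrials()` draws, per scenario: the environment count uniformly
from 4–10, environment effects from $N(100, 20^2)$ (trait units),
per-environment heritabilities uniformly from [0.25, 0.75]
(heteroscedastic noise), genotypes with replacement from the pool, and
environment labels uniformly — so environments get unequal entry counts
and, below ~1000 observations, most genotypes are unreplicated. The
noise variance uses the *pool's* tbv variance, not the per-environment
realised sample, keeping the per-environment heritability interpretable.
The draw order (environment count, effects, heritabilities, genotype
assignment, environment assignment, noise) is fixed, so adding draws
never perturbs earlier ones for the same seed. All generators are pure
functions of their seed and restore the caller's RNG state.

**What the simulators do not emulate** — and hence what passing tests do
*not* establish about real data: genotype-by-environment interaction,
dominance and epistasis, spatial field trends, genotyping errors and
missing marker data, multi-allelic loci, and selection during the
breeding cycles (the bottlenecks are random). Effects of equal magnitude
±1 at every QTL are also idealised; real architectures mix effect sizes.

# Problem sizes and runtime choices

The test suite and the acceptance script run at the sizes the package's
own validation is designed around: a 1000-genotype pool with 500
markers; 20 replicate phenotype draws for the QTL-recovery and
architecture comparisons; 5 seeds for the balanced RR-SS/GBLUP
comparison; trial sizes 250 / 1000 / 5000 observations; 200 scenarios
for simulator calibration; 30 × 20 and 200 × 500 instances for the
algebraic equivalences. These sizes put each comparison's Monte Carlo
error well below the effects being asserted while keeping the whole
validation in the minutes range on a single core.

# Known limitations

* Diagonal residual structure only (`RDiag`); autocorrelated residuals
  would need a dense $R$ and different conditioning.
* The single-stage solver is a computational shortcut: it shares its
  fixed point with the plain FLM in the unreplicated reduction, but on
  general unbalanced data it is *comparable to, not identical with*,
  fitting the full $ZM$ model (RR-SS vs the GBLUP oracle: correlation
  > 0.99 on balanced trials, slightly lower when unbalanced).
* GBLUP-oracle REML is performed on weighted genotype means — exact for
  balanced designs, an approximation otherwise.
* The two-stage baseline's moment estimates degrade when replication is
  scarce; it exists for comparison, not as a recommended analysis.
* No missing-data handling anywhere: filter first.
* The marker-effect variances $\sigma^2_{\beta j}$ are full-conditional
  quantities, not posterior variances; they are well suited to ranking
  and regularization, not to credible intervals.
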