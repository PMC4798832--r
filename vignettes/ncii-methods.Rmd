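---
title: "Methods: variance components, heritability and G×E in NC II designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance components, heritability and G×E in NC II designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ncii)
```

This vignette documents the statistical machinery of `ncii`: the models it
fits, the conventions it adopts where several are defensible, the
numerical choices that make the fits deterministic, and what the built-in
simulator does and does not emulate.

## The design and the model

A North Carolina II (NC II) design crosses every sire with every dam, so
that phenotypic variance can be split into a sire component (additive
genetic), a dam component (maternal environmental plus genetic,
inseparable with a single generation), a sire-by-dam interaction
(dominance), and a residual. The default scale throughout is the
motivating whitefish experiment: 4 dams × 12 sires = 48 full-sib
families, embryos raised singly, nine raw treatment groups (an untreated
control, two sodium-citrate dispersant controls, and silver as AgNO3,
20 nm or 100 nm nanoparticles, each at 0.5 or 100 µg/L) pooled into seven
analysis groups before any model is fitted, and five to seven replicates
per family per treatment.

For a Gaussian trait the model is

$$y_{ijk} = \mu + x_{ijk}'\beta + s_i + d_j + (sd)_{ij} + e_{ijk},$$

with independent zero-mean Gaussian random effects of scalar variances
$\sigma^2_s, \sigma^2_d, \sigma^2_{sd}, \sigma^2_e$. Random-effect
covariance is diagonal throughout — including for the group-crossed
interaction terms used in the reaction-norm tests — which is the
variance-component reading of a "random slope–intercept" model; full
slope–intercept covariance matrices are deliberately out of scope.
Treatment is a fixed factor; for the size traits (larval length, log
yolk-sac volume) hatching time enters as an additional fixed covariate,
because hatching earlier mechanically means hatching smaller with a
larger yolk. Yolk volume is log-transformed before analysis. Mortality is
binary and rare and is modelled with a binomial-logit mixed model.

The NC II conversion to genetic parameters is

$$V_A = 4\sigma^2_s,\quad V_{Dam} = \sigma^2_d,\quad V_{NA} = 4\sigma^2_{sd},
\quad V_P = \sigma^2_s + \sigma^2_d + \sigma^2_{sd} + \sigma^2_e,\quad
h^2 = V_A / V_P.$$

Two points deserve emphasis. First, the denominator of $h^2$ is the sum
of the *raw* components, not of the inflated ones. This is the only
reading under which heritabilities near 1 — and occasionally above 1 —
are coherent, and it is the convention `decompose_variance()` implements
and documents. Second, the residual component still contains
$\tfrac12 V_A$ and $\tfrac34 V_{NA}$ in expectation; the decomposition
output carries this caveat as an annotation rather than attempting any
further arithmetic.

## REML engine

`ncii_lmm()` maximizes the restricted (or full) likelihood profiled
analytically over $\beta$ and $\sigma^2_e$, leaving a bounded search over
the log variance ratios $\log\gamma_k = \log(\sigma^2_k/\sigma^2_e)$.
With $V_* = I + \sum_k \gamma_k Z_k Z_k'$, the Woodbury identity reduces
every likelihood evaluation to one Cholesky factorization of the
$m \times m$ matrix $I_m + G^{1/2} Z'Z G^{1/2}$ ($m$ = total number of
random-effect levels, at most a few hundred here), after the
cross-products $X'X, X'y, Z'X, Z'y, Z'Z$ are formed once per fit. This
makes a fit at the design scale take a few milliseconds, which the
simulation-based tests exploit.

Numerical choices:

* **Initialisation** is deterministic at an equal partition of the
  response variance over all components ($\gamma_k = 1$); optional extra
  starts sit at fixed offsets and the best optimum is kept.
* **Optimizer**: bounded quasi-Newton (`nlminb`) on
  $\log\gamma \in [-30, 30]$ with relative tolerance $10^{-10}$; if it
  reports anything other than clean or singular convergence, a
  Nelder–Mead polish and a re-run follow. Everything is deterministic
  given the data.
* **Boundary handling**: after optimization, any ratio whose removal
  (setting $\log\gamma_k = -30$) costs less than $10^{-6}$ in the
  criterion is collapsed onto the boundary, and estimates below
  $10^{-8}\,\mathrm{var}(y)$ are reported as exactly 0 and listed in
  `boundary_terms`. Boundary fits are legitimate results, not errors.
* **Degenerate inputs**: singular fixed designs abort naming the
  collinear columns; grouping factors need at least two levels;
  non-convergence is flagged on the object, never silent.

The balanced-design method-of-moments estimator (`anova_ncii()`), which
equates the sire/dam/interaction/residual mean squares to their
expectations, is kept in the package as an independent closed-form check;
it deliberately reports negative solutions untruncated. The test suite
verifies that REML and this oracle agree to $10^{-4}$ relative whenever
the oracle solution is interior, and that the REML optimum beats a
surrounding parameter grid.

## Testing conventions

Likelihood-ratio tests compare nested fits; `lrt()` derives the degrees
of freedom from the parameter-count difference. Two conventions are
encoded:

* **Estimation flavor per test**: random-effect tests compare REML fits
  sharing the fixed structure; fixed-effect tests (treatment, the
  hatching-time covariate) compare ML fits. REML likelihoods are not
  comparable across different fixed effects, and `lrt()` refuses such
  comparisons. The flavor is recorded in every result.
* **Reference distribution**: the naive $\chi^2$ p-value is primary —
  matching the conventional analysis this package re-implements — and a
  50:50 chi-bar mixture p-value (`p_boundary`) is reported alongside for
  variance components tested on their boundary. The naive test is
  conservative there; the acceptance suite demonstrates a rejection rate
  below 5% across 1000 null simulations.

Pairwise treatment contrasts use the single-step max-|z| family-wise
adjustment: the adjusted p-value of a contrast is
$P(\max_j |Z_j| \ge |z|)$ under the joint normal with the contrasts'
estimated correlation, evaluated by seeded Monte Carlo (default $10^5$
draws; the seed is an explicit argument recorded in the output, and the
Monte Carlo estimate is clamped to be no smaller than the raw p-value).
Pairs are ordered by factor level with the control first. The test suite
cross-checks the adjustment against the closed form under independence
and against the established `multcomp` implementation.

## Bayesian engine

`ncii_gibbs()` is a blocked Gibbs sampler: fixed and random effects are
drawn jointly from their multivariate-normal full conditional (flat prior
on fixed effects), then each variance — residual included — from its
scaled-inverse-gamma full conditional. The prior "(nu, V)" is
parameterized as inverse-gamma with shape $\nu/2$ and scale $\nu V/2$,
the convention of the animal-model MCMC literature; this matters, because
other parameterizations change the prior, so it is stated on the function
and here. The default $\nu = 0.002, V = 1$ is the conventional weak
prior.

Chain defaults are desk-scale — 50,000 iterations, 5,000 burn-in,
thinning 10 — and the pipeline configuration uses 20,000/2,000/10.
Production-scale settings in the millions of iterations are supported
through the same arguments; for this conjugate blocked sampler the
settings affect Monte Carlo error only, and the test suite checks that a
conjugate sub-model reproduces its closed-form posterior
(Kolmogorov–Smirnov distance) and that posteriors on well-replicated
designs cover the REML estimates.

Posterior summaries follow the conventions of the motivating analysis:

* **HPD intervals**: the shortest contiguous window over the sorted draws
  containing $\lceil p\,n \rceil$ draws; width ties break toward the
  lowest lower bound, making the interval deterministic. An exhaustive
  $O(n^2)$ window search serves as the test oracle.
* **Posterior mode**: argmax of a Gaussian kernel density (Silverman
  bandwidth, 512-point grid); constant chains return the constant.
* **DIC**: conditional-deviance convention — deviance is evaluated given
  the location effects and residual variance, $p_D$ is mean deviance
  minus deviance at the posterior means, and a difference of **10 or
  more** (boundary inclusive) is flagged as a meaningful difference in
  fit. Marginal-deviance DIC is out of scope.
* **Heidelberger–Welch**: Cramér–von Mises stationarity test on the
  standardized cumulative-sum process, long-run variance from an AR-fit
  spectral density at zero, discarding initial 10% increments up to 50%;
  halfwidth test at $\epsilon = 0.1$, $\alpha = 0.05$ (the conventional
  defaults). The diagnostic is *reported*, never used to gate results —
  mirroring how such failures are handled in practice (inspected, not
  censored).

## Genotype-by-environment analysis

Reaction-norm tests work on two-group subsets (pooled control versus one
silver treatment): the base model with sire, dam and sire×dam random
effects is compared by REML LRT against the model adding one group-crossed
interaction term (sire×treatment, dam×treatment, sire×dam×treatment), each
an independent scalar-variance intercept deviation per genotype-by-group
cell. A significant sire×treatment term is additive genetic variance for
the reaction norm. The degrees of freedom are derived from parameter
counts and reported per test rather than assumed.

Cross-environment genetic correlations are Pearson correlations of
paternal sibgroup means (per sire × analysis group, over all dams jointly
— the per-dam-then-average alternative is not used), with
pairwise-complete deletion and per-pair counts reported so the effective
n is visible. With 7 groups there are 21 pairs and the Bonferroni
threshold is $0.05/21 \approx 0.00238$, displayed at three decimals
(0.002) while the full-precision value is used internally. Family-mean
correlations are attenuated toward zero by within-family sampling noise —
they are conservative, cannot exceed ±1, and grow toward the generative
sire-effect correlation as offspring per sire per environment increase,
a monotonicity the test suite checks.

## The simulator

`simulate_ncii()` generates data with exactly the structure the analysis
assumes: crossed Gaussian effects per trait, treatment fixed effects on
the analysis groups, sire effects drawn *jointly across environments*
with a correlation matrix $R_G$ (a scalar is expanded exchangeably), so
the strength of G×E is a single dial — $R_G = 1$ means identical sire
effects everywhere (no genetic variance for plasticity), $R_G = 0$ means
independent reaction norms. Dam and sire×dam effects are shared across
environments. Survival is Bernoulli on the logit scale; dead embryos
carry no trait values; size traits are observed only on a random
measurement subset per analysis group. All randomness flows from one
seeded stream, recorded on the output.

Default generative parameters are **synthetic**: the original study
reports no variance-component table in its main text, so the defaults are
chosen once to reproduce its qualitative pattern and are not adjusted
thereafter. Specifically: hatching time at mean 360 degree days (6.5 °C ×
days; the simulator works directly on the degree-day scale, and observed
hatch times exceed the 240.5 DD treatment start) with components
(30, 40, 10, 70) giving $h^2 = 0.8$; earlier hatching under high-dose
silver, strongest for ionic silver (−30 DD) and weaker for nanoparticles
(−10 to −12 DD), with near-null low-dose effects; dam-dominated variance
for length and log yolk volume with small sire components; length
increasing (0.01 mm/DD) and log yolk volume decreasing (−0.002/DD) in
hatching time; $R_G = 0.95$ for hatching time and 0.5 for the size
traits; mortality 0.5% with zero family variance (the observed mortality
was essentially family- and treatment-independent; non-zero variances are
available for power studies); and a measurement fraction of 0.17, which
reproduces roughly 49 measured larvae per raw treatment group. Replicate
counts are drawn independently per family × treatment cell from
{5, 6, 7}, since the original allocation rule is not recoverable; the
pipeline reports achieved totals (about 2,500–2,600 embryos) rather than
targeting the historical 2,896.

Yolk-sac volume uses the prolate-spheroid formula $V = (\pi/6) L W^2$,
the standard salmonid convention; the source analysis cites an external
formula without reproducing it, so the coefficient is configurable and
the spheroid choice is a documented default, not a claim about the
original computation. The simulated volume is split into length and width
through a random aspect ratio so that the recorded dimensions are exactly
consistent with the recorded volume — an invariant the record validator
enforces.

What the simulator does **not** emulate: image-measurement error in the
larval photographs, temporal structure in hatching checks (daily
monitoring), block/plate effects, nanoparticle dissolution chemistry, or
any non-Gaussian trait structure. Passing tests therefore demonstrate
that the estimators recover the parameters of the assumed model at the
design's scale — including its real weaknesses, such as the wide
uncertainty from only four dams — not that the model is adequate for any
particular real data set.

## Pipeline and reproducibility

`run_full_analysis()` executes the stages in a fixed order (validate and
pool controls → mortality → treatment tests and contrasts → 21
per-treatment variance models with decompositions and LRT ladders → Gibbs
summaries → interaction suites → correlations), logging stage names to
standard error and exporting every table as CSV with a metadata file
carrying the seed and a configuration hash. A stage failure aborts with a
stage-named error and leaves partial outputs with an `INCOMPLETE` marker.
Model-selection in the LRT ladder follows the fewer-terms-on-a-tie
policy: both models' results are retained and the tests are reported, so
the preference is a flagged recommendation rather than a silent choice.
Two runs with the same configuration and seed produce identical numbers.

Problem sizes used by the test and acceptance suites — the 4 × 12 × 6
balanced design for estimator checks, 200 replicates for parameter
recovery, 1000 for null calibration, desk-scale chains of 8,000–20,000
iterations — are the package's own choices, sized so that Monte Carlo
error is far below the tolerances being asserted.

## Known limitations

* Dam effects rest on four dams: their variance (and anything involving
  it) is estimated with very wide uncertainty, visibly so in the HPD
  intervals.
* No Satterthwaite/Kenward–Roger corrections; inference on fixed effects
  uses normal-theory z statistics, appropriate at these sample sizes.
* Binary traits beyond the logit mortality model, heteroscedastic
  residuals, epistasis, pedigree/animal models and genomic relationship
  matrices are out of scope.
* The Laplace approximation for the mortality GLMM is known to be rough
  for very sparse binary data; with ~0.5% mortality the fitted variance
  components sit near the boundary and are reported with flags rather
  than confidence statements.
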