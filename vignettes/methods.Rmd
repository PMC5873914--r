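---
title: "Function-valued leaf growth traits: model, mapping and prediction methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function-valued leaf growth traits: model, mapping and prediction methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvtqtl)
```

## The problem this package addresses

Leaf growth is a process, not a single number. `fvtqtl` treats a leaf's
longitudinal size measurements as a *function-valued trait* (FVT): a logistic
growth curve over thermal time whose fitted parameters — growth rate,
final size, and the derived duration and inflection traits — become the
phenotypes for quantitative genetics. The package covers the full chain for a
biparental recombinant inbred line (RIL) population grown across density
treatments and seasons: hierarchical Bayesian curve fitting, shrinkage
genotype means, interval mapping, QTL-by-environment tests, and prediction of
entire growth curves for unseen genotypes from their QTL alleles alone.

## Growth model

Leaf size $L$ follows the logistic growth equation on a degree-day axis $t$:

$$\frac{dL}{dt} = r\,L\left(1 - \frac{L}{L_{max}}\right), \qquad
L(t) = \frac{L_{max}}{1 + A e^{-rt}},\; A = \frac{L_{max}-L_0}{L_0}.$$

This is the only logistic parameterization with an interior inflection
point — growth accelerates until half of final size, then decelerates —
which is what the inflection-time trait presupposes. Under it, $r$ carries
units of 1/degree-day (a relative growth rate), even though rate traits are
often loosely labeled in mm per degree-day; we document rather than hide
this. Two derived traits are closed-form inversions of the curve:

* `iD` $= \log(A)/r$, the inflection time (size $= L_{max}/2$);
* `d` $= \log(19A)/r$, the duration from germination to 95% of final size.

Both scale as $1/r$ at fixed sizes, and `d > iD` whenever the target
fraction exceeds one half. Closed-form inversion (not curve scanning) makes
them exact and fast. Degenerate inputs ($L_0 \ge L_{max}/2$) report an
inflection of 0 with a warning rather than an error, since such curves can
arise transiently inside samplers.

Thermal time uses the simple-average method, $\max(0, (T_{min}+T_{max})/2 -
T_{base})$ per day with the species-specific base temperature 0.96 °C as
default. We chose the simple-average formulation for determinism and
testability; hourly integration schemes are out of scope.

## Hierarchical Bayesian curve fitting

`fit_hierarchical()` fits, for one trait in one treatment × season (the
combinations are modeled independently), a three-level model:

* observations: $y_i \sim N(L(t_i;\, r_p, L_{max,p}, L_{0,p}),\ \sigma^2)$
  for plant $p$;
* plants: $\log\theta_p \sim N(\mu_{g(p)} + \beta\, a_{g(p)},\ \omega^2)$
  componentwise, where $a_g$ is the centered genotypic photosynthetic
  capacity ($A_{max}$) when supplied;
* genotypes: $\mu_g \sim N(\mu_0, \tau^2)$, with weakly-informative
  hyperpriors.

Design choices where the protocol is genuinely open:

* **Log-scale Gaussian hierarchy.** Prior families for the curve parameters
  are not standardized anywhere; sampling $\log r$, $\log L_{max}$, $\log
  L_0$ with Gaussian levels guarantees positivity and makes the genotype and
  global layers conjugate.
* **Hyperpriors scaled to the data.** The global $\log L_{max}$ prior is
  centered on the maximum observed size (SD 2 on the log scale); the
  hierarchy variances get weak inverse-gamma(1, 0.01) priors — heavier
  scale choices measurably inflate the genotype-mean layer whenever the
  true plant-level variance is small, which surfaces directly as
  posterior-predictive overcoverage; the residual variance prior is
  centered at $(0.1\,\mathrm{sd}(y))^2$.
* **$L_0$ is estimated per plant** under the shared hierarchical prior; it
  is not fixed, since nothing in the protocol pins it.
* **$A_{max}$ enters the plant-level prior mean** as a centered linear
  co-factor so the global mean stays interpretable. With one $A_{max}$ value
  per genotype the slope is identified only through partial pooling; its
  posterior is informative mainly when genotype-level spread tracks the
  covariate. The covariate is optional per fit, since it may not be measured
  in every season.
* **Metropolis-within-Gibbs.** Only the plant-level parameters need
  random-walk Metropolis steps (vectorized across plants, joint 3-D
  proposals with per-plant scales); genotype means, global means, variance
  components, the covariate slope and $\sigma$ all have conjugate updates.
  Proposal scales adapt toward ~30% acceptance during burn-in only, so
  detailed balance holds in the retained chain.
* **Single chain by default**; the full
  preset is 500,000 iterations with 440,000 burn-in and 1-in-20 thinning
  (3,000 retained samples). The `"test"` preset (12,000 / 6,000 / 3) is what
  the test suite and the analysis scripts use; parameter-recovery tests show
  <5% bias at that length for the data sizes simulated here.

`credible_envelopes()` produces the two 95% bands used throughout: the
*inner* band is the pointwise credible band of the genotype-mean curve
(logistic curve over genotype-level draws); the *outer* band is the
posterior-predictive band for a single future observation (same draws plus
residual noise). The outer band contains the inner band pointwise by
construction; with finitely many draws the sampled quantiles are clipped to
enforce this. Coverage of the outer band against truth-generated new data is
slightly above nominal at small data sizes because posterior parameter
uncertainty widens the band; the acceptance suite bounds it in [0.92, 0.99].

`convergence_report()` provides lag autocorrelations, an
initial-positive-sequence effective sample size, acceptance summaries, and
degeneracy flags — the numerical equivalent of trace-plot inspection.

## Trait statistics

* **Outliers**: observations more than 3 SD from the mean are dropped in a
  single pass, with mean and SD from the full input. The rule is
  deliberately not iterated (re-running it can remove more points; the tests
  document this).
* **Genotype means**: `estimate_genotype_means()` fits
  `value ~ (1|genotype) + (1|block)` by REML through lme4 and reports the
  grand mean plus conditional modes — shrinkage (BLUP) means. In the
  balanced case the shrinkage factor is
  $\lambda = \sigma^2_g/(\sigma^2_g + \sigma^2_e/m)$, which the tests check
  against engineered data with exact ANOVA variance components.
* **Random-effect tests**: `test_random_effect()` compares REML fits with
  and without one random term, $\chi^2 = 2\Delta\log L$ with 1 df per
  dropped variance component. Testing on the boundary of the parameter
  space makes this conservative; we report the conventional df without a
  mixture correction, and say so here rather than in the output.
  `plasticity_test_table()` applies this across the 7-term crossed/nested
  layout (block within treatment × year; genotype; environments; all
  interactions). Only crossed/nested random intercepts are supported — no
  random slopes.

## QTL mapping

RILs are fully inbred, so the genotype-probability HMM has two states
(homozygote classes); heterozygote codes, if they appear, are treated as
missing. Transitions use the Haldane map function on the cM scale — the map
is interpreted as already expansion-corrected to the RIL scale, which avoids
modeling selfing generations — and the emission model is a symmetric
genotyping error (default 0.001). Probabilities are computed by
forward–backward on the marker-plus-1-cM grid.

`scan_hk()` is Haley–Knott regression: phenotype on expected signed dosage,
$LOD = (n/2)\log_{10}(RSS_0/RSS_1)$. Genome-wide thresholds come from
permutations of the phenotype-to-line assignment (`permutation_threshold()`,
0.95 quantile for mapping, 0.90 for the prediction pipeline). The stepwise
multi-QTL search adds the best conditional peak above threshold, refines
each locus holding the others fixed (up to three sweeps), and stops when no
peak passes; conditioning is by residualization on the model dosages,
keeping everything in the regression approximation. Ties break to the lowest
chromosome then lowest cM, deterministically. Reported per locus: drop-one
LOD, additive effect (half the homozygote class difference), direction
(+1 when the first-parent allele increases the trait), PVE
$= 100(1 - 10^{-2LOD/n})$, and the 1.5-LOD support interval — the outermost
evaluated positions within 1.5 LOD of the peak. QTL for the same trait
whose intervals overlap with the same effect direction collapse to one
reported locus (`collapse_colocalized()`).

The exact stopping/refinement schedule of iterative model search is not
fully specified anywhere; the loop above is one faithful, deterministic
realization and is validated by recovery of injected architectures rather
than by matching a particular implementation.

## QTL-by-environment interactions

`marker_env_anova()` fits the full crossed fixed-effect model of the trait
on one marker's genotype, treatment and year, and reports Type III F tests
for the interaction terms involving the marker. Sum-to-zero contrasts are
enforced internally (Type III tests are coding-dependent; under treatment
contrasts they answer a different question). Markers are tested one at a
time, matching a per-QTL testing protocol, not jointly. Terms with empty
design cells are flagged inestimable and skipped. Either plant-level values
or genotype means may be supplied; the denominator df reveals which was
used, and the analysis scripts use plant-level values.

## Prediction of unseen genotypes

For a held-out genotype, each trait parameter is predicted as the training
population mean plus $\sum_j \text{direction}_j \times \text{effect}_j$ over
the QTL model's loci, with the direction resolved by which allele the
genotype carries. Whole curves then come from the logistic model with the
predicted $r$ and $L_{max}$ and a constant $L_0$ taken as the population
median of fitted $L_0$ values from the training genotypes. Predictions with
non-positive parameters or $L_{max} \le L_0$ are scored as failures, not
clamped — clamping would flatter the success metric.

`leave_k_out_evaluate()` runs the resampling protocol: per round, exclude
$k = 5$ mappable genotypes (parents and lines without marker data are never
candidates), refit the Bayesian model, BLUPs and the QTL model (0.90
threshold) on the remainder, predict the excluded genotypes, and score each
predicted curve against envelopes fitted to the held-out genotypes' own
plants. Scoring is pointwise over the whole curve; a curve is a success
inside the inner band, marginal inside the outer. Because a scalar
parameter has no band of its own, per-parameter verdicts attribute
containment failures by growth phase: failures confined to after the
predicted 95% duration implicate $L_{max}$, failures confined to before the
predicted inflection implicate $r$, anything else counts against both. This
preserves separate success rates for the two parameters while being
operationally unambiguous. The proportion-Z test against chance (0.5) uses
the pooled count of scored genotypes as $n$ — the only $n$ that is
unambiguous under resampling with overlapping rounds — and the raw counts
are reported alongside it. Round membership, refits and verdicts are
fully determined by the seed, and the training log records that no held-out
genotype ever enters model building.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the pipeline targets:
119 RILs plus two parents, fully homozygous two-state genotypes on 10
chromosomes (markers evenly spaced; the Markov walk uses the same Haldane
function as the mapping HMM, i.e. no interference), two density treatments
across seasons with randomized blocks (one replicate per line per block),
5–16 sequential measurements per plant at 2–3 visits per week converted to
degree days from simulated daily temperatures, and Gaussian measurement
noise floored at 0.1 mm (sizes are physical measurements). QTL effects are
purely additive — the class-mean difference is the configured effect — with
genotype-by-year deviations drawn i.i.d. Gaussian per genotype-year, the
simplest structure exhibiting genetic variation in plasticity. Population
curve means (r = 0.012/DD, $L_{max}$ = 40 mm, $L_0$ = 2 mm) give growth
durations of ~500 degree days, a realistic leaf-growth time scale. The
within- vs among-genotype variance split of real field data cannot be
pinned down without the data; the defaults were chosen once for
detectability at n ≈ 119 and are stated here rather than tuned. What the generator does *not* emulate:
segregation distortion, residual heterozygosity, epistasis, non-Gaussian
measurement error, and spatial field structure beyond block intercepts —
so passing tests demonstrate estimator correctness under the assumed model,
not robustness to violations of it.

Spectra are generated on the instrument's native grid (1.4 nm to 1000 nm,
2 nm beyond), averaged over 10 sweeps, and interpolated to one point per nm
over 350–2500 nm (2151 points). Only the red:far-red ratio
(655–665 nm over 725–735 nm, endpoints inclusive — the windows' endpoint
convention is not standardized, so inclusive was fixed once) is built in;
named literature indices are configurable band-math expressions left as
empty placeholders because their formulas live in their original
references.

## Numerical choices and problem sizes

Tolerances: the closed-form logistic is validated against 4th-order ODE
integration to 1e-6 relative error; HMM probabilities against brute-force
enumeration to 1e-12; Haley–Knott LODs against explicit least squares to
1e-10; Type III F statistics against direct RSS comparison to 1e-12.
Monte-Carlo checks state their bands in advance: permutation-threshold
calibration at 400 replicates × 1,000 permutations accepts an exceedance
rate in [0.028, 0.072]; the leave-5-out benchmark (50 lines, three QTL
totaling ~60% of genotypic variance, 12 rounds × 5 experiments) requires a
pooled predicted-vs-observed $L_{max}$ correlation above 0.5 in at least
80% of experiments. The test suite runs every simulation at reduced scale
(tens of lines, short chains) — scales chosen as the smallest at which the
statistical properties under test are still sharp, and stated in each test.

## Known limitations

* Single-trait fits: leaf length and width are modeled independently, with
  no cross-trait covariance.
* The sampler is random-walk based; gradient samplers would mix faster for
  large populations but are out of scope.
* LRT p-values for variance components are conservative at the boundary.
* Conditional scans are residualization-based approximations to joint
  multi-QTL likelihood; exactness is traded for speed, as in the
  regression formulation generally.
* Prediction is additive-only — no epistasis and no QTL×E terms in the
  predictive equations.
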