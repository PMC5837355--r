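---
title: "Methods: two-sample Mendelian randomization of fat distribution on adiponectin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization of fat distribution on adiponectin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depotmr)
```

## The scientific question and the model

Circulating adiponectin falls with obesity, but the fall appears to depend
on *where* fat accumulates: abdominal depots (proxied at population scale
by waist circumference) are associated with lower adiponectin, while the
gluteofemoral depot (proxied by hip circumference) appears protective.
Observational regressions cannot distinguish causation from confounding, so
the package implements two-sample Mendelian randomization (MR): genetic
variants associated with a fat-distribution trait serve as instrumental
variables, their trait associations estimated in one large GWAS sample and
their adiponectin associations in another, non-overlapping sample.

For variant $j$, let $\hat\gamma_j$ (SE $\sigma_{\gamma j}$) be the
variant–exposure association and $\hat\Gamma_j$ (SE $\sigma_{\Gamma j}$)
the variant–outcome association, both per effect-allele copy on
standardized trait scales. Under the instrumental-variable assumptions each
Wald ratio $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ estimates the causal
effect $\beta$ (SD of log adiponectin per SD of the girth trait). The
estimators:

* **IVW** — precision-weighted combination
  $\hat\beta = \sum_j w_j \hat\gamma_j\hat\Gamma_j \big/ \sum_j w_j
  \hat\gamma_j^2$ with $w_j = \sigma_{\Gamma j}^{-2}$, identical to
  weighted least squares of $\hat\Gamma$ on $\hat\gamma$ through the
  origin. The fixed-effect SE is $(\sum_j w_j\hat\gamma_j^2)^{-1/2}$; a
  multiplicative random-effects variant inflates it by
  $\max\{1, \sqrt{Q/(k-1)}\}$.
* **Multivariable IVW** — origin-constrained WLS of $\hat\Gamma$ on both
  exposures' $\hat\gamma$ vectors, giving mutually adjusted effects (waist
  adjusted for hip and vice versa). SEs come from the weighted
  normal-equations covariance $(X^\top W X)^{-1}$.
* **MR-Egger** — the same regression with a free intercept after orienting
  every variant to $\hat\gamma_j > 0$. Under the InSIDE assumption the
  slope remains consistent when instruments are pleiotropic and the
  intercept estimates the average directional pleiotropic effect.
* **(Penalized) weighted median** — the interpolated 50% point of the
  weight-ordered Wald ratios with weights
  $\hat\gamma_j^2/\sigma_{\Gamma j}^2$; consistent while valid instruments
  hold a majority of weight. Penalization multiplies each weight by
  $\min(1, 20\,q_j)$, where $q_j$ is the upper-tail $\chi^2_1$ probability
  of the variant's heterogeneity contribution against the unpenalized
  median.

Diagnostics mirror meta-analysis practice: Cochran's $Q$ over the Wald
ratios with per-variant contributions, $I^2 = \max(0, (Q - df)/Q)$ with a
test-based (log-$H$) confidence interval, funnel plots of ratio against
precision, the Egger intercept as the asymmetry test, and a single-pass
removal of variants with $Q_j$ above the $\chi^2_1$ 95th percentile
(3.84) followed by IVW re-estimation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gwas_p` | 5e-8 | instrument inclusion threshold (strict `<`) |
| `ld_r2` | 0.05 | greedy pruning threshold; kept variants are pairwise below it |
| `palindromic_eaf_window` | 0.08 | palindromic variants are dropped when either EAF is in [0.42, 0.58] |
| `flag_threshold` | `qchisq(0.95, 1)` | per-variant heterogeneity flag |
| `penalty_scale` | 20 | weighted-median penalization constant |
| `n_boot` | 1000 | percentile-bootstrap replicates for Egger/median CIs |
| `variance_model` | `"fixed"` | IVW SE model; `"multiplicative_random"` for heterogeneous sets |

Design choices made where the procedure was genuinely open:

* **Harmonization policy.** Consortium exports rarely document strand.
  We resolve strand flips by complementing alleles before comparison and
  orient palindromic (A/T, G/C) variants by allele-frequency agreement,
  dropping them when either frequency is within 0.08 of 0.5 or missing.
  Frequency-based orientation is unreliable near 0.5, which fixes the
  window's order of magnitude; it is configurable.
* **Pruning.** Greedy, p-value-ranked (clumping-style) pruning with
  lexical tie-breaks, chosen for determinism and permutation invariance
  over pairwise-iterative deletion; the audit log names, for every removed
  variant, the kept variant responsible.
* **Overlap exclusion** between the two exposures' instrument sets matches
  ids exactly; LD-linked cross-trait exclusion would need an external LD
  panel and is out of scope.
* **Egger orientation.** Egger regression is not invariant to allele
  re-labelling; we follow the convention of flipping each variant so the
  exposure beta is positive.
* **P-values** are two-sided normal from `beta/se` for IVW and
  multivariable IVW; for Egger and the medians the bootstrap percentile
  interval is reported alongside a normal approximation consistent with
  the bootstrap SE.
* **Multivariable instrument set.** The union of both exposures'
  instruments is used (configurable), since mutual adjustment needs
  variants informative for either trait.
* **Power.** For standardized traits the IVW z-statistic has
  non-centrality $|\beta|\sqrt{n_{out} R^2}$, where
  $R^2 = \sum_j 2 p_j (1-p_j) \gamma_j^2$ is the variance explained; a
  Monte-Carlo oracle in the test suite guards this approximation.
* **I² interval.** The test-based log-$H$ method; at $Q \le df$ with
  $df = 1$ the interval degenerates to zero width at zero.

## The fractional-polynomial cohort arm

The cohort analysis regresses standardized log adiponectin on each of four
fat depots (visceral, deep subcutaneous, superficial subcutaneous
abdominal; gluteofemoral), by sex, unadjusted and adjusted for lifestyle
covariates, genomic ancestry and the other depots. Nonlinearity is probed
with two-degree fractional polynomials: both powers range over
$\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ with $x^0 \equiv \ln x$ and a repeated
power $(p, p)$ contributing $(x^p, x^p \ln x)$ — 36 models per depot. The
best (minimum-deviance) FP2 model is compared with the linear model by
likelihood-ratio test on 3 degrees of freedom (two power choices plus one
coefficient; the paper-standard convention), Bonferroni-corrected across
the eight depot-by-sex models (0.05/8 = 0.00625). Because the test refers
the best of 36 correlated fits to a fixed $\chi^2_3$ reference it is
conservative in practice — our simulations under a linear truth reject at
roughly 1–3% at the nominal 5% — which we accept rather than recalibrate,
as the original procedure does. Depot values must be positive before
transformation; if not, half the smallest positive value is added.

## What the synthetic-data generator emulates

`simulate_two_sample()` draws, per variant: a minor-allele frequency
$\mathrm{U}(0.05, 0.5)$; a true exposure effect
$\gamma_j \sim N(0, \tau^2)$ (bivariate with correlation $\rho$ for two
exposures); a direct (pleiotropic) outcome effect $\alpha_j$ for a
configurable invalid fraction — zero-centred when balanced, with a
nonzero mean applied on the positive-$\gamma$ orientation when
directional, and optionally correlated with instrument strength to break
InSIDE; the true outcome effect
$\Gamma_j = \beta\gamma_j (+ \beta_2\gamma_{2j}) + \alpha_j$; and
observed betas with independent Gaussian noise at the standardized-trait
standard errors $1/\sqrt{2p(1-p)n}$ in each of the two non-overlapping
samples. Dataset mode additionally assigns alleles (including a
configurable palindromic fraction) and randomly re-orients the outcome
table's representation, so the harmonization stage is exercised end to
end.

The packaged scenarios encode the study conditions:

* `waist_ivw`: $k = 56$, $n_{exp} = 210\,088$, $n_{out} = 29\,347$,
  $\beta = -0.27$; $\tau = 0.0242$ makes the set explain about 1.2% of
  exposure variance. Balanced pleiotropy with SD 0.0155 yields an expected
  per-variant $E[Q_j] = 1 + \mathrm{SD}^2 \cdot E[2p(1-p)]\,n_{out}
  \approx 3.6$, i.e. $I^2 \approx 72\%$.
* `hip_ivw`: $k = 75$, $\beta = +0.17$, $\tau = 0.027$ (about 2.0%
  variance explained), pleiotropy SD 0.0089 ($I^2 \approx 46\%$).
* `joint_mv`: direct effects $-0.45$ and $+0.42$ on the union of 131
  instruments. With correlated instrument effects, each univariable IVW
  converges to $\beta_1 + \beta_2\,\rho\,\tau_2/\tau_1$ (and vice versa);
  solving the pair of equations against univariable values $-0.27$ and
  $+0.17$ gives $\rho = 0.488$ and $\tau_2/\tau_1 = 0.878$. This is the
  omitted-exposure algebra that makes mutual adjustment move the waist
  effect from $-0.27$ to $-0.45$ and the hip effect from $+0.17$ to
  $+0.42$.
* `null_no_pleiotropy`, `directional_pleiotropy`, `adipoq_reverse`: the
  type-I-error, robustness and reverse-direction conditions (four strong
  adiponectin instruments explaining ~4% of variance, no true reverse
  effect).

`simulate_cohort()` draws sex, four correlated depot measures on raw
scales matched to a young-adult birth cohort (e.g. male visceral fat
6.8 ± 1.9 cm, gluteofemoral 3.7 ± 1.6 kg; ~48% male of 2743), lifestyle
covariates, and log adiponectin from within-sex standardized depots with
default adjusted effects (−0.25 visceral, −0.10 deep, −0.20 superficial,
+0.20 gluteofemoral, residual SD 0.93 giving approximately unit outcome
variance). Because the depots are mutually positively correlated while
their effects have opposite signs, the generator reproduces the
qualitative sign flip: the unadjusted gluteofemoral coefficient is
negative, the adjusted one positive. An optional mean-preserving quadratic
term `quad * (z^2 - 1)` produces the U-shaped gluteofemoral dose-response;
`quad = 0.1` at this cohort size corresponds to a likelihood-ratio
non-centrality near 26 for the male stratum, comfortably detectable.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: linkage disequilibrium among instruments
(the LD table is an input, not simulated), allele-frequency spectra with
selection or population structure, non-Gaussian effect-size tails,
winner's-curse in instrument discovery, sample overlap between the two
GWAS, and real measurement error in anthropometry. Estimates on real
consortium files can therefore differ from the synthetic operating
characteristics in ways the suite cannot detect.

## Numerical choices and degenerate inputs

* Instruments drawn $\gamma_j \sim N(0, \tau^2)$ include weak variants;
  the resulting regression dilution of IVW is about
  $\tau^2/(\tau^2 + \bar\sigma_\gamma^2) \approx 2.6\%$ toward the null at
  the waist scenario scale. The acceptance suite compares the mean
  estimate against this analytically implied value rather than silently
  absorbing it into a loose tolerance.
* Bootstrap resampling is variant-level with replacement, percentile
  intervals, seeded; with homogeneous data and 2000 replicates the
  bootstrap CI width agrees with the analytic width to within ~10%.
* The weighted median interpolates cumulative-weight midpoints; at the
  boundaries (median outside the midpoint range) the extreme ratio is
  returned. Zero weights after penalization raise an error only when all
  weights vanish.
* A second exposure whose betas are all zero reduces multivariable IVW to
  the univariable model (with a warning) instead of failing the rank
  check; genuinely collinear exposures raise an error.
* Heterogeneity removal is deliberately single-pass: iterating it on the
  reduced set can flag further variants and turns a diagnostic into an
  outlier hunt, so it is documented but not applied.
* FP2 deviance uses the Gaussian $-2\log L$; transformed bases are
  column-standardized for conditioning (deviances are unaffected).

## Problem sizes used in the checks

Simulation-based checks run at the sizes their claims are stated for:
1000 replicates for IVW recovery and coverage, 2000 for type-I error,
400–500 for robustness orderings and Egger-intercept recovery, 200–300
for the FP size and power runs, with bootstrap replicates reduced to
100–200 inside replicated studies (the full default of 1000 applies to
single analyses).

## Known limitations

* Instrument selection assumes the LD information supplied covers the
  candidate set; unlisted pairs are treated as independent.
* The Egger intercept test uses a normal reference; at small $k$ a
  $t_{k-2}$ reference would be slightly more conservative.
* The penalized weighted median remains biased when invalid variants
  carry close to half the weight *and* per-variant ratios are noisy at
  consortium scale; the robustness guarantees hold for large pleiotropy
  relative to the ratio noise, as the test suite's constructions show.
* Reverse-direction MR with four instruments has limited power; its null
  behaviour, not its power, is what the suite verifies.
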