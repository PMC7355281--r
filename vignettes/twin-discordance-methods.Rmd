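---
title: "Quantitative MZ twin discordance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MZ twin discordance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinconcord)
```

## The scientific question

Monozygotic (MZ) twins share their genome, so the similarity of their trait
scores bounds the familial (genetic plus shared-environment) contribution
to trait variance, and their differences measure non-shared influence.
For a continuously distributed trait like quantitative autistic symptoms
(SRS-2 total T-scores), categorical "concordance" relative to a fixed
clinical cutoff conflates two very different situations: pairs that truly
diverge by tens of T-points, and pairs that merely straddle the line.
`twinconcord` provides the statistics for the quantitative reframing —
concordance rates, a quantitative discordance definition, a correction for
reported discordance, difference/correlation summaries — together with a
synthetic cohort generator and a truncation simulation that separates
*mathematical* attenuation of a correlation (restriction of range above a
cutoff) from *real* loss of twin similarity in the clinical range.

## Data model

The unit of analysis is the pair, stored wide (one row per pair):
per-twin SRS total T-scores (required), optional raw scores, SCI and RRB
subscale T-scores, ADOS social-affect scores, reported-diagnosis flags,
plus sex and age metadata. Validation is total: every CSV row is either
accepted or rejected with a row-indexed diagnostic, and accepted + rejected
equals the row count. Missing optional values stay missing (`NA`, empty
CSV cells) and analyses that need them drop incomplete pairs and report
how many were dropped.

Raw and T scores are linked by a single affine map `T = 0.55·raw + 25`
(configurable). The published SRS-2 norm tables are sex-specific and not
reproduced here; the default slope and intercept were chosen once because
they jointly reconcile the raw-scale difference summaries (means 7.7 and
33.0) with the T-scale summary statistics (means 49T/78T, SDs 7.6T/18.5T)
and twin correlations (.754/.27) of the two sampling regimes the package
models. Pearson correlations are affine-invariant, so nothing downstream
depends on the map beyond the unit labels; both scales are supported
throughout, with the convention that twin *differences* are most naturally
reported on the raw scale and the classification constants (65T cutoff,
18.1 SD) live on the T scale.

## The discordance classifier and the correction

A pair is **quantitatively discordant** iff

1. `|T1 − T2| ≥ k · σ_c` with `k = 1.5` and `σ_c = 18.1` T (the SD of a
   clinically ascertained score distribution), i.e. a gap of at least
   27.15 T-points, **and**
2. the twins fall on opposite sides of the clinical threshold:
   `min < 65 ≤ max`.

A twin exactly at 65T counts as affected (the threshold is conventionally
"a T-score of 65 or above"); the subthreshold band of the straddle
analysis is inclusive at its 50T floor, `lower ∈ [50, 65)`. Pairs that
straddle but miss the magnitude criterion get their own label
(`straddling_subcriterion`); the four labels partition every cohort and
classification is invariant to twin order. Whether the 18.1 constant is a
T- or raw-scale quantity is a genuine ambiguity; it is applied on the
T scale here (it approximates the clinical T-score SD of 18.5) and is
configurable.

The **correction procedure** applies these standards to *reported*
discordance with `k = 1`: a reported-discordant pair is reclassified
concordant if (a) its lower-scoring twin exceeds the cutoff, or (b) its
difference is under one clinical SD. Rule (a) is checked first and the
audit trail records which rule fired for each pair. The correction can
only decrease the discordant count and never changes the pair total.
Rates are reported both pairwise, `C/(C+D)`, and probandwise,
`2C/(2C+D)`. The published registry rates this package reproduces
(0.91, 0.61, 0.82, and 0.91 after correction) all equal the *pairwise*
ratio of the printed counts despite being labelled probandwise, so the
reproduction targets use the pairwise formula; both statistics are always
available, and `probandwise ≥ pairwise` with equality only at `D = 0` or
`C = 0`.

Two-decimal printed comparisons use half-away-from-zero rounding, not
banker's rounding. One straddle-analysis denominator is knowingly left
alone: 13 straddling pairs among 78 is 16.7%, which rounds to 17% rather
than a printed 16%; the package reports the exact fraction.

## The synthetic cohort generator

Each pair's raw scores are

$$t_1 = \mu + d/2, \qquad t_2 = \mu - d/2,$$

with independent Gaussians $\mu \sim N(m_\mu, \sigma_\mu^2)$ (familial
severity shared by the pair) and $d \sim N(0, \sigma_d^2)$ (non-shared
deviation). The model's moments invert in closed form: from a target mean
absolute difference $m = E|d| = \sigma_d\sqrt{2/\pi}$ and twin correlation
$r = (\sigma_\mu^2 - \sigma_d^2/4)/(\sigma_\mu^2 + \sigma_d^2/4)$,

$$\sigma_d = m\sqrt{\pi/2}, \qquad
  \sigma_\mu^2 = \frac{\sigma_d^2}{4}\cdot\frac{1+r}{1-r}.$$

For the epidemiologic targets ($r = .754$, $m = 7.7$) this gives
$\sigma_d = 9.651$, $\sigma_\mu = 12.89$ raw points; for the clinical
targets ($r = .27$, $m = 33.0$) the implied individual T-score SD is
$0.55\sqrt{\sigma_\mu^2 + \sigma_d^2/4} \approx 18.8$, consistent with a
clinical population SD of 18.5.

**Severity-dependent variance regime.** The defining feature of the
clinical regime is that within-pair variance is amplified once severity
crosses the clinical threshold. The generator keys a hard variance step on
the *latent* pair mean $\mu$ (on the T scale), not on observed scores —
keying on observations would build the classifier's input into its own
test. Below the threshold the difference SD is $\sigma_0$, at or above it
$\sigma_1 = \gamma\sigma_0$. The epidemiologic preset uses
$\gamma = 33.0/7.7 \approx 4.29$ — above-threshold pairs enter the
clinical difference regime, since $\sigma_d$ is proportional to $E|d|$ —
while the clinical presets use $\gamma = 1$: essentially their whole
distribution lies above the cutoff, a single (already amplified) regime,
which also reproduces the observed near-zero severity-vs-difference
association in clinical samples. When $\gamma > 1$ the calibration solves
a short fixed point in the above-threshold mass $p$ so the *mixture* still
reproduces both targets exactly:
$E|d| = \sqrt{2/\pi}\,\sigma_0\,((1-p) + p\gamma)$ and the correlation
formula holds with $E[\sigma_d^2] = \sigma_0^2((1-p) + p\gamma^2)$.

**What the presets emulate.** Three cohorts: epidemiologic (288 pairs,
mean 49T, r = .754, mean raw difference 7.7, 105/288 male–male pairs,
ages 4–15), and clinical IAN (23 pairs) and AGRE (55 pairs) with combined
statistics mean 78T, r = 0.27, mean raw difference 33.0, 62/78 male–male,
ages 4–18. Subscale T-scores (SCI, RRB) are generated with squared twin
correlations 57%/48% (epidemiologic) and 6%/20% (clinical), their
pair-level component loading 0.7 on the total-severity factor (subscales
are strongly intercorrelated with the total; the exact loading only
shapes cross-scale correlations, not the calibrated twin correlations).
AGRE pairs carry ADOS social-affect scores on a 0–20 integer scale
(location 12, scale 4 — realistic values; the source scale bounds are not
published) as an affine function of each twin's T-score plus independent
instrument noise sized so the ADOS twin correlation is 0.21. Sex and age
are metadata only, with no effect on scores — the emulated samples showed
no sex or age effects — so age-association analyses on synthetic cohorts
are null by construction. Clinical presets also emit reported-diagnosis
flags as threshold exceedance, a deliberately crude stand-in for community
diagnosis that makes the correction procedure exercisable end to end.

**Clamping.** T-scores are clamped to the valid range `[30, 130]` and raw
scores recomputed from the clamped T, so the two scales satisfy the affine
map exactly for every emitted pair; the clamp count is recorded on the
cohort. Clamping (rather than redrawing) slightly shrinks extreme
moments — about 0.1 raw points of the clinical mean difference — which is
well inside the Monte-Carlo tolerances used anywhere the calibration is
checked. One deterministic object sits outside the stochastic generator:
a hard-coded 23-pair fixture whose 9 reported-discordant pairs decompose
exactly into 3 reclassified by rule (a), 4 by rule (b), and 2 genuinely
discordant, giving the corrected rate 21/23 = 0.91.

## The truncation simulation and its oracle

To ask how much of a weak above-threshold twin correlation is explained by
restriction of range alone, the package resamples pairs from a score pool
under a **Gaussian copula**: draw latent bivariate-normal pairs with
correlation $\rho_{latent}$ and push each margin through the pool's
empirical quantile function. This preserves the pool's marginal exactly —
the semantics of sampling the pool with replacement — while the latent
correlation induces the pairing. $\rho_{latent}$ is calibrated by
monotone bisection (common random numbers, tolerance 0.005 on the realized
Pearson correlation of a dedicated 10^5-pair calibration draw, at most 60
halvings) so that the realized full-sample correlation sits within ±0.01
of the target, e.g. the all-groups twin correlation 0.77. The calibration
draw is separate from, and larger than, the reporting draw of 10,000 pairs
so calibration noise does not leak into results. The supplementary details
of how the original resampling induced its correlation constraint are not
available; the copula is this package's canonical interpretation because
it is the unique construction that keeps with-replacement marginals while
hitting the constraint, and it is what the calibration contract tests pin
down.

The default pool (`synthetic_score_pool()`) is 6,000 SRS-like T-scores:
gamma-distributed raw scores whose mean and SD map to 50T/10T, giving the
right-skewed population marginal with a long clinical tail. The original
6,000-score population sample and registry twin data are not publicly
deposited, so the printed expected/observed values (0.15 vs 0.01) are not
numerically reproducible at the desk; the package instead verifies the
machinery against an analytic oracle and reproduces the *contrast*
property — the expected above-threshold correlation exceeds the observed
one in clinical-regime cohorts by a wide margin.

**The analytic oracle.** `bvn_truncated_corr(rho, h, mode)` computes the
correlation of a standard bivariate normal restricted to
$\{X \ge h, Y \ge h\}$ (`both_above`) or $\{X \ge h\}$ (`one_above`) by
iterated quadrature: the outer integral over $x \ge h$ uses
`stats::integrate` (rel. tol 10^-10), the inner conditional moments of the
truncated normal $Y \mid X$ are closed-form in the Mills ratio, evaluated
on the log scale so the far tail is stable. Truncation at both ends of
the grid behaves as theory demands: independence is preserved
($\rho = 0$ maps to 0), $h \to -\infty$ recovers $\rho$, attenuation is
monotone toward 0 in $h$, and $\rho = 0.999$ stays near 1. The
implementation was checked cell by cell against a frozen independent
Monte-Carlo oracle (10^7 rejection draws per $(\rho, h)$ cell) and, for
single truncation, against the classical selection formula
$\rho\sqrt{v}/\sqrt{\rho^2 v + 1 - \rho^2}$ with
$v = 1 + h\lambda(h) - \lambda(h)^2$. For intuition: at $\rho = 0.77$ and
a +1.5 SD cutoff, double truncation alone attenuates the correlation to
about 0.37 — so an observed above-cutoff correlation near zero is far
below mathematical expectation, not an artifact of it. A published table
of expected correlations under less stringent thresholds (0.50–0.62 for
cutoffs spanning the upper 70% to upper 30%) is directionally ambiguous
about single vs double truncation; both modes are provided rather than
forcing agreement.

## Numerical choices and degenerate inputs

* Boundary rules: threshold inclusive for the upper twin (`65 ≤ max`),
  exclusive for the lower (`min < 65`); straddle floor inclusive at 50T;
  the magnitude criterion uses `≥` (meeting the bar meets the criterion).
* Rates, correlations and r² are carried at full precision; rounding
  (half away from zero) happens only at report time. `familiality_variance`
  discards the sign of r.
* Degenerate inputs fail loudly with specific errors: zero-variance
  correlation inputs, fewer than 3 survivor pairs after truncation, fewer
  than 2/3/5 complete pairs for the respective summaries, constant ages,
  pools that cannot reach the target correlation (bisection reports the
  attainable maximum).
* Spearman statistics use the large-sample approximation
  (`exact = FALSE`), and the double-entry ICC reports no p-value (its
  doubled rows are not independent observations).
* All randomness flows through explicit integer seeds; a cohort, pipeline
  report, or pair matrix regenerated with the same seed is bit-identical.

## Problem sizes used in the tests

Calibration-recovery checks run at 10,000 pairs with 3-standard-error
tolerances; oracle-equivalence simulations at 10^5 pairs per grid cell;
the severity-association sign property at 200 replicate cohorts of 5,000
pairs; the expected-vs-observed gap property at 100 replicates of
800-pair clinical cohorts with a 5-fold variance regime against a 10,000-
pair simulation. These sizes were chosen from power analysis so that each
property is resolvable with honest margins at conventional Monte-Carlo
tolerances.

## Known limitations

* The hard variance step at the clinical threshold is the simplest regime
  model consistent with "differences become pronounced near the
  threshold"; no functional form for the transition is published. A
  consequence: in an epidemiologic cohort centred at 49T only ~1.5% of
  pairs lie above 65T, so at n = 288 the severity-vs-difference Spearman
  association is far weaker than the ~0.33 observed in real epidemiologic
  data — the real effect plausibly begins *near*, not at, the threshold.
  The package asserts only the association's sign, at sample sizes where
  it is resolvable.
* A printed 5% ADOS familiality figure is inconsistent with its own
  correlation (0.21² = 4.4%); the package reports exact r² and does not
  reproduce the discrepancy.
* The generator emulates summary moments and the regime structure, not
  item-level response processes, rater effects, or longitudinal
  trajectories; passing recovery tests shows the statistics are computed
  correctly, not that real registry data look Gaussian.
* Reported-diagnosis flags in synthetic clinical cohorts are threshold
  exceedance, so synthetic "reported" discordance is exactly straddling —
  adequate for exercising the correction machinery, but real community
  diagnosis is noisier; the deterministic fixture exists precisely to pin
  the correction arithmetic to known counts.
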