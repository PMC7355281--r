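# twinconcord

Quantitative concordance and discordance analysis for monozygotic (MZ) twin
pairs measured on continuous trait scales.

## The problem

Twin concordance for categorical diagnoses is the foundational statistic of
psychiatric genetics, but when the underlying trait is continuously
distributed — as autistic traits measured by the Social Responsiveness Scale
(SRS-2) are — a fixed diagnostic cutoff makes "discordance" an artifact of
where twins happen to fall relative to an arbitrary line. Two twins scoring
64T and 66T are categorically discordant yet quantitatively almost
identical; two twins at 70T and 120T are categorically concordant yet
dramatically different. `twinconcord` implements the quantitative reframing
of MZ concordance for researchers in behavior genetics and autism
epidemiology:

* **Concordance statistics.** Pairwise `C/(C+D)` and probandwise
  `2C/(2C+D)` rates from counts, at full precision and 2-decimal rounding.
* **A quantitative discordance classifier.** A pair is discordant iff
  `|T1 − T2| ≥ k·σ_c` (default `k = 1.5`, `σ_c = 18.1` T — the clinical
  population SD) **and** the twins fall on opposite sides of the clinical
  threshold (65T). Everything else is concordant-affected,
  concordant-unaffected, or "straddling" the threshold sub-criterion.
* **A correction for reported discordance.** Parent-reported discordant
  pairs are reclassified concordant when the lower-scoring twin actually
  exceeds the clinical cutoff, or when the twin–twin difference is under
  one clinical SD; every reclassification is audited.
* **Twin-difference and correlation analyses.** Mean/SD of `|T1 − T2|`,
  Pearson/Spearman/double-entry-ICC twin correlations, familiality as
  `100·r²`%, severity-vs-difference and age-vs-difference associations.
* **A calibrated synthetic cohort generator.** Each pair is
  `t_i = μ ± d/2` with Gaussian `μ` (familial severity) and `d` (non-shared
  deviation); closed-form calibration `σ_d = m√(π/2)`,
  `σ_μ² = (σ_d²/4)(1+r)/(1−r)` hits any target twin correlation `r` and
  mean absolute difference `m`, with an optional amplified
  difference-variance regime above the clinical threshold.
* **A truncation simulation with an analytic oracle.** Pairs resampled from
  a score pool through a Gaussian copula (preserving the pool's marginal
  exactly, latent correlation bisection-calibrated to a target such as
  0.77), truncated at a cutoff, and compared against
  `bvn_truncated_corr(ρ, h)` — a deterministic quadrature for the
  correlation of a bivariate normal restricted to `{X ≥ h, Y ≥ h}` — to
  quantify how much restriction of range alone should attenuate a twin
  correlation.

## Worked example

```r
library(twinconcord)
cfg <- analysis_config()   # 65T threshold, 18.1 SD, k = 1.5, T = 0.55*raw + 25

epi <- generate_preset_cohort("epidemiologic", seed = 20191218)      # 288 pairs
cl  <- generate_preset_cohort("clinical_combined", seed = 20191219)  #  78 pairs

difference_summary(epi, "raw")
#> <difference_summary> |d| on the raw scale, 288 pairs (0 dropped)
#>   mean 7.72 (SD 6.87)
twin_correlation(epi, "SRS_total")
#> <correlation_result> SRS_total (pearson, 288 pairs): r = 0.753 (57% of variance), p = 6.11e-54
twin_correlation(cl, "SRS_total")
#> <correlation_result> SRS_total (pearson, 78 pairs): r = 0.224 (5% of variance), p = 0.0487
```

The epidemiologic regime shows tightly similar twins (mean raw difference
7.7, familiality 57%); the clinical regime shows four-fold larger
differences and a collapsed correlation. Classifying the clinical cohort
and correcting a reported-discordance fixture:

```r
cohort_concordance(cl)
#> <concordance_result> 78 pairs: 61 concordant, 17 discordant
#>   pairwise   : 0.7821 (0.78)
#>   probandwise: 0.8777 (0.88)

fix <- make_reclassification_fixture()   # 23 pairs, 9 reported discordant
correct_reported_concordance(fix)
#> <concordance_result> 23 pairs: 21 concordant, 2 discordant
#>   pairwise   : 0.9130 (0.91)
#>   probandwise: 0.9545 (0.95)
#>   7 pair(s) reclassified concordant:
#>     IAN-15  [lower_twin_above_cutoff]
#>     ...
#>     IAN-21  [difference_below_sd]
```

Three of the nine reported-discordant pairs have their "unaffected" twin
above the clinical cutoff and four differ by less than one clinical SD;
after correction the rate is 0.91. Finally, the truncation experiment:

```r
pool <- synthetic_score_pool(seed = 20191218)   # 6000 SRS-like T-scores
expected_vs_observed(pool, target_r = 0.77, threshold = 65,
                     observed_cohort = cl, n = 10000, seed = 20191218)
#> <truncation_sim_result> 10000 pairs, latent rho 0.7812, r_full 0.774
#>   truncated at 65: 429 survivors, expected r = 0.365
#>   observed r above threshold: 0.021 (38 pairs)

bvn_truncated_corr(0.77, 1.5)   # analytic check at a +1.5 SD cutoff
#> [1] 0.3682778
```

Restriction of range above 65T should attenuate a 0.77 correlation to
roughly 0.37 — but the observed above-threshold twins correlate at only
0.02, far below the mathematical expectation. That gap, not the truncation
itself, is the signature of amplified non-shared influence in the clinical
range.

A full pipeline over several cohorts, with a JSON report and figures, is
`run_pipeline()`; a thin command-line front end lives at
`inst/cli/twinconcord.R`.

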