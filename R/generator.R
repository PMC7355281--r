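#' Cohort presets
#'
#' Canned generator targets for the three sampling regimes the package
#' models: an epidemiologically ascertained cohort (288 pairs, mean 49T,
#' twin r = .754, mean raw twin difference 7.7) and two clinically
#' ascertained cohorts, IAN (23 pairs) and AGRE (55 pairs), whose combined
#' statistics are mean 78T, twin r = 0.27 and mean raw difference 33.0;
#' AGRE additionally carries ADOS social-affect scores with twin r = 0.21.
#'
#' The epidemiologic preset amplifies the within-pair difference SD above
#' the clinical threshold by the clinical-to-epidemiologic difference ratio
#' (33.0 / 7.7), so pairs whose latent severity exceeds the cutoff show the
#' clinical discordance-variance regime. The clinical presets sit almost
#' entirely above the cutoff and use a single regime.
#'
#' @param name Preset name.
#' @return A list of class `cohort_preset` with fields `n_pairs`, `target_r`,
#'   `target_mean_absdiff` (raw points), `mean_t`, `regime_ratio`,
#'   `subscale_r2` (named vector, squared twin correlations for SCI/RRB),
#'   `ados_r`, `prop_mm` (male-male pair fraction) and `age_range`.
#' @export
cohort_preset <- function(name = c("epidemiologic", "IAN", "AGRE",
                                   "clinical_combined")) {
  name <- match.arg(name)
  p <- switch(name,
    epidemiologic = list(
      n_pairs = 288L, target_r = 0.754, target_mean_absdiff = 7.7,
      mean_t = 49, regime_ratio = 33.0 / 7.7,
      subscale_r2 = c(SCI = 0.57, RRB = 0.48),
      ados_r = NA_real_, prop_mm = 105 / 288, age_range = c(4, 15)
    ),
    IAN = list(
      n_pairs = 23L, target_r = 0.27, target_mean_absdiff = 33.0,
      mean_t = 78, regime_ratio = 1,
      subscale_r2 = c(SCI = 0.06, RRB = 0.20),
      ados_r = NA_real_, prop_mm = 62 / 78, age_range = c(4, 18)
    ),
    AGRE = list(
      n_pairs = 55L, target_r = 0.27, target_mean_absdiff = 33.0,
      mean_t = 78, regime_ratio = 1,
      subscale_r2 = c(SCI = 0.06, RRB = 0.20),
      ados_r = 0.21, prop_mm = 62 / 78, age_range = c(4, 18)
    ),
    clinical_combined = list(
      n_pairs = 78L, target_r = 0.27, target_mean_absdiff = 33.0,
      mean_t = 78, regime_ratio = 1,
      subscale_r2 = c(SCI = 0.06, RRB = 0.20),
      ados_r = 0.21, prop_mm = 62 / 78, age_range = c(4, 18)
    )
  )
  structure(c(list(name = name), p), class = "cohort_preset")
}

#' Calibrate the pair-mean / difference generator
#'
#' The generator models each pair's raw scores as `t1 = mu + d/2`,
#' `t2 = mu - d/2` with independent Gaussians: `mu` is the shared
#' ("familial") severity component and `d` the within-pair (non-shared)
#' deviation. Inverting the model's moments gives the closed-form
#' calibration
#' \deqn{\sigma_d = m \sqrt{\pi/2}, \qquad
#'       \sigma_\mu^2 = \frac{\sigma_d^2}{4}\,\frac{1+r}{1-r},}
#' where `m` is the target mean absolute difference `E|d|` and `r` the
#' target twin correlation, since `E|d| = sigma_d * sqrt(2/pi)` and
#' `cor(t1, t2) = (sigma_mu^2 - sigma_d^2/4) / (sigma_mu^2 + sigma_d^2/4)`.
#'
#' With `regime_ratio > 1` the within-pair SD is `sigma_0` below the
#' clinical threshold (on the latent pair-mean T scale) and
#' `sigma_1 = ratio * sigma_0` at or above it. Calibration then solves a
#' short fixed point so that the *mixture* still reproduces both targets
#' exactly: `E|d| = sqrt(2/pi) * sigma_0 * ((1-p) + p*ratio)` and the
#' correlation formula holds with the mixture variance
#' `sigma_0^2 ((1-p) + p*ratio^2)`, `p` being the above-threshold mass of
#' the latent pair mean.
#'
#' @param target_r Target twin Pearson correlation in `[0, 1)`.
#' @param target_mean_absdiff Target mean absolute raw-score difference (> 0).
#' @param config Analysis configuration (supplies threshold and raw/T map).
#' @param regime_ratio `sigma_1 / sigma_0 >= 1`.
#' @param mean_t Mean T-score of the cohort (locates the latent mean
#'   relative to the threshold; only consequential when `regime_ratio > 1`).
#' @return A list of class `generator_params`: `mean_severity` and
#'   `sd_severity` (raw scale), `sd_diff_below`, `sd_diff_above`,
#'   `target_r`, `target_mean_absdiff`, `prob_above`.
#' @examples
#' p <- calibrate_generator(0.754, 7.7)
#' c(p$sd_diff_below, p$sd_severity)  # 9.651, 12.89 raw points
#' @export
calibrate_generator <- function(target_r, target_mean_absdiff,
                                config = analysis_config(),
                                regime_ratio = 1, mean_t = 50) {
  if (target_r >= 1) {
    stop("target_r = 1 is degenerate (zero within-pair variance)", call. = FALSE)
  }
  if (target_r < 0) {
    stop("negative MZ twin correlations are not supported", call. = FALSE)
  }
  if (target_mean_absdiff <= 0) {
    stop("`target_mean_absdiff` must be > 0", call. = FALSE)
  }
  if (regime_ratio < 1) stop("`regime_ratio` must be >= 1", call. = FALSE)
  m <- target_mean_absdiff
  g <- regime_ratio
  p <- 0
  for (iter in 1:200) {
    s0 <- m * sqrt(pi / 2) / ((1 - p) + p * g)
    sd2_eff <- s0^2 * ((1 - p) + p * g^2)
    sd_mu <- sqrt((sd2_eff / 4) * (1 + target_r) / (1 - target_r))
    if (g == 1) break
    mu_t_sd <- config$raw_to_t_slope * sd_mu
    p_new <- stats::pnorm(config$clinical_threshold, mean = mean_t,
                          sd = mu_t_sd, lower.tail = FALSE)
    if (abs(p_new - p) < 1e-12) { p <- p_new; break }
    p <- p_new
  }
  s0 <- m * sqrt(pi / 2) / ((1 - p) + p * g)
  sd_mu <- sqrt((s0^2 * ((1 - p) + p * g^2) / 4) * (1 + target_r) / (1 - target_r))
  structure(
    list(
      mean_severity = t_to_raw(mean_t, config),
      sd_severity = sd_mu,
      sd_diff_below = s0,
      sd_diff_above = g * s0,
      target_r = target_r,
      target_mean_absdiff = m,
      prob_above = p
    ),
    class = "generator_params"
  )
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params> (raw-score scale)\n")
  cat(sprintf("  pair mean   : mu ~ N(%.2f, %.3f^2)\n", x$mean_severity, x$sd_severity))
  cat(sprintf("  difference  : sd %.3f below / %.3f above threshold (P[above] = %.3g)\n",
              x$sd_diff_below, x$sd_diff_above, x$prob_above))
  cat(sprintf("  targets     : r = %.3f, E|d| = %.2f\n",
              x$target_r, x$target_mean_absdiff))
  invisible(x)
}

#' Generate a synthetic MZ twin cohort
#'
#' Draws `n_pairs` pairs from the calibrated pair-mean / difference model.
#' For each pair the latent mean `mu` is drawn first; the within-pair
#' difference SD is `sd_diff_below` or `sd_diff_above` according to whether
#' `mu` (on the T scale) falls below or at/above the clinical threshold —
#' keying the regime on the latent mean rather than the observed scores
#' avoids circularity when the generated cohort is later classified. Raw
#' scores are mapped to T-scores, T-scores are clamped to the valid range
#' (with the clamp count recorded) and raw scores recomputed from the
#' clamped T so the two scales always satisfy the affine map exactly.
#'
#' Optional measures: SCI/RRB subscale T-scores with squared twin
#' correlations matching `subscale_r2`, and integer ADOS social-affect
#' scores (0-20) as an affine function of each twin's T-score plus
#' independent instrument noise calibrated to `ados_r`. Sex and age are
#' generated as metadata only and have no effect on scores.
#'
#' @param params A [calibrate_generator()] result.
#' @param n_pairs Number of pairs (>= 2).
#' @param config Analysis configuration.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param label Cohort label.
#' @param subscale_r2 Named vector `c(SCI = , RRB = )` of squared twin
#'   correlations, or `NULL` to omit subscales.
#' @param ados_r Target ADOS twin correlation (must not exceed `target_r`),
#'   or `NA` to omit ADOS.
#' @param subscale_sd_t Subscale T-score SD (defaults to the model-implied
#'   total-score T SD).
#' @param ados_mean,ados_sd Location/scale of the ADOS mapping before
#'   rounding and clamping to 0-20.
#' @param prop_mm Fraction of male-male pairs.
#' @param age_range Age range (years), sampled uniformly.
#' @param emit_dx If `TRUE`, reported-diagnosis flags are emitted as
#'   threshold exceedance of each twin's T-score (a stand-in for community
#'   diagnosis, useful for exercising the correction procedure).
#' @return A `twin_cohort` with attributes `params`, `seed`, `n_clamped`.
#' @export
generate_cohort <- function(params, n_pairs, config = analysis_config(),
                            seed = config$seed, label = "synthetic",
                            subscale_r2 = NULL, ados_r = NA_real_,
                            subscale_sd_t = NULL,
                            ados_mean = 12, ados_sd = 4,
                            prop_mm = 0.5, age_range = c(4, 18),
                            emit_dx = FALSE) {
  stopifnot(inherits(params, "generator_params"))
  if (n_pairs < 2) stop("`n_pairs` must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))

  mu <- stats::rnorm(n_pairs, params$mean_severity, params$sd_severity)
  mu_t <- config$raw_to_t_slope * mu + config$raw_to_t_intercept
  sd_d <- ifelse(mu_t >= config$clinical_threshold,
                 params$sd_diff_above, params$sd_diff_below)
  d <- stats::rnorm(n_pairs, 0, sd_d)
  raw1 <- mu + d / 2
  raw2 <- mu - d / 2
  t1 <- config$raw_to_t_slope * raw1 + config$raw_to_t_intercept
  t2 <- config$raw_to_t_slope * raw2 + config$raw_to_t_intercept
  clamp_t <- function(x) pmin(pmax(x, config$t_range[1]), config$t_range[2])
  n_clamped <- sum(t1 != clamp_t(t1)) + sum(t2 != clamp_t(t2))
  t1 <- clamp_t(t1); t2 <- clamp_t(t2)
  raw1 <- t_to_raw(t1, config); raw2 <- t_to_raw(t2, config)

  pairs <- tibble(
    pair_id = sprintf("%s-%04d", label, seq_len(n_pairs)),
    cohort = label,
    sex = ifelse(stats::runif(n_pairs) < prop_mm, "MM", "FF"),
    age = round(stats::runif(n_pairs, age_range[1], age_range[2]), 1),
    score_t1 = t1, score_t2 = t2, raw_t1 = raw1, raw_t2 = raw2
  )

  # model-implied individual T-score SD, used as the default subscale SD
  # and as the latent scale of the ADOS mapping
  var_ind <- params$sd_severity^2 +
    ((1 - params$prob_above) * params$sd_diff_below^2 +
       params$prob_above * params$sd_diff_above^2) / 4
  sd_t_total <- config$raw_to_t_slope * sqrt(var_ind)
  mean_t <- config$raw_to_t_slope * params$mean_severity + config$raw_to_t_intercept

  if (!is.null(subscale_r2)) {
    if (is.null(subscale_sd_t)) subscale_sd_t <- sd_t_total
    z_mu <- (mu - params$mean_severity) / params$sd_severity
    loading <- 0.7  # subscale pair-mean loading on the total-severity factor
    for (sub in c("SCI", "RRB")) {
      r_s <- sqrt(subscale_r2[[sub]])
      # t = m +/- d/2 gives corr = (var_m - var_d/4) / (var_m + var_d/4),
      # so split the subscale variance V as var_m = (1+r)/2 V, var_d/4 = (1-r)/2 V
      sd_ms <- sqrt((1 + r_s) / 2) * subscale_sd_t
      sd_ds <- 2 * sqrt((1 - r_s) / 2) * subscale_sd_t
      m_s <- mean_t + sd_ms * (loading * z_mu +
                                 sqrt(1 - loading^2) * stats::rnorm(n_pairs))
      d_s <- stats::rnorm(n_pairs, 0, sd_ds)
      col <- if (sub == "SCI") c("sci_t1", "sci_t2") else c("rrb_t1", "rrb_t2")
      pairs[[col[1]]] <- clamp_t(m_s + d_s / 2)
      pairs[[col[2]]] <- clamp_t(m_s - d_s / 2)
    }
  }

  if (!is.na(ados_r)) {
    if (ados_r > params$target_r) {
      stop("`ados_r` cannot exceed the SRS twin correlation `target_r`",
           call. = FALSE)
    }
    b <- ados_sd / sd_t_total
    a <- ados_mean - b * mean_t
    noise_sd <- b * sd_t_total * sqrt(params$target_r / ados_r - 1)
    ados <- function(tv) {
      pmin(pmax(round(a + b * tv + stats::rnorm(n_pairs, 0, noise_sd)), 0), 20)
    }
    pairs$ados_t1 <- ados(t1)
    pairs$ados_t2 <- ados(t2)
  }

  if (emit_dx) {
    pairs$dx_t1 <- ifelse(t1 >= config$clinical_threshold, "yes", "no")
    pairs$dx_t2 <- ifelse(t2 >= config$clinical_threshold, "yes", "no")
  }

  out <- twin_cohort(pairs, label = label, provenance = "synthetic",
                     seed = as.integer(seed), config = config, validate = FALSE)
  attr(out, "params") <- params
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Generate a cohort from a named preset
#'
#' Convenience wrapper: calibrates the generator to the preset's targets and
#' generates the cohort with the preset's sample size, regime ratio,
#' subscale and ADOS structure. Clinical presets emit reported-diagnosis
#' flags; the epidemiologic preset does not.
#'
#' @param preset A preset name or [cohort_preset()] object.
#' @param config Analysis configuration.
#' @param seed Integer seed.
#' @param n_pairs Override the preset's sample size (e.g. for
#'   reduced-variance recovery checks at large n).
#' @return A `twin_cohort`.
#' @examples
#' epi <- generate_preset_cohort("epidemiologic", seed = 1)
#' mean(abs(epi$raw_t1 - epi$raw_t2))  # close to 7.7
#' @export
generate_preset_cohort <- function(preset, config = analysis_config(),
                                   seed = config$seed, n_pairs = NULL) {
  if (is.character(preset)) preset <- cohort_preset(preset)
  stopifnot(inherits(preset, "cohort_preset"))
  params <- calibrate_generator(preset$target_r, preset$target_mean_absdiff,
                                config = config,
                                regime_ratio = preset$regime_ratio,
                                mean_t = preset$mean_t)
  generate_cohort(params, n_pairs %||% preset$n_pairs, config = config,
                  seed = seed, label = preset$name,
                  subscale_r2 = preset$subscale_r2, ados_r = preset$ados_r,
                  prop_mm = preset$prop_mm, age_range = preset$age_range,
                  emit_dx = preset$name != "epidemiologic")
}

#' Deterministic reclassification fixture
#'
#' A hard-coded, seed-independent 23-pair clinically ascertained cohort for
#' exercising the reported-discordance correction: 14 pairs are reported
#' concordant (both twins diagnosed, both at or above the cutoff) and 9
#' reported discordant, of which exactly 3 have the lower-scoring twin
#' *above* the 65T cutoff (correction rule a), exactly 4 have a twin-twin
#' difference below 18.1 T with the lower twin below the cutoff (rule b),
#' and 2 satisfy both quantitative discordance conditions and therefore
#' remain discordant after correction (corrected pairwise rate 21/23 = 0.91).
#'
#' @param config Analysis configuration (used for the raw-score columns).
#' @return A 23-pair `twin_cohort` labelled `"IAN"`.
#' @export
make_reclassification_fixture <- function(config = analysis_config()) {
  conc <- matrix(c(
    78, 85,   90, 96,   70, 77,   88, 103,  66, 71,   95, 120,  72, 80,
    81, 92,   69, 75,  100, 118,  74, 86,   83, 91,   67, 73,  110, 125
  ), ncol = 2, byrow = TRUE)
  # reported discordant: 3 x rule (a), 4 x rule (b), 2 x truly discordant
  disc <- matrix(c(
    66, 95,   70, 100,  68, 88,          # lower twin above the cutoff
    55, 70,   60, 72,   58, 66,  52, 68, # difference under 18.1 T
    45, 90,   40, 85                     # >= 1.5 SD apart and straddling
  ), ncol = 2, byrow = TRUE)
  scores <- rbind(conc, disc)
  n <- nrow(scores)
  dx2 <- c(rep("yes", nrow(conc)), rep("yes", nrow(disc)))
  dx1 <- c(rep("yes", nrow(conc)), rep("no", nrow(disc)))
  pairs <- tibble(
    pair_id = sprintf("IAN-%02d", seq_len(n)),
    cohort = "IAN",
    sex = rep(c("MM", "MM", "FF"), length.out = n),
    age = rep(c(5, 7, 9, 11, 13), length.out = n),
    score_t1 = scores[, 1], score_t2 = scores[, 2],
    raw_t1 = t_to_raw(scores[, 1], config),
    raw_t2 = t_to_raw(scores[, 2], config),
    dx_t1 = dx1, dx_t2 = dx2
  )
  twin_cohort(pairs, label = "IAN", provenance = "synthetic", seed = NULL,
              config = config)
}
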