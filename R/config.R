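#' Analysis configuration
#'
#' Bundles the constants shared by every analysis stage: the clinical T-score
#' cutoff, the subthreshold floor of the "straddling" band, the clinical-
#' population standard deviation used by the quantitative discordance
#' criterion, the discordance multiplier k, and the affine raw-to-T map.
#'
#' Defaults follow SRS-2 conventions: a T-score of 65 (1.5 population SDs
#' above the mean) marks clinical-level affectation; 50T is the population
#' mean and the floor of the subthreshold band; 18.1 T-points is the standard
#' deviation of scores in a clinically ascertained population. The default
#' discordance multiplier is 1.5, so quantitative discordance requires a
#' twin-twin difference of at least 1.5 x 18.1 = 27.15 T-points *and* the
#' twins on opposite sides of the clinical threshold. The correction procedure
#' for reported discordance ([correct_reported_concordance()]) uses k = 1.
#'
#' The raw-to-T map `T = slope * raw + intercept` is a single affine
#' approximation to the (sex-specific, unpublished) SRS-2 norm tables; the
#' default slope 0.55 and intercept 25 jointly reconcile raw-scale difference
#' summaries with T-scale means, SDs and correlations in the two sampling
#' regimes this package models. Pearson correlations are invariant to the
#' choice, so it only matters when converting between scales.
#'
#' @param clinical_threshold T-score cutoff for clinical-level affectation.
#' @param subthreshold_floor T-score floor of the subthreshold band used by
#'   the straddle analysis. Must be strictly below `clinical_threshold`.
#' @param discordance_sd Clinical-population SD (T-points) entering the
#'   magnitude criterion.
#' @param discordance_multiplier Multiplier k applied to `discordance_sd`.
#' @param raw_to_t_slope,raw_to_t_intercept Affine raw-to-T map coefficients.
#' @param t_range,raw_range,age_range Valid ranges for T-scores, raw scores
#'   and ages (years) used by input validation and generator clamping.
#' @param seed Default integer seed for stochastic operations.
#' @return An object of class `twin_analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$discordance_multiplier * cfg$discordance_sd  # 27.15 T magnitude bar
#' @export
analysis_config <- function(clinical_threshold = 65,
                            subthreshold_floor = 50,
                            discordance_sd = 18.1,
                            discordance_multiplier = 1.5,
                            raw_to_t_slope = 0.55,
                            raw_to_t_intercept = 25,
                            t_range = c(30, 130),
                            raw_range = c(0, 195),
                            age_range = c(0, 30),
                            seed = 20191218L) {
  stopifnot(is.numeric(clinical_threshold), is.numeric(subthreshold_floor))
  if (!(clinical_threshold > subthreshold_floor)) {
    stop("`clinical_threshold` must exceed `subthreshold_floor`", call. = FALSE)
  }
  if (discordance_sd <= 0) stop("`discordance_sd` must be > 0", call. = FALSE)
  if (discordance_multiplier <= 0) stop("`discordance_multiplier` must be > 0", call. = FALSE)
  if (raw_to_t_slope <= 0) stop("`raw_to_t_slope` must be > 0", call. = FALSE)
  for (rg in list(t_range, raw_range, age_range)) {
    stopifnot(length(rg) == 2, rg[1] < rg[2])
  }
  structure(
    list(
      clinical_threshold = clinical_threshold,
      subthreshold_floor = subthreshold_floor,
      discordance_sd = discordance_sd,
      discordance_multiplier = discordance_multiplier,
      raw_to_t_slope = raw_to_t_slope,
      raw_to_t_intercept = raw_to_t_intercept,
      t_range = t_range,
      raw_range = raw_range,
      age_range = age_range,
      seed = as.integer(seed)
    ),
    class = "twin_analysis_config"
  )
}

#' @export
print.twin_analysis_config <- function(x, ...) {
  cat("<twin_analysis_config>\n")
  cat(sprintf("  clinical threshold : %g T (floor %g T)\n",
              x$clinical_threshold, x$subthreshold_floor))
  cat(sprintf("  discordance bar    : %g x %g = %g T\n",
              x$discordance_multiplier, x$discordance_sd,
              x$discordance_multiplier * x$discordance_sd))
  cat(sprintf("  raw -> T map       : T = %g * raw + %g\n",
              x$raw_to_t_slope, x$raw_to_t_intercept))
  invisible(x)
}

#' Read an analysis configuration from a flat YAML or JSON file
#'
#' Keys mirror the arguments of [analysis_config()]; keys absent from the
#' file keep their defaults. Unknown keys are an error (they are almost
#' always typos).
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return A `twin_analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(analysis_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' Convert between raw scores and T-scores
#'
#' The affine map `T = slope * raw + intercept` (and its exact inverse).
#' Because the map is affine, any Pearson correlation computed downstream is
#' identical on either scale.
#'
#' @param raw,t Numeric vectors of raw scores / T-scores.
#' @param config A [analysis_config()].
#' @return Numeric vector on the other scale.
#' @examples
#' raw_to_t(45.4545)          # 50, the population-mean T
#' t_to_raw(raw_to_t(100))    # 100 back again
#' @export
raw_to_t <- function(raw, config = analysis_config()) {
  stopifnot(is.numeric(raw))
  ok <- is.na(raw) | (raw >= config$raw_range[1] & raw <= config$raw_range[2])
  if (!all(ok)) {
    stop(sprintf("raw score(s) outside [%g, %g]: %s",
                 config$raw_range[1], config$raw_range[2],
                 paste(utils::head(raw[!ok], 5), collapse = ", ")),
         call. = FALSE)
  }
  config$raw_to_t_slope * raw + config$raw_to_t_intercept
}

#' @rdname raw_to_t
#' @export
t_to_raw <- function(t, config = analysis_config()) {
  stopifnot(is.numeric(t))
  (t - config$raw_to_t_intercept) / config$raw_to_t_slope
}

# Round half away from zero (base round() rounds half to even, which would
# turn e.g. 0.845 -> 0.84 when the printed convention is 0.85).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
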