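#' Twin-difference density plot
#'
#' Density of absolute twin-twin differences, one curve per cohort —
#' epidemiologic cohorts show a narrow spike near zero, clinical cohorts a
#' broad right tail.
#'
#' @param ... Named `twin_cohort` objects.
#' @param scale `"raw"` or `"T"`.
#' @return A ggplot object.
#' @export
plot_difference_density <- function(..., scale = "raw") {
  cohorts <- list(...)
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    names(cohorts) <- vapply(cohorts, function(x) attr(x, "label"), character(1))
  }
  df <- do.call(rbind, lapply(names(cohorts), function(nm) {
    cp <- complete_pairs(cohorts[[nm]], "SRS_total", scale)
    tibble(cohort = nm, absdiff = abs(cp$t1 - cp$t2))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$absdiff, colour = .data$cohort)) +
    ggplot2::geom_density(linewidth = 0.8) +
    ggplot2::labs(x = sprintf("absolute twin-twin difference (%s points)", scale),
                  y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Twin-twin scatter plot
#'
#' Twin 2 against twin 1 with the identity line and the clinical threshold.
#'
#' @param cohort A `twin_cohort`.
#' @param measure Measure to plot.
#' @param config Analysis configuration.
#' @return A ggplot object.
#' @export
plot_twin_scatter <- function(cohort, measure = "SRS_total",
                              config = analysis_config()) {
  cp <- complete_pairs(cohort, measure, "T")
  ggplot2::ggplot(tibble(t1 = cp$t1, t2 = cp$t2),
                  ggplot2::aes(x = .data$t1, y = .data$t2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = config$clinical_threshold,
                        colour = "firebrick", linetype = "dotted") +
    ggplot2::geom_vline(xintercept = config$clinical_threshold,
                        colour = "firebrick", linetype = "dotted") +
    ggplot2::labs(x = "twin 1", y = "twin 2",
                  title = sprintf("%s (%s)", measure, attr(cohort, "label"))) +
    ggplot2::theme_minimal()
}

#' Ordered straddle plot
#'
#' Each pair drawn as a vertical segment from the lower- to the
#' higher-scoring twin, ordered by the lower twin's T-score, with the
#' clinical threshold and subthreshold floor marked — pairs whose segment
#' crosses the threshold from inside the subthreshold band are the
#' "straddling" pairs.
#'
#' @param cohort A `twin_cohort`.
#' @param config Analysis configuration.
#' @return A ggplot object.
#' @export
plot_straddle <- function(cohort, config = analysis_config()) {
  lower <- pmin(cohort$score_t1, cohort$score_t2)
  upper <- pmax(cohort$score_t1, cohort$score_t2)
  ord <- order(lower)
  df <- tibble(rank = seq_along(ord), lower = lower[ord], upper = upper[ord])
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$rank, xend = .data$rank,
                                       y = .data$lower, yend = .data$upper),
                          colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(x = .data$rank, y = .data$lower), size = 1) +
    ggplot2::geom_point(ggplot2::aes(x = .data$rank, y = .data$upper), size = 1,
                        colour = "grey30") +
    ggplot2::geom_hline(yintercept = config$clinical_threshold,
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = config$subthreshold_floor,
                        colour = "steelblue", linetype = "dashed") +
    ggplot2::labs(x = "pairs, ascending by lower twin's T-score",
                  y = "SRS total T-score") +
    ggplot2::theme_minimal()
}
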