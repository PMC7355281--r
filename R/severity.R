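#' Twin-difference summary
#'
#' Mean and sample SD (n-1 denominator) of the absolute twin-twin
#' difference `|score_1 - score_2|` on the chosen scale, plus a binned
#' histogram of the differences for density display. Incomplete pairs are
#' dropped and counted.
#'
#' @param cohort A `twin_cohort`.
#' @param scale `"raw"` or `"T"`.
#' @param bin_width Histogram bin width in score points.
#' @return An object of class `difference_summary`: `scale`, `n_pairs`,
#'   `n_dropped`, `mean_absdiff`, `sd_absdiff`, `histogram` (tibble with
#'   `mid`, `count`, `density`).
#' @examples
#' epi <- generate_preset_cohort("epidemiologic", seed = 1)
#' difference_summary(epi, "raw")$mean_absdiff  # close to 7.7
#' @export
difference_summary <- function(cohort, scale = c("raw", "T"), bin_width = 5) {
  scale <- match.arg(scale)
  cp <- complete_pairs(cohort, "SRS_total", scale)
  if (nrow(cp) < 2) {
    stop("need at least 2 complete pairs on the ", scale, " scale", call. = FALSE)
  }
  absdiff <- abs(cp$t1 - cp$t2)
  breaks <- seq(0, max(absdiff, bin_width) + bin_width, by = bin_width)
  h <- graphics::hist(absdiff, breaks = breaks, plot = FALSE)
  structure(
    list(
      scale = scale,
      n_pairs = nrow(cp),
      n_dropped = attr(cp, "n_dropped"),
      mean_absdiff = mean(absdiff),
      sd_absdiff = stats::sd(absdiff),
      histogram = tibble(mid = h$mids, count = h$counts, density = h$density)
    ),
    class = "difference_summary"
  )
}

#' @export
print.difference_summary <- function(x, ...) {
  cat(sprintf("<difference_summary> |d| on the %s scale, %d pairs (%d dropped)\n",
              x$scale, x$n_pairs, x$n_dropped))
  cat(sprintf("  mean %.2f (SD %.2f)\n", x$mean_absdiff, x$sd_absdiff))
  invisible(x)
}

#' Twin-twin correlation
#'
#' Correlation between the twin-1 and twin-2 score columns of a cohort, by
#' Pearson or Spearman in input order, or by the order-free double-entry
#' intraclass method (each pair entered twice, in both orders). The squared
#' correlation, as an integer percentage, estimates familiality — the trait
#' variance attributable to family-level (genetic plus shared-environment)
#' influence.
#'
#' The p-value is an auxiliary large-sample test from [stats::cor.test()];
#' for the double-entry method it is `NA` (the doubled rows are not
#' independent, so the nominal test would be anticonservative).
#'
#' @param cohort A `twin_cohort`.
#' @param measure `"SRS_total"`, `"SCI"`, `"RRB"` or `"ADOS"`.
#' @param method `"pearson"`, `"spearman"` or `"icc_double_entry"`.
#' @param scale Score scale for `SRS_total` (subscales and ADOS have one).
#' @return An object of class `correlation_result`: `measure`, `method`,
#'   `r`, `r2_percent`, `n_pairs`, `p_value`.
#' @examples
#' epi <- generate_preset_cohort("epidemiologic", seed = 1)
#' twin_correlation(epi, "SRS_total")$r  # close to 0.754
#' @export
twin_correlation <- function(cohort,
                             measure = c("SRS_total", "SCI", "RRB", "ADOS"),
                             method = c("pearson", "spearman", "icc_double_entry"),
                             scale = "T") {
  measure <- match.arg(measure)
  method <- match.arg(method)
  cp <- complete_pairs(cohort, measure, scale)
  if (nrow(cp) < 3) {
    stop("need at least 3 complete pairs for ", measure, call. = FALSE)
  }
  if (stats::sd(cp$t1) == 0 || stats::sd(cp$t2) == 0) {
    stop("undefined correlation: zero variance in a twin column", call. = FALSE)
  }
  if (method == "icc_double_entry") {
    x <- c(cp$t1, cp$t2)
    y <- c(cp$t2, cp$t1)
    r <- stats::cor(x, y)
    p <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(cp$t1, cp$t2, method = method, exact = FALSE)
    )
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(measure = measure, method = method, r = r,
         r2_percent = familiality_variance(r),
         n_pairs = nrow(cp), n_dropped = attr(cp, "n_dropped"), p_value = p),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s (%s, %d pairs): r = %.3f (%d%% of variance)%s\n",
              x$measure, x$method, x$n_pairs, x$r, x$r2_percent,
              if (is.na(x$p_value)) "" else sprintf(", p = %.3g", x$p_value)))
  invisible(x)
}

#' Familiality variance from a twin correlation
#'
#' `100 * r^2`, half-up rounded to an integer percentage; the sign of `r`
#' is discarded. For monozygotic twins the squared twin correlation bounds
#' the trait variance attributable to familial (genetic plus shared
#' environment) influence.
#'
#' @param r Correlation in `[-1, 1]`.
#' @return Integer percentage.
#' @examples
#' familiality_variance(0.754)  # 57
#' familiality_variance(0.27)   # 7
#' @export
familiality_variance <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  as.integer(round_half_up(100 * r^2))
}

#' Severity vs twin-difference association
#'
#' Spearman rank correlation between each pair's mean score and its
#' absolute twin-twin difference, with a two-sided large-sample p-value.
#' A positive association means pairs of higher mean severity (in
#' particular, pairs near the clinical threshold) show larger differences.
#'
#' @param cohort A `twin_cohort`.
#' @param scale Score scale (Spearman is invariant to the affine raw/T map,
#'   so this only matters for display).
#' @return A list: `rho`, `p_value`, `n_pairs`.
#' @export
severity_difference_association <- function(cohort, scale = "T") {
  cp <- complete_pairs(cohort, "SRS_total", scale)
  if (nrow(cp) < 5) stop("need at least 5 complete pairs", call. = FALSE)
  pair_mean <- (cp$t1 + cp$t2) / 2
  absdiff <- abs(cp$t1 - cp$t2)
  if (length(unique(pair_mean)) < 2 || length(unique(absdiff)) < 2) {
    stop("undefined association: a variable is constant (ties only)",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(pair_mean, absdiff, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_pairs = nrow(cp))
}

#' Age vs twin-difference association
#'
#' Pearson and Spearman correlations between pair age and the absolute
#' twin-twin difference; near-zero values indicate that the non-shared
#' influences driving twin differences are not accumulating with age.
#'
#' @param cohort A `twin_cohort` with ages.
#' @param scale Score scale for the difference.
#' @return A list: `pearson_r`, `spearman_rho`, `n_pairs`.
#' @export
age_association <- function(cohort, scale = "T") {
  cp0 <- complete_pairs(cohort, "SRS_total", scale)
  age <- cohort$age[match(cp0$pair_id, cohort$pair_id)]
  ok <- !is.na(age)
  if (sum(ok) < 5) stop("need at least 5 pairs with ages", call. = FALSE)
  age <- age[ok]
  absdiff <- abs(cp0$t1 - cp0$t2)[ok]
  if (stats::sd(age) == 0) {
    stop("undefined correlation: ages are constant", call. = FALSE)
  }
  list(
    pearson_r = stats::cor(age, absdiff),
    spearman_rho = stats::cor(age, absdiff, method = "spearman"),
    n_pairs = sum(ok)
  )
}
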