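#' Concordance rates from counts
#'
#' Standard twin-study statistics: the pairwise rate `C / (C + D)` and the
#' probandwise rate `2C / (2C + D)` (each concordant pair contributes two
#' probands under complete ascertainment). Rates are carried at full
#' precision together with a 2-decimal half-up rounding for comparison with
#' printed values. Note that `probandwise >= pairwise` always, with equality
#' only when `C = 0` or `D = 0`.
#'
#' @param n_concordant,n_discordant Non-negative pair counts, `C + D >= 1`.
#' @param audit Optional tibble of reclassification events.
#' @return An object of class `concordance_result`.
#' @examples
#' concordance_from_counts(50, 5)$rate_pairwise_2dp   # 0.91
#' concordance_from_counts(14, 9)$rate_pairwise_2dp   # 0.61
#' @export
concordance_from_counts <- function(n_concordant, n_discordant, audit = NULL) {
  C <- n_concordant; D <- n_discordant
  stopifnot(C >= 0, D >= 0, C == round(C), D == round(D))
  if (C + D < 1) stop("undefined rate: no pairs (C + D = 0)", call. = FALSE)
  if (is.null(audit)) {
    audit <- tibble(pair_id = character(), rule = character())
  }
  structure(
    list(
      n_pairs = C + D,
      n_concordant = C,
      n_discordant = D,
      rate_pairwise = C / (C + D),
      rate_probandwise = 2 * C / (2 * C + D),
      rate_pairwise_2dp = round_half_up(C / (C + D), 2),
      rate_probandwise_2dp = round_half_up(2 * C / (2 * C + D), 2),
      audit = audit
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %d pairs: %d concordant, %d discordant\n",
              x$n_pairs, x$n_concordant, x$n_discordant))
  cat(sprintf("  pairwise   : %.4f (%.2f)\n", x$rate_pairwise, x$rate_pairwise_2dp))
  cat(sprintf("  probandwise: %.4f (%.2f)\n", x$rate_probandwise, x$rate_probandwise_2dp))
  if (nrow(x$audit) > 0) {
    cat(sprintf("  %d pair(s) reclassified concordant:\n", nrow(x$audit)))
    for (i in seq_len(nrow(x$audit))) {
      cat(sprintf("    %s  [%s]\n", x$audit$pair_id[i], x$audit$rule[i]))
    }
  }
  invisible(x)
}

#' Quantitative discordance classification
#'
#' Classifies each pair on its total-score T-scores under the quantitative
#' discordance definition: a pair is `discordant` iff (1) the twin-twin
#' difference is at least `k * discordance_sd` T-points (default
#' 1.5 x 18.1 = 27.15) *and* (2) the twins fall on opposite sides of the
#' clinical threshold (`min < threshold <= max`; a twin exactly at the
#' cutoff counts as affected). Pairs with both twins at/above the threshold
#' are `concordant_affected`; both below, `concordant_unaffected`; pairs
#' that straddle the threshold but miss the magnitude criterion are
#' `straddling_subcriterion`. The four labels are mutually exclusive and
#' exhaustive, and classification is invariant to twin order.
#'
#' @param cohort A `twin_cohort` with complete total T-scores.
#' @param config Analysis configuration.
#' @param k Discordance multiplier; defaults to the configured value.
#' @return A tibble with one row per pair: `pair_id`, `lower_score`,
#'   `upper_score`, `abs_diff_t`, `meets_magnitude`, `straddles_threshold`,
#'   `label`.
#' @examples
#' coh <- make_reclassification_fixture()
#' table(classify_pairs(coh)$label)
#' @export
classify_pairs <- function(cohort, config = analysis_config(),
                           k = config$discordance_multiplier) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (any(is.na(cohort$score_t1) | is.na(cohort$score_t2))) {
    stop("incomplete pair(s): both T-scores are required for classification",
         call. = FALSE)
  }
  lower <- pmin(cohort$score_t1, cohort$score_t2)
  upper <- pmax(cohort$score_t1, cohort$score_t2)
  thr <- config$clinical_threshold
  meets_magnitude <- (upper - lower) >= k * config$discordance_sd
  straddles <- lower < thr & thr <= upper
  label <- ifelse(meets_magnitude & straddles, "discordant",
           ifelse(lower >= thr, "concordant_affected",
           ifelse(upper < thr, "concordant_unaffected",
                  "straddling_subcriterion")))
  tibble(
    pair_id = cohort$pair_id,
    lower_score = lower,
    upper_score = upper,
    abs_diff_t = upper - lower,
    meets_magnitude = meets_magnitude,
    straddles_threshold = straddles,
    label = label
  )
}

#' @rdname classify_pairs
#' @param score_t1,score_t2 A single pair's T-scores.
#' @export
classify_pair <- function(score_t1, score_t2, config = analysis_config(),
                          k = config$discordance_multiplier) {
  if (is.na(score_t1) || is.na(score_t2)) {
    stop("incomplete pair: both T-scores are required", call. = FALSE)
  }
  coh <- twin_cohort(
    tibble(pair_id = "pair", cohort = "other",
           score_t1 = score_t1, score_t2 = score_t2),
    config = config, validate = FALSE
  )
  classify_pairs(coh, config, k)
}

#' Cohort concordance under the quantitative classifier
#'
#' Applies [classify_pairs()] and counts `discordant` pairs against all
#' others (concordant by quantitative standards).
#'
#' @inheritParams classify_pairs
#' @return A `concordance_result` with the per-pair classification attached
#'   as attribute `"classes"`.
#' @export
cohort_concordance <- function(cohort, config = analysis_config(),
                               k = config$discordance_multiplier) {
  cls <- classify_pairs(cohort, config, k)
  D <- sum(cls$label == "discordant")
  res <- concordance_from_counts(nrow(cls) - D, D)
  attr(res, "classes") <- cls
  res
}

#' Correct reported concordance by quantitative standards
#'
#' Reported (e.g. parent-reported community-diagnosis) discordance is often
#' an overcount: a pair is reclassified concordant if (a) the lower-scoring
#' twin's total T-score *exceeds* the clinical cutoff — "discordant" twins
#' who are both clinically affected — or (b) the twin-twin difference is
#' below `k` clinical standard deviations (default `k = 1`, i.e. one full
#' SD of 18.1 T). Reported-concordant pairs are never touched; the
#' correction can only decrease the discordant count and never changes the
#' total. Every reclassification is recorded in the audit trail with the
#' rule that fired (rule (a) takes precedence when both apply).
#'
#' @param cohort A `twin_cohort` whose pairs carry reported-diagnosis flags
#'   (`dx_t1`, `dx_t2` in yes/no).
#' @param config Analysis configuration.
#' @param k Multiplier on `discordance_sd` for rule (b); default 1.
#' @return A `concordance_result` with the corrected counts and audit trail.
#' @examples
#' fix <- make_reclassification_fixture()
#' correct_reported_concordance(fix)$rate_pairwise_2dp  # 0.91
#' @export
correct_reported_concordance <- function(cohort, config = analysis_config(),
                                         k = 1.0) {
  stopifnot(inherits(cohort, "twin_cohort"))
  dx1 <- cohort$dx_t1; dx2 <- cohort$dx_t2
  known <- !is.na(dx1) & !is.na(dx2) & dx1 %in% c("yes", "no") & dx2 %in% c("yes", "no")
  if (!any(known)) {
    stop("no reported-diagnosis flags in this cohort; ",
         "use classify_pairs()/cohort_concordance() for quantitative classification",
         call. = FALSE)
  }
  coh <- cohort[known, ]
  rep_disc <- coh$dx_t1 != coh$dx_t2
  lower <- pmin(coh$score_t1, coh$score_t2)
  diff_t <- abs(coh$score_t1 - coh$score_t2)
  rule_a <- rep_disc & lower > config$clinical_threshold
  rule_b <- rep_disc & !rule_a & diff_t < k * config$discordance_sd
  reclass <- rule_a | rule_b
  audit <- tibble(
    pair_id = coh$pair_id[reclass],
    rule = ifelse(rule_a[reclass], "lower_twin_above_cutoff",
                  "difference_below_sd")
  )
  D <- sum(rep_disc & !reclass)
  C <- sum(!rep_disc) + sum(reclass)
  concordance_from_counts(C, D, audit = audit)
}

#' Threshold-straddle analysis
#'
#' Counts pairs whose lower-scoring twin falls in the subthreshold band
#' `[subthreshold_floor, clinical_threshold)` while the co-twin scores at or
#' above the threshold — pairs "straddling the line" of clinical
#' affectation, technically discordant by category yet quantitatively
#' similar. The pair list is returned sorted ascending by the lower twin's
#' T-score (the display order of the ordered-pair plot).
#'
#' @param cohort A `twin_cohort` with complete total T-scores.
#' @param config Analysis configuration.
#' @return A list: `count`, `fraction` (of all pairs), and `pairs` (ordered
#'   tibble with `pair_id`, `lower_score`, `upper_score`, `abs_diff_t`).
#' @export
straddle_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  if (any(is.na(cohort$score_t1) | is.na(cohort$score_t2))) {
    stop("incomplete pair(s): both T-scores are required", call. = FALSE)
  }
  lower <- pmin(cohort$score_t1, cohort$score_t2)
  upper <- pmax(cohort$score_t1, cohort$score_t2)
  sel <- lower >= config$subthreshold_floor &
    lower < config$clinical_threshold &
    upper >= config$clinical_threshold
  pairs <- tibble(
    pair_id = cohort$pair_id[sel],
    lower_score = lower[sel],
    upper_score = upper[sel],
    abs_diff_t = (upper - lower)[sel]
  )
  pairs <- pairs[order(pairs$lower_score), ]
  list(count = sum(sel), fraction = sum(sel) / nrow(cohort), pairs = pairs)
}
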