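#' Run the full twin-concordance analysis pipeline
#'
#' Executes, per cohort and in order: twin-difference summaries (raw and T),
#' twin correlations and familiality (total score plus any available
#' subscales and ADOS, Pearson/Spearman/double-entry ICC), severity- and
#' age-vs-difference associations, quantitative classification and
#' concordance (with the reported-discordance correction wherever diagnosis
#' flags exist), and the threshold-straddle analysis; then, if a score pool
#' is supplied or requested, the truncation simulation comparing the
#' expected above-threshold correlation with the observed one. Results are
#' collected into a machine-readable report with a config snapshot and all
#' seeds, so a rerun with the same inputs is bit-identical.
#'
#' @param cohorts A named list of `twin_cohort` objects, or a character
#'   vector of preset names (generated synthetically with `seed`).
#' @param config Analysis configuration.
#' @param pool A [score_pool()], `TRUE` to build the synthetic population
#'   pool, or `NULL` to skip the truncation stage.
#' @param target_r Constraint for the truncation simulation (default 0.77,
#'   an all-groups twin correlation).
#' @param n_sim Simulated pairs for the truncation stage.
#' @param seed Integer seed for synthetic cohorts and the simulation.
#' @param out Optional path; the report is written there as JSON.
#' @param quiet Suppress per-stage messages.
#' @return The report, an object of class `analysis_report` (nested list).
#' @export
run_pipeline <- function(cohorts, config = analysis_config(), pool = NULL,
                         target_r = 0.77, n_sim = 10000, seed = config$seed,
                         out = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.character(cohorts)) {
    names <- cohorts
    cohorts <- lapply(seq_along(names), function(i) {
      generate_preset_cohort(names[i], config = config, seed = seed + i - 1L)
    })
    names(cohorts) <- names
  }
  stopifnot(length(cohorts) >= 1)
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    names(cohorts) <- vapply(cohorts, function(x) attr(x, "label"), character(1))
  }

  cohort_block <- function(coh, name) {
    say("stage differences [%s]: %d pairs", name, nrow(coh))
    block <- list(n_pairs = nrow(coh))
    block$differences <- lapply(c(raw = "raw", T = "T"), function(sc) {
      d <- tryCatch(difference_summary(coh, sc), error = function(e) NULL)
      if (is.null(d)) return(NULL)
      list(n_pairs = d$n_pairs, mean_absdiff = d$mean_absdiff,
           sd_absdiff = d$sd_absdiff)
    })
    say("stage correlations [%s]", name)
    corrs <- list()
    for (meas in c("SRS_total", "SCI", "RRB", "ADOS")) {
      for (meth in c("pearson", "spearman", "icc_double_entry")) {
        cr <- tryCatch(twin_correlation(coh, meas, meth),
                       error = function(e) NULL)
        if (!is.null(cr)) {
          corrs[[paste(meas, meth, sep = ".")]] <-
            list(r = cr$r, r2_percent = cr$r2_percent, n_pairs = cr$n_pairs,
                 p_value = cr$p_value)
        }
      }
    }
    block$correlations <- corrs
    pe <- corrs[["SRS_total.pearson"]]
    de <- corrs[["SRS_total.icc_double_entry"]]
    if (!is.null(pe) && !is.null(de) && abs(pe$r - de$r) > 0.05) {
      say("note [%s]: Pearson (%.3f) and double-entry ICC (%.3f) diverge by > 0.05",
          name, pe$r, de$r)
    }
    say("stage associations [%s]", name)
    block$severity_vs_difference <- tryCatch(
      severity_difference_association(coh), error = function(e) NULL)
    block$age_vs_difference <- tryCatch(
      age_association(coh), error = function(e) NULL)
    say("stage concordance [%s]", name)
    qc <- cohort_concordance(coh, config)
    block$concordance <- list(
      n_concordant = qc$n_concordant, n_discordant = qc$n_discordant,
      rate_pairwise = qc$rate_pairwise, rate_probandwise = qc$rate_probandwise,
      rate_pairwise_2dp = qc$rate_pairwise_2dp,
      rate_probandwise_2dp = qc$rate_probandwise_2dp,
      labels = as.list(table(attr(qc, "classes")$label))
    )
    corr <- tryCatch(correct_reported_concordance(coh, config),
                     error = function(e) NULL)
    if (!is.null(corr)) {
      block$corrected_concordance <- list(
        n_concordant = corr$n_concordant, n_discordant = corr$n_discordant,
        rate_pairwise = corr$rate_pairwise,
        rate_pairwise_2dp = corr$rate_pairwise_2dp,
        rate_probandwise = corr$rate_probandwise,
        audit = if (nrow(corr$audit) > 0) {
          lapply(seq_len(nrow(corr$audit)), function(i) {
            list(pair_id = corr$audit$pair_id[i], rule = corr$audit$rule[i])
          })
        } else list()
      )
    }
    say("stage straddle [%s]", name)
    st <- straddle_analysis(coh, config)
    block$straddle <- list(count = st$count, fraction = st$fraction,
                           pair_ids = as.list(st$pairs$pair_id))
    block
  }

  report <- list(
    software = list(package = "twinconcord",
                    version = as.character(utils::packageVersion("twinconcord"))),
    config = unclass(config),
    seed = as.integer(seed),
    cohorts = stats::setNames(
      lapply(names(cohorts), function(nm) cohort_block(cohorts[[nm]], nm)),
      names(cohorts)
    )
  )

  if (isTRUE(pool)) pool <- synthetic_score_pool(config = config, seed = seed)
  if (!is.null(pool) && inherits(pool, "score_pool")) {
    say("stage truncation_sim: n = %d, target r = %.2f", n_sim, target_r)
    clinical <- Filter(function(x) mean(x$score_t1 >= config$clinical_threshold,
                                        na.rm = TRUE) > 0.5, cohorts)
    observed <- if (length(clinical) > 0) clinical[[1]] else NULL
    ts <- expected_vs_observed(pool, target_r, config$clinical_threshold,
                               observed_cohort = observed, config = config,
                               n = n_sim, seed = seed)
    report$truncation_sim <- list(
      n_simulated = ts$n_simulated, latent_rho = ts$latent_rho,
      r_full = ts$r_full, threshold = ts$threshold,
      n_survivors = ts$n_survivors, r_truncated = ts$r_truncated,
      r_observed = ts$r_observed,
      n_observed_survivors = ts$n_observed_survivors
    )
  }

  class(report) <- "analysis_report"
  if (!is.null(out)) {
    write_report(report, out)
    say("report written to %s", out)
  }
  report
}

#' Write an analysis report as JSON
#'
#' Stable key order, full numeric precision, scalars unboxed — reruns with
#' identical inputs and seeds produce byte-identical files.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
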