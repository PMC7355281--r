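# Small deterministic cohort builders used across the suite.

make_cohort <- function(t1, t2, raw = FALSE, ages = NULL, dx1 = NULL, dx2 = NULL,
                        label = "test", config = analysis_config()) {
  df <- tibble::tibble(
    pair_id = sprintf("p%02d", seq_along(t1)),
    cohort = label,
    score_t1 = t1, score_t2 = t2
  )
  if (raw) {
    df$raw_t1 <- t_to_raw(t1, config)
    df$raw_t2 <- t_to_raw(t2, config)
  }
  if (!is.null(ages)) df$age <- ages
  if (!is.null(dx1)) { df$dx_t1 <- dx1; df$dx_t2 <- dx2 }
  twin_cohort(df, label = label, config = config)
}

# a random valid cohort for property-style loops
random_cohort <- function(n, config = analysis_config()) {
  t1 <- round(stats::runif(n, 35, 125), 1)
  t2 <- round(stats::runif(n, 35, 125), 1)
  make_cohort(t1, t2, config = config)
}

# 78-pair clinically ascertained fixture with exactly 13 straddling pairs
# (lower twin in [50, 65), co-twin >= 65); the rest split between
# concordant-affected, concordant-unaffected and wide-discordant pairs.
make_straddle_fixture <- function(config = analysis_config()) {
  straddle_lower <- c(50, 51, 53, 54, 56, 57, 58, 59, 60, 61, 62, 63, 64)
  straddle_upper <- straddle_lower + c(20, 16, 18, 15, 14, 17, 13, 12,
                                       11, 15, 10, 9, 8)
  both_above <- cbind(seq(66, 124, length.out = 45),
                      seq(70, 128, length.out = 45))
  both_below <- cbind(seq(36, 45, length.out = 15),
                      seq(38, 49, length.out = 15))
  wide <- cbind(c(40, 42, 44, 46, 48), c(90, 95, 100, 105, 110))
  t1 <- c(straddle_lower, both_above[, 1], both_below[, 1], wide[, 1])
  t2 <- c(straddle_upper, both_above[, 2], both_below[, 2], wide[, 2])
  make_cohort(round(t1, 1), round(t2, 1), label = "clinical_combined",
              config = config)
}
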