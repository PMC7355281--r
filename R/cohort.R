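#' @importFrom tibble tibble as_tibble
NULL

# Canonical wide-format column order; one row = one MZ pair.
COHORT_COLUMNS <- c(
  "pair_id", "cohort", "sex", "age",
  "score_t1", "score_t2", "raw_t1", "raw_t2",
  "sci_t1", "sci_t2", "rrb_t1", "rrb_t2",
  "ados_t1", "ados_t2", "dx_t1", "dx_t2"
)
COHORT_REQUIRED <- c("pair_id", "cohort", "score_t1", "score_t2")
COHORT_NUMERIC <- c("age", "score_t1", "score_t2", "raw_t1", "raw_t2",
                    "sci_t1", "sci_t2", "rrb_t1", "rrb_t2", "ados_t1", "ados_t2")

#' Construct a twin cohort
#'
#' A twin cohort is a tibble with one row per monozygotic pair, carrying the
#' SRS total T-scores of both twins plus optional raw scores, SCI/RRB subscale
#' T-scores, ADOS social-affect scores, reported-diagnosis flags, sex and age.
#' Missing optional values are `NA`, never zero.
#'
#' @param pairs A data frame with at least `pair_id`, `cohort`, `score_t1`,
#'   `score_t2`; optional columns are filled with `NA` when absent.
#' @param label Cohort label (kept as an attribute).
#' @param provenance `"observed"` or `"synthetic"`.
#' @param seed Integer seed (synthetic cohorts only).
#' @param config Validation configuration.
#' @param validate If `TRUE` (default), rows violating the pair invariants
#'   are an error; [read_cohort()] instead rejects them row by row.
#' @return A tibble of class `twin_cohort`.
#' @export
twin_cohort <- function(pairs, label = "cohort",
                        provenance = c("observed", "synthetic"),
                        seed = NULL, config = analysis_config(),
                        validate = TRUE) {
  provenance <- match.arg(provenance)
  pairs <- as_tibble(pairs)
  missing_req <- setdiff(COHORT_REQUIRED, names(pairs))
  if (length(missing_req) > 0) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(COHORT_COLUMNS, names(pairs))) {
    pairs[[col]] <- if (col %in% COHORT_NUMERIC) NA_real_ else NA_character_
  }
  pairs <- pairs[COHORT_COLUMNS]
  pairs$pair_id <- as.character(pairs$pair_id)
  pairs$cohort <- as.character(pairs$cohort)
  for (col in COHORT_NUMERIC) pairs[[col]] <- as.numeric(pairs[[col]])
  if (anyDuplicated(pairs$pair_id)) {
    stop("duplicate pair_id(s): ",
         paste(unique(pairs$pair_id[duplicated(pairs$pair_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (validate) {
    diag <- validate_pairs(pairs, config)
    if (nrow(diag) > 0) {
      stop("invalid pair data:\n  ",
           paste(sprintf("row %d (%s): %s", diag$row, diag$field, diag$message),
                 collapse = "\n  "),
           call. = FALSE)
    }
  }
  structure(pairs,
            class = c("twin_cohort", class(pairs)),
            label = label, provenance = provenance, seed = seed)
}

# Row-by-row invariant checks. Returns a tibble(row, field, message);
# zero rows means everything passed.
validate_pairs <- function(pairs, config = analysis_config()) {
  out <- list()
  note <- function(row, field, message) {
    out[[length(out) + 1]] <<- tibble(row = row, field = field, message = message)
  }
  rng_check <- function(field, rng, unit) {
    v <- pairs[[field]]
    bad <- which(!is.na(v) & (v < rng[1] | v > rng[2]))
    for (i in bad) {
      note(i, field, sprintf("%g outside [%g, %g] %s", v[i], rng[1], rng[2], unit))
    }
  }
  for (f in c("score_t1", "score_t2", "sci_t1", "sci_t2", "rrb_t1", "rrb_t2")) {
    rng_check(f, config$t_range, "T")
  }
  for (f in c("raw_t1", "raw_t2")) rng_check(f, config$raw_range, "raw")
  rng_check("age", config$age_range, "years")
  for (i in which(is.na(pairs$score_t1) | is.na(pairs$score_t2))) {
    f <- if (is.na(pairs$score_t1[i])) "score_t1" else "score_t2"
    note(i, f, "required T-score is missing or unparseable")
  }
  # raw/T consistency within 1 T-point of the configured affine map
  for (side in 1:2) {
    rawv <- pairs[[paste0("raw_t", side)]]
    tv <- pairs[[paste0("score_t", side)]]
    both <- which(!is.na(rawv) & !is.na(tv) &
                    rawv >= config$raw_range[1] & rawv <= config$raw_range[2])
    off <- both[abs(config$raw_to_t_slope * rawv[both] +
                      config$raw_to_t_intercept - tv[both]) > 1]
    for (i in off) {
      note(i, paste0("raw_t", side),
           sprintf("raw %g maps to %.1fT but score is %gT (> 1 T-point apart)",
                   rawv[i],
                   config$raw_to_t_slope * rawv[i] + config$raw_to_t_intercept,
                   tv[i]))
    }
  }
  sexv <- pairs$sex
  for (i in which(!is.na(sexv) & !sexv %in% c("MM", "FF", "unknown"))) {
    note(i, "sex", sprintf("'%s' is not MM/FF/unknown", sexv[i]))
  }
  for (f in c("dx_t1", "dx_t2")) {
    v <- pairs[[f]]
    for (i in which(!is.na(v) & !v %in% c("yes", "no", "unknown"))) {
      note(i, f, sprintf("'%s' is not yes/no/unknown", v[i]))
    }
  }
  if (length(out) == 0) {
    return(tibble(row = integer(), field = character(), message = character()))
  }
  diag <- do.call(rbind, out)
  diag[order(diag$row), ]
}

#' Read a twin cohort from CSV
#'
#' Expects the wide comma-separated format written by [write_cohort()]:
#' UTF-8, header row, "." decimal separator, empty cell = missing. Rows that
#' violate the pair invariants (scores out of range, unparseable numbers,
#' missing required T-scores, raw/T map mismatch) are rejected with
#' row-numbered diagnostics rather than aborting the read; accepted plus
#' rejected always equals the row total.
#'
#' @param path CSV file path.
#' @param config Validation configuration.
#' @param label Cohort label; defaults to the most common `cohort` value.
#' @param quiet Suppress the accepted/rejected message.
#' @return A `twin_cohort`; rejected-row diagnostics are in
#'   `attr(x, "diagnostics")` (tibble with `row`, `field`, `message`).
#' @export
read_cohort <- function(path, config = analysis_config(), label = NULL,
                        quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- do.call(readr::cols, c(
    stats::setNames(rep(list(readr::col_character()),
                        length(setdiff(COHORT_COLUMNS, COHORT_NUMERIC))),
                    setdiff(COHORT_COLUMNS, COHORT_NUMERIC)),
    stats::setNames(rep(list(readr::col_double()), length(COHORT_NUMERIC)),
                    COHORT_NUMERIC),
    list(.default = readr::col_character())
  ))
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = spec, na = c("", "NA"),
                    progress = FALSE, show_col_types = FALSE)
  )
  force_materialize <- as.data.frame(raw)  # lazy readers record parse problems on access
  if (nrow(raw) == 0) stop("empty cohort file: ", path, call. = FALSE)
  # unparseable numeric cells: readr leaves NA and records the cell;
  # problems() indexes file rows (header included) and file column order,
  # so capture it before any column reshuffling
  probs <- readr::problems(raw)
  parse_diag <- NULL
  if (nrow(probs) > 0) {
    parse_diag <- tibble(
      row = probs$row - 1L,
      field = names(raw)[probs$col],
      message = sprintf("cannot parse '%s' as a number", probs$actual)
    )
  }
  missing_req <- setdiff(COHORT_REQUIRED, names(raw))
  if (length(missing_req) > 0) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(COHORT_COLUMNS, names(raw))) {
    raw[[col]] <- if (col %in% COHORT_NUMERIC) NA_real_ else NA_character_
  }
  raw <- raw[COHORT_COLUMNS]
  inv_diag <- validate_pairs(raw, config)
  diag <- rbind(
    if (is.null(parse_diag)) tibble(row = integer(), field = character(),
                                    message = character()) else parse_diag,
    inv_diag
  )
  # a parse failure on a required score also trips the missing-score check;
  # keep the more specific parse message
  diag <- diag[!duplicated(diag[c("row", "field")]), ]
  diag <- diag[order(diag$row), ]

  keep <- setdiff(seq_len(nrow(raw)), unique(diag$row))
  if (length(keep) == 0) {
    stop("no valid rows in ", path, " (", nrow(raw), " rejected)", call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("read_cohort: %d accepted, %d rejected (of %d rows)",
                    length(keep), nrow(raw) - length(keep), nrow(raw)))
  }
  accepted <- raw[keep, ]
  if (is.null(label)) {
    label <- names(sort(table(accepted$cohort), decreasing = TRUE))[1]
    if (is.null(label) || is.na(label)) label <- "cohort"
  }
  out <- twin_cohort(accepted, label = label, provenance = "observed",
                     config = config, validate = FALSE)
  attr(out, "diagnostics") <- diag
  out
}

#' Write a twin cohort to CSV
#'
#' Deterministic column order, full precision, empty cells for missing
#' values; round-trips losslessly through [read_cohort()].
#'
#' @param cohort A `twin_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (nrow(cohort) == 0) stop("refusing to write an empty cohort", call. = FALSE)
  readr::write_csv(as_tibble(cohort)[COHORT_COLUMNS], path, na = "")
  invisible(path)
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("<twin_cohort> %s (%s%s): %d pairs\n",
              attr(x, "label") %||% "?", attr(x, "provenance") %||% "?",
              if (!is.null(attr(x, "seed"))) paste0(", seed ", attr(x, "seed")) else "",
              nrow(x)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Complete-pair extractor for a measure; returns a tibble(t1, t2) plus the
# dropped-count as an attribute so callers can log it.
measure_columns <- function(measure = c("SRS_total", "SCI", "RRB", "ADOS"),
                            scale = c("T", "raw")) {
  measure <- match.arg(measure)
  scale <- match.arg(scale)
  if (measure == "SRS_total") {
    if (scale == "raw") c("raw_t1", "raw_t2") else c("score_t1", "score_t2")
  } else if (measure == "SCI") c("sci_t1", "sci_t2")
  else if (measure == "RRB") c("rrb_t1", "rrb_t2")
  else c("ados_t1", "ados_t2")
}

complete_pairs <- function(cohort, measure = "SRS_total", scale = "T") {
  cols <- measure_columns(measure, scale)
  t1 <- cohort[[cols[1]]]
  t2 <- cohort[[cols[2]]]
  ok <- !is.na(t1) & !is.na(t2)
  out <- tibble(pair_id = cohort$pair_id[ok], t1 = t1[ok], t2 = t2[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}
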