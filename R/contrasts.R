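#' Restrict a cohort to an inclusive age window
#'
#' @param cohort A [cohort_table()].
#' @param age_range Inclusive integer bounds `c(lo, hi)`.
#' @return The filtered `cohort_table`.
#' @export
filter_age <- function(cohort, age_range) {
  stopifnot(inherits(cohort, "cohort_table"), length(age_range) == 2L)
  keep <- cohort$age >= age_range[1] & cohort$age <= age_range[2]
  out <- cohort[keep, , drop = FALSE]
  class(out) <- class(cohort)
  out
}

#' Drop participants with incomplete diagnoses or unscorable scale
#'
#' Retains exactly the participants with full diagnosis data for every
#' required reporter and a scorable scale (no missing item under the
#' `exclude` policy; at least 50% of items under `prorate`). This is the
#' pipeline's analysis-exclusion step.
#'
#' @param cohort A [cohort_table()].
#' @param required_reporters Reporters whose diagnosis flags must all be
#'   present.
#' @param required_scale A [scale_definition()] that must be scorable.
#' @param scale_reporter Reporter whose items are scored (default
#'   `"parent"`).
#' @param missing_policy Scoring policy used to judge scorability.
#' @return The filtered `cohort_table` (possibly empty).
#' @export
exclude_incomplete <- function(cohort, required_reporters, required_scale,
                               scale_reporter = "parent",
                               missing_policy = c("exclude", "prorate")) {
  stopifnot(inherits(cohort, "cohort_table"))
  missing_policy <- match.arg(missing_policy)
  keep <- rep(TRUE, nrow(cohort))
  for (r in required_reporters) {
    cols <- dx_columns(cohort, r)
    if (length(cols) == 0L) stop_scaleval("no diagnosis columns for reporter ", r)
    keep <- keep & stats::complete.cases(cohort[, cols, drop = FALSE])
  }
  sc <- score_scale(cohort, required_scale, scale_reporter,
                    missing_policy = missing_policy)
  keep <- keep & !is.na(sc$raw_score)
  out <- cohort[keep, , drop = FALSE]
  class(out) <- class(cohort)
  out
}

#' Build a case-control contrast from one reporter's diagnoses
#'
#' The three contrast kinds, with depression as the target disorder:
#' \describe{
#'   \item{sensitivity}{positives = participants the reporter flags with
#'     depression (comorbidity allowed); negatives = everyone else,
#'     including participants with no diagnosis.}
#'   \item{specificity}{positives as in sensitivity; negatives =
#'     participants with at least one diagnosis, none of them depression.}
#'   \item{strict_specificity}{positives = depression and no other flag;
#'     negatives as in specificity.}
#' }
#' Hence strict positives are always a subset of specificity positives,
#' and specificity negatives a subset of sensitivity negatives.
#'
#' @param cohort A [cohort_table()].
#' @param kind One of `"sensitivity"`, `"specificity"`,
#'   `"strict_specificity"`.
#' @param reporter Reporter whose diagnosis flags define the contrast.
#' @param target Target disorder column suffix (default `"depression"`).
#' @return An unbalanced `contrast_sample`: list with `kind`, `reporter`,
#'   `positives`, `negatives` (id vectors), `balanced = FALSE`.
#' @examples
#' cohort <- sample_cohort(sim_config(n_participants = 2000, seed = 11))
#' cs <- build_contrast(cohort, "sensitivity", "parent")
#' length(cs$positives); length(cs$negatives)
#' @export
build_contrast <- function(cohort,
                           kind = c("sensitivity", "specificity",
                                    "strict_specificity"),
                           reporter, target = "depression") {
  stopifnot(inherits(cohort, "cohort_table"))
  kind <- match.arg(kind)
  dx_cols <- dx_columns(cohort, reporter)
  if (length(dx_cols) == 0L) {
    stop_scaleval("no diagnosis columns for reporter ", reporter)
  }
  target_col <- paste0(reporter, ".dx_", target)
  if (!target_col %in% dx_cols) {
    stop_scaleval("no ", target, " diagnosis column for reporter ", reporter)
  }
  flags <- as.matrix(cohort[, dx_cols, drop = FALSE]) == 1
  has_target <- flags[, target_col]
  other_cols <- setdiff(dx_cols, target_col)
  has_other <- if (length(other_cols)) {
    rowSums(flags[, other_cols, drop = FALSE]) > 0
  } else rep(FALSE, nrow(cohort))
  has_any <- has_target | has_other

  pos <- switch(kind,
    sensitivity = has_target,
    specificity = has_target,
    strict_specificity = has_target & !has_other)
  neg <- switch(kind,
    sensitivity = !has_target,
    specificity = has_any & !has_target,
    strict_specificity = has_any & !has_target)

  if (!any(pos)) {
    stop_scaleval("contrast unconstructible: no positives for ", kind,
                  " (", reporter, ")")
  }
  if (!any(neg)) {
    stop_scaleval("contrast unconstructible: no negatives for ", kind,
                  " (", reporter, ")")
  }
  structure(
    list(kind = kind, reporter = reporter, target = target,
         positives = cohort$id[pos], negatives = cohort$id[neg],
         target_ratio = NA_real_, seed = NA_integer_,
         balanced = FALSE, ratio_met = NA),
    class = "contrast_sample"
  )
}

#' Balance a contrast to a target positive-case ratio
#'
#' Keeps all positives and draws controls uniformly at random without
#' replacement so positives make up `target_ratio` of the analysis sample:
#' `round(n_pos * (1 - ratio) / ratio)` controls (half away from zero). If
#' the control pool is smaller than that, every control is kept and
#' `ratio_met` is set to `FALSE` (all-controls fallback).
#'
#' @param sample An unbalanced `contrast_sample`.
#' @param target_ratio Target positive fraction in (0, 1); default 0.10.
#' @param seed Integer seed for the control draw.
#' @return The balanced `contrast_sample` (`balanced = TRUE`, `ratio_met`
#'   flag recorded).
#' @examples
#' # 30 positives at a 10% target call for 270 controls
#' @export
balance_to_ratio <- function(sample, target_ratio = 0.10, seed = 1L) {
  stopifnot(inherits(sample, "contrast_sample"))
  if (isTRUE(sample$balanced)) stop_scaleval("sample is already balanced")
  assert_prob(target_ratio, "target_ratio")
  n_pos <- length(sample$positives)
  n_ctrl <- as.integer(round_half_away(n_pos * (1 - target_ratio) /
                                         target_ratio))
  pool <- sample$negatives
  if (length(pool) >= n_ctrl) {
    set.seed(seed)
    sample$negatives <- sample(pool, n_ctrl)
    sample$ratio_met <- TRUE
  } else {
    sample$ratio_met <- FALSE
  }
  sample$target_ratio <- target_ratio
  sample$seed <- as.integer(seed)
  sample$balanced <- TRUE
  sample
}

#' @export
print.contrast_sample <- function(x, ...) {
  cat("Contrast '", x$kind, "' (", x$reporter, " diagnoses): ",
      length(x$positives), " positives vs ", length(x$negatives),
      " negatives\n", sep = "")
  if (isTRUE(x$balanced)) {
    cat("  balanced to target ratio ", x$target_ratio,
        if (isTRUE(x$ratio_met)) " (met)" else " (pool exhausted, not met)",
        ", seed ", x$seed, "\n", sep = "")
  }
  invisible(x)
}

#' Export a contrast as an id/label table
#'
#' @param sample A `contrast_sample`.
#' @return A data.frame with columns `id` and `label` (1 = positive,
#'   0 = control).
#' @export
contrast_labels <- function(sample) {
  stopifnot(inherits(sample, "contrast_sample"))
  data.frame(id = c(sample$positives, sample$negatives),
             label = rep(c(1L, 0L), c(length(sample$positives),
                                      length(sample$negatives))),
             stringsAsFactors = FALSE)
}
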