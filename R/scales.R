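#' Define a questionnaire scale
#'
#' A scale is a named, ordered set of item identifiers summed into a raw
#' score. Items are three-point Likert responses (0/1/2), so a complete
#' score lies in `[0, 2 * length(item_ids)]`. Raw sums are used throughout
#' (no t-score normalisation).
#'
#' @param name Scale name.
#' @param item_ids Non-empty character vector of unique item identifiers
#'   (e.g. `"item_01"`), matched against cohort columns
#'   `reporter.item_id`.
#' @param min_item_value,max_item_value Item response bounds (0 and 2).
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(name, item_ids,
                             min_item_value = 0L, max_item_value = 2L) {
  item_ids <- as.character(item_ids)
  if (length(item_ids) == 0L) stop_scaleval("item_ids must be non-empty")
  if (anyDuplicated(item_ids)) stop_scaleval("item_ids must be unique")
  structure(
    list(name = as.character(name), item_ids = item_ids,
         min_item_value = as.integer(min_item_value),
         max_item_value = as.integer(max_item_value)),
    class = "scale_definition"
  )
}

#' Default 13-item depression scale
#'
#' A DSM-oriented affective-problems style scale of 13 three-point items.
#' The item membership here is a placeholder (`item_01` ... `item_13`,
#' matching the simulator's default items): real instruments define scale
#' membership in their scoring manuals, which is configuration, not code.
#'
#' @return A [scale_definition()] with 13 items.
#' @export
default_depression_scale <- function() {
  scale_definition("dep13", sprintf("item_%02d", 1:13))
}

#' @export
print.scale_definition <- function(x, ...) {
  cat("Scale '", x$name, "': ", length(x$item_ids), " items (",
      x$min_item_value, "-", x$max_item_value, " each)\n", sep = "")
  invisible(x)
}

#' Score a scale for every participant
#'
#' Computes the raw (summed) scale score from one reporter's item
#' responses. Under the default `exclude` policy the score is missing if
#' any item is missing, matching the analysis rule of omitting
#' participants with incomplete scale data. Under `prorate` the score is
#' `round(mean(present items) * n_items)` (half away from zero) when at
#' least 50% of items are present, else missing; proration is an extension
#' for instruments whose manuals tolerate limited missingness, off by
#' default.
#'
#' @param cohort A [cohort_table()].
#' @param scale A [scale_definition()].
#' @param reporter Reporter whose responses are scored (`"parent"` or
#'   `"child"`).
#' @param missing_policy `"exclude"` (default) or `"prorate"`.
#' @return A data.frame of class `scale_scores` with columns `id`,
#'   `raw_score` (integer or NA) and `n_items_missing`.
#' @examples
#' cohort <- sample_cohort(sim_config(n_participants = 50, seed = 3))
#' head(score_scale(cohort, default_depression_scale(), "parent"))
#' @export
score_scale <- function(cohort, scale, reporter,
                        missing_policy = c("exclude", "prorate")) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(scale, "scale_definition"))
  missing_policy <- match.arg(missing_policy)
  if (!reporter %in% c("parent", "child", "clinician")) {
    stop_scaleval("unknown reporter: ", reporter)
  }
  cols <- paste0(reporter, ".", scale$item_ids)
  absent <- setdiff(cols, names(cohort))
  if (length(absent)) {
    stop_scaleval("unknown item id for reporter '", reporter, "': ",
                  sub("^.*\\.", "", absent[1]))
  }
  m <- as.matrix(cohort[, cols, drop = FALSE])
  k <- length(cols)
  n_miss <- rowSums(is.na(m))
  score <- switch(missing_policy,
    exclude = {
      s <- rowSums(m)            # NA when any item missing
      as.integer(s)
    },
    prorate = {
      s <- ifelse(k - n_miss >= k / 2,
                  round_half_away(rowMeans(m, na.rm = TRUE) * k),
                  NA_real_)
      s[n_miss == k] <- NA_real_
      as.integer(s)
    })
  out <- data.frame(id = cohort$id, raw_score = score,
                    n_items_missing = as.integer(n_miss),
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- scale$name
  attr(out, "reporter") <- reporter
  class(out) <- c("scale_scores", "data.frame")
  out
}

#' Pearson correlation between two sets of scale scores
#'
#' Correlates two `scale_scores` tables over participants with both
#' scores present (pairwise complete, matched on `id`).
#'
#' @param a,b `scale_scores` data.frames.
#' @return A list with `r` (Pearson correlation), `p_value` (two-sided),
#'   and `n` (complete pairs used).
#' @export
correlate_scores <- function(a, b) {
  merged <- merge(a[, c("id", "raw_score")], b[, c("id", "raw_score")],
                  by = "id", suffixes = c("_a", "_b"))
  merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  if (nrow(merged) < 3L) {
    stop_scaleval("need at least 3 participants with both scores present")
  }
  if (stats::sd(merged$raw_score_a) == 0 ||
      stats::sd(merged$raw_score_b) == 0) {
    stop_scaleval("zero variance in a score vector; correlation undefined")
  }
  ct <- cor.test(merged$raw_score_a, merged$raw_score_b,
                 method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(merged))
}
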