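check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_scaleval("scores and labels must have equal length")
  }
  if (any(!is.finite(scores))) stop_scaleval("scores must be finite")
  if (!all(labels %in% c(0, 1))) stop_scaleval("labels must be 0/1")
  if (length(unique(labels)) < 2L) {
    stop_scaleval("both classes must be present")
  }
  invisible(NULL)
}

#' Area under the ROC curve (tie-aware)
#'
#' The AUCROC under the Mann-Whitney half-credit convention: the
#' probability that a random positive outscores a random negative, with
#' ties counted 1/2. Computed from mid-ranks, which is exactly equivalent
#' to the exhaustive pairwise comparison and to trapezoidal integration of
#' the tie-aware ROC curve. 0.5 is chance performance; 1.0 a perfect
#' classifier.
#'
#' @param scores Numeric vector of classifier scores (higher = more
#'   case-like).
#' @param labels Binary vector, 1 = positive (case), 0 = negative
#'   (control).
#' @return AUCROC in \[0, 1\].
#' @examples
#' auc(c(3, 1, 2, 4), c(0, 1, 0, 1))  # 0.5
#' @export
auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold (classification rule:
#' score >= threshold predicts positive), plus the (0,0) endpoint. The
#' curve starts at (0,0), ends at (1,1), and its trapezoidal area equals
#' [auc()] exactly.
#'
#' @inheritParams auc
#' @return An object of class `roc_curve`: data.frame with columns
#'   `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # last index of each block of tied scores
  last <- which(c(diff(s) != 0, TRUE))
  tpr <- c(0, cumsum(l)[last] / n1)
  fpr <- c(0, cumsum(1 - l)[last] / n0)
  out <- data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve with", nrow(x), "points; trapezoidal area =",
      format(trapezoid_area(x), digits = 6), "\n")
  invisible(x)
}

trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}

#' Bootstrap distribution of the AUCROC
#'
#' Resamples the data `n_boot` times and returns the AUCROC of each
#' resample. The default `stratified` scheme resamples positives and
#' negatives separately with replacement, preserving class counts — with
#' few cases (e.g. 30 positives at a 10% ratio), joint resampling can
#' produce single-class resamples. The `simple` scheme resamples rows
#' jointly; single-class resamples are redrawn and the redraw count is
#' attached as attribute `n_redrawn`.
#'
#' @inheritParams auc
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param seed Integer seed for the resampling.
#' @param scheme `"stratified"` (default) or `"simple"`.
#' @return Numeric vector of `n_boot` AUC values.
#' @export
bootstrap_auc <- function(scores, labels, n_boot = 1000L, seed = 1L,
                          scheme = c("stratified", "simple")) {
  check_scores_labels(scores, labels)
  scheme <- match.arg(scheme)
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop_scaleval("n_boot must be >= 1")
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  n <- length(scores)
  out <- numeric(n_boot)
  n_redrawn <- 0L
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    if (scheme == "stratified") {
      idx <- c(pos[sample.int(length(pos), replace = TRUE)],
               neg[sample.int(length(neg), replace = TRUE)])
    } else {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (any(labels[idx] == 1) && any(labels[idx] == 0)) break
        n_redrawn <- n_redrawn + 1L
      }
    }
    out[b] <- auc(scores[idx], labels[idx])
  }
  if (scheme == "simple") attr(out, "n_redrawn") <- n_redrawn
  out
}

#' One-sided bootstrap p-value against a fixed AUC threshold
#'
#' For `direction = "below"` (testing that true performance is below the
#' threshold), the p-value is the count of bootstrap AUCs above the
#' threshold divided by `n_boot + 1` (the +1 standing in for the original
#' arrangement of the data). When the count is zero the p-value is floored
#' at `1 / (n_boot + 1)` with `at_floor = TRUE` and displayed as e.g.
#' `"<0.001"` at 1000 bootstraps — none of the bootstrapped values crossed
#' the threshold. `direction = "above"` mirrors the construction with
#' values below the threshold.
#'
#' @param boot Numeric vector of bootstrap AUC values.
#' @param threshold Performance threshold (default 0.8).
#' @param direction Alternative tested: `"below"` or `"above"`.
#' @return A list of class `boot_pvalue`: `p` (numeric, never 0),
#'   `at_floor` (logical), `display` (string, `"<..."` at the floor),
#'   `count`, `denominator`.
#' @export
p_threshold_one_sided <- function(boot, threshold = 0.8,
                                  direction = c("below", "above")) {
  if (length(boot) == 0L) stop_scaleval("empty bootstrap vector")
  direction <- match.arg(direction)
  count <- if (direction == "below") sum(boot > threshold)
           else sum(boot < threshold)
  make_boot_pvalue(count, length(boot) + 1L)
}

#' Two-sided bootstrap p-value against a fixed AUC threshold
#'
#' `p = min(1, 2 * min(share of bootstrap values <= threshold, share >=
#' threshold))`, with both shares over the `n_boot + 1` denominator.
#' Symmetric in direction. Floored at `1 / (n_boot + 1)` (display
#' `"<..."`) when the smaller tail is empty.
#'
#' @inheritParams p_threshold_one_sided
#' @return A `boot_pvalue` list (see [p_threshold_one_sided()]).
#' @export
p_threshold_two_sided <- function(boot, threshold = 0.8) {
  if (length(boot) == 0L) stop_scaleval("empty bootstrap vector")
  denom <- length(boot) + 1L
  k <- min(sum(boot <= threshold), sum(boot >= threshold))
  make_boot_pvalue(2L * k, denom)
}

make_boot_pvalue <- function(count, denom) {
  at_floor <- count == 0L
  p <- min(1, max(count, 1L) / denom)
  display <- if (at_floor) {
    paste0("<", formatC(1 / denom, format = "f", digits = 3))
  } else {
    formatC(p, format = "f", digits = 3)
  }
  structure(list(p = p, at_floor = at_floor, display = display,
                 count = as.integer(count), denominator = as.integer(denom)),
            class = "boot_pvalue")
}

#' @export
print.boot_pvalue <- function(x, ...) {
  cat("bootstrap p = ", x$display, "  (count ", x$count, " / ",
      x$denominator, ")\n", sep = "")
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' The (1-level)/2 and 1-(1-level)/2 quantiles of the bootstrap
#' distribution, under R's default linear-interpolation quantile
#' definition (type 7), fixed for reproducibility.
#'
#' @param boot Numeric vector of bootstrap statistics.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(boot, level = 0.95) {
  if (length(boot) == 0L) stop_scaleval("empty bootstrap vector")
  assert_prob(level, "level")
  alpha <- (1 - level) / 2
  unname(quantile(boot, c(alpha, 1 - alpha), type = 7, names = FALSE))
}

#' Full AUCROC threshold test
#'
#' Point AUCROC, bootstrap distribution, percentile CI, and one- and
#' two-sided bootstrap p-values against a fixed performance threshold —
#' the complete record for one validation analysis row.
#'
#' @inheritParams bootstrap_auc
#' @param threshold Performance threshold the AUC is tested against
#'   (default 0.8, the conventional "excellent performance" bar).
#' @param ci_level Confidence level for the percentile CI (default 0.95).
#' @param direction Direction of the one-sided test (default `"below"`:
#'   the preregistration-style test that performance is below threshold).
#' @return An object of class `roc_result`: list with `auc`,
#'   `n_positives`, `n_negatives`, `n_boot`, `ci_level`, `ci`,
#'   `threshold`, `p_one_sided`, `p_two_sided`, `boot_mean`, `seed`,
#'   `scheme`, and the bootstrap vector `boot`.
#' @examples
#' set.seed(1)
#' scores <- c(rnorm(20, 1.5), rnorm(180))
#' labels <- rep(c(1, 0), c(20, 180))
#' roc_test(scores, labels, n_boot = 200, seed = 9)
#' @export
roc_test <- function(scores, labels, threshold = 0.8, n_boot = 1000L,
                     ci_level = 0.95, seed = 1L,
                     scheme = c("stratified", "simple"),
                     direction = c("below", "above")) {
  scheme <- match.arg(scheme)
  direction <- match.arg(direction)
  assert_prob(threshold, "threshold")
  point <- auc(scores, labels)
  boot <- bootstrap_auc(scores, labels, n_boot = n_boot, seed = seed,
                        scheme = scheme)
  structure(
    list(auc = point,
         n_positives = sum(labels == 1),
         n_negatives = sum(labels == 0),
         n_boot = as.integer(n_boot),
         ci_level = ci_level,
         ci = bootstrap_ci(boot, ci_level),
         threshold = threshold,
         p_one_sided = p_threshold_one_sided(boot, threshold, direction),
         p_two_sided = p_threshold_two_sided(boot, threshold),
         boot_mean = mean(boot),
         seed = as.integer(seed),
         scheme = scheme,
         boot = boot),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("AUCROC threshold test (", x$n_positives, " pos / ",
      x$n_negatives, " neg, threshold ", x$threshold, ")\n", sep = "")
  cat(sprintf("  AUCROC %.3f (%.3f, %.3f)  [%d%% percentile CI, %d bootstraps]\n",
              x$auc, x$ci[1], x$ci[2], round(100 * x$ci_level), x$n_boot))
  cat("  p two-sided: ", x$p_two_sided$display,
      "   p one-sided: ", x$p_one_sided$display, "\n", sep = "")
  invisible(x)
}
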