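#' Confusion matrix at a score cutoff
#'
#' Applies the rule score >= cutoff => predicted positive and tallies the
#' 2x2 confusion matrix with its derived rates.
#'
#' @inheritParams auc
#' @param cutoff Classification cutoff.
#' @return An object of class `confusion_matrix`: list with counts `tp`,
#'   `fp`, `fn`, `tn`, rates `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `youden_j`, and `cutoff`.
#' @export
confusion_at <- function(scores, labels, cutoff) {
  check_scores_labels(scores, labels)
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = sens, specificity = spec,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         youden_j = sens + spec - 1,
         cutoff = cutoff),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix at cutoff", x$cutoff, "(score >= cutoff => positive)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("pred +", "pred -"),
                              c("label +", "label -")))
  print(m)
  cat(sprintf("  sensitivity %.3f  specificity %.3f  ppv %s  npv %s  J %.3f\n",
              x$sensitivity, x$specificity,
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$npv), "NA", sprintf("%.3f", x$npv)),
              x$youden_j))
  invisible(x)
}

#' Optimal diagnostic cutoff (exploratory)
#'
#' Scans every midpoint between adjacent distinct scores, plus -Inf (all
#' predicted positive) and +Inf (all predicted negative), and returns the
#' cutoff maximising the criterion:
#' \describe{
#'   \item{youden}{Youden's J = sensitivity + specificity - 1 (default).}
#'   \item{closest_topleft}{minimal Euclidean distance of the ROC point to
#'     the perfect-classifier corner (0, 1).}
#' }
#' Ties among equally optimal cutoffs are broken towards higher
#' specificity (fewer false positives — screening parsimony); a residual
#' tie goes to the larger cutoff. When the criterion is flat over the
#' entire scan (e.g. constant scores), the degenerate all-positive cutoff
#' (-Inf) is returned. `tie` is `TRUE` whenever more than one scanned
#' cutoff attains the optimum.
#'
#' @inheritParams auc
#' @param criterion `"youden"` or `"closest_topleft"`.
#' @return A list of class `cutoff_result`: `cutoff`, `criterion`,
#'   `value` (criterion value at the optimum; for `closest_topleft` the
#'   distance to (0,1), minimised), `tie`, and the [confusion_at()]
#'   matrix at the chosen cutoff.
#' @examples
#' optimal_cutoff(c(0, 1, 2, 3, 10, 11), c(0, 0, 0, 1, 1, 1))$cutoff  # 2.5
#' @export
optimal_cutoff <- function(scores, labels,
                           criterion = c("youden", "closest_topleft")) {
  check_scores_labels(scores, labels)
  criterion <- match.arg(criterion)
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (head(u, -1) + tail(u, -1)) / 2 else numeric(0)
  cand <- c(-Inf, mids, Inf)
  confs <- lapply(cand, function(ct) confusion_at(scores, labels, ct))
  crit <- vapply(confs, function(cm) {
    if (criterion == "youden") cm$youden_j
    else -sqrt((1 - cm$sensitivity)^2 + (1 - cm$specificity)^2)
  }, numeric(1))
  best <- which(crit >= max(crit) - 1e-12)
  tie <- length(best) > 1L
  if (tie && max(crit) - min(crit) < 1e-12) {
    # criterion flat over the whole scan: degenerate all-positive cutoff
    pick <- 1L
  } else if (tie) {
    spec <- vapply(confs[best], `[[`, numeric(1), "specificity")
    best <- best[spec >= max(spec) - 1e-12]
    pick <- best[length(best)]
  } else {
    pick <- best
  }
  structure(
    list(cutoff = cand[pick], criterion = criterion,
         value = if (criterion == "youden") crit[pick] else -crit[pick],
         tie = tie, confusion = confs[[pick]]),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("Optimal cutoff (", x$criterion, "): ", x$cutoff,
      if (x$tie) "  [tie among scanned cutoffs]" else "", "\n", sep = "")
  print(x$confusion)
  invisible(x)
}
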