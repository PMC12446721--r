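# Independent oracles and fixture builders used across the suite.

# Exhaustive pairwise AUC: P(score_pos > score_neg) + 0.5 P(equal),
# computed by brute force over every positive-negative pair.
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (x in sp) total <- total + sum(x > sn) + 0.5 * sum(x == sn)
  total / (length(sp) * length(sn))
}

# Hanley-McNeil standard error of an empirical AUC.
auc_se <- function(A, n1, n0) {
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n0 - 1) * (q2 - A^2)) /
         (n1 * n0))
}

# Build a small cohort by hand from a list of diagnosis-flag sets, one
# element per participant, e.g. list(c("depression"), character(0), ...).
# Items default to a single all-zero item per reporter so scales score.
make_dx_cohort <- function(dx_sets, reporter = "parent", n_items = 1L) {
  n <- length(dx_sets)
  df <- data.frame(id = sprintf("P%03d", seq_len(n)),
                   age = rep(9L, n), sex = rep(c("F", "M"), length.out = n),
                   stringsAsFactors = FALSE)
  for (j in seq_len(n_items)) {
    df[[sprintf("%s.item_%02d", reporter, j)]] <- rep(0L, n)
  }
  for (d in c("depression", "anxiety", "adhd")) {
    df[[paste0(reporter, ".dx_", d)]] <-
      vapply(dx_sets, function(s) as.integer(d %in% s), integer(1))
  }
  cohort_table(df)
}

# Empty unbalanced contrast with synthetic ids, for balancing arithmetic.
make_contrast <- function(n_pos, n_neg, kind = "sensitivity") {
  structure(
    list(kind = kind, reporter = "parent", target = "depression",
         positives = sprintf("pos%04d", seq_len(n_pos)),
         negatives = sprintf("neg%04d", seq_len(n_neg)),
         target_ratio = NA_real_, seed = NA_integer_,
         balanced = FALSE, ratio_met = NA),
    class = "contrast_sample"
  )
}
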