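#' Configure an end-to-end validation run
#'
#' Bundles everything [run_validation()] needs: a cohort source (an
#' in-memory [cohort_table()], a delimited file path, or a [sim_config()]
#' to simulate from), the contrasts and diagnosis reporters to test, the
#' scales to score, and the analysis parameters (target positive-case
#' ratio, bootstrap iterations, performance threshold, CI level, master
#' seed).
#'
#' @param cohort A `cohort_table`, or a path to a delimited cohort file,
#'   or `NULL` if `sim` is given.
#' @param sim A [sim_config()]; used when `cohort` is `NULL`
#'   (simulate-then-analyze mode).
#' @param age_range Optional inclusive age bounds applied before any
#'   contrast construction.
#' @param reporters Diagnosis reporters to test against (default all
#'   present; specify e.g. `c("parent", "child", "clinician")`).
#' @param contrasts Contrast kinds to run.
#' @param scales Named list of scale specs; each element a list with
#'   `scale` (a [scale_definition()]) and `reporter` (whose items are
#'   scored, default `"parent"`).
#' @param target_ratio Target positive fraction (default 0.10).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param threshold AUCROC performance threshold (default 0.8).
#' @param ci_level CI level (default 0.95).
#' @param missing_policy Scale scoring policy (default `"exclude"`).
#' @param group_by_sex If `TRUE`, run each analysis separately per sex;
#'   default `FALSE` (pooled).
#' @param seed Master seed; every balancing draw and bootstrap derives its
#'   own seed from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, sim = NULL, age_range = NULL,
                       reporters = NULL,
                       contrasts = c("sensitivity", "specificity",
                                     "strict_specificity"),
                       scales = list(dep13 = list(
                         scale = default_depression_scale(),
                         reporter = "parent")),
                       target_ratio = 0.10, n_boot = 1000L,
                       threshold = 0.8, ci_level = 0.95,
                       missing_policy = c("exclude", "prorate"),
                       group_by_sex = FALSE, seed = 1L) {
  if (is.null(cohort) && is.null(sim)) {
    stop_scaleval("provide a cohort (object or path) or a sim config")
  }
  assert_prob(threshold, "threshold")
  assert_prob(target_ratio, "target_ratio")
  missing_policy <- match.arg(missing_policy)
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  for (nm in names(scales)) {
    sp <- scales[[nm]]
    if (!inherits(sp$scale, "scale_definition")) {
      stop_scaleval("scale spec '", nm, "' lacks a scale_definition")
    }
    scales[[nm]]$reporter <- sp$reporter %||% "parent"
  }
  structure(
    list(cohort = cohort, sim = sim, age_range = age_range,
         reporters = reporters, contrasts = contrasts, scales = scales,
         target_ratio = target_ratio, n_boot = as.integer(n_boot),
         threshold = threshold, ci_level = ci_level,
         missing_policy = missing_policy,
         group_by_sex = isTRUE(group_by_sex), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a flat key:value file
#'
#' YAML-compatible flat text. Scalar keys match [run_config()] arguments;
#' `scales` is a map scale-name -> list of item ids (optionally with a
#' `reporter:` sibling key `scale_reporters`); `sim` may hold inline
#' simulator keys as accepted by [read_sim_config()].
#'
#' @param path Path to the configuration file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("age_range", "reporters", "contrasts", "target_ratio",
                "n_boot", "threshold", "ci_level", "missing_policy",
                "group_by_sex", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- unlist(raw[[key]])
  }
  if (!is.null(raw$cohort)) args$cohort <- raw$cohort
  if (!is.null(raw$sim)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    yaml::write_yaml(raw$sim, tmp)
    args$sim <- read_sim_config(tmp)
  }
  if (!is.null(raw$scales)) {
    reps <- raw$scale_reporters %||% list()
    args$scales <- lapply(seq_along(raw$scales), function(i) {
      nm <- names(raw$scales)[i]
      list(scale = scale_definition(nm, unlist(raw$scales[[i]])),
           reporter = reps[[nm]] %||% "parent")
    })
    names(args$scales) <- names(raw$scales)
  }
  do.call(run_config, args)
}

resolve_cohort <- function(config) {
  if (!is.null(config$cohort)) {
    if (inherits(config$cohort, "cohort_table")) return(config$cohort)
    return(read_cohort(config$cohort))
  }
  sample_cohort(config$sim)
}

#' Run the full scale-validation analysis
#'
#' For every combination of contrast kind, diagnosis reporter and scale
#' (and sex group, if requested): applies the age filter, drops
#' participants with incomplete diagnoses or unscorable scale, builds the
#' contrast, balances controls to the target ratio, scores the scale, and
#' runs the bootstrap AUCROC threshold test. Unconstructible contrasts
#' (e.g. no comorbidity-free cases for strict specificity) yield an NA row
#' carrying the reason, not an error, so multi-contrast runs complete.
#'
#' Deterministic given `config$seed`: each analysis row derives its
#' balancing and bootstrap seeds from the master seed and the row index.
#' A sidecar log (attribute `"log"`) records cohort provenance, every
#' exclusion count and every seed consumed.
#'
#' @param config A [run_config()].
#' @return A data.frame of class `validation_report`, one row per
#'   analysis: `contrast`, `reporter`, `scale`, `group`, `n_pos`,
#'   `n_neg`, `ratio_met`, `threshold`, `auc`, `ci_low`, `ci_high`,
#'   `p_one_sided`, `p_one_floor`, `p_two_sided`, `p_two_floor`, `note`.
#' @examples
#' cfg <- run_config(sim = sim_config(n_participants = 1500, seed = 5),
#'                   reporters = "parent", contrasts = "sensitivity",
#'                   n_boot = 100, seed = 5)
#' run_validation(cfg)
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note_log <- function(...) log <<- c(log, paste0(...))

  cohort <- resolve_cohort(config)
  note_log("cohort: ", nrow(cohort), " participants",
           if (!is.null(config$sim) && is.null(config$cohort))
             paste0(" (simulated, seed ", config$sim$seed, ")") else "")

  if (!is.null(config$age_range)) {
    n0 <- nrow(cohort)
    cohort <- filter_age(cohort, config$age_range)
    note_log("age filter ", config$age_range[1], "-", config$age_range[2],
             ": excluded ", n0 - nrow(cohort), ", retained ", nrow(cohort))
  }

  reporters <- config$reporters %||% cohort_reporters(cohort)
  groups <- if (config$group_by_sex) c("F", "M") else "pooled"

  rows <- list()
  i_row <- 0L
  for (grp in groups) {
    sub <- if (grp == "pooled") cohort else {
      out <- cohort[cohort$sex == grp, , drop = FALSE]
      class(out) <- class(cohort)
      out
    }
    for (sc_name in names(config$scales)) {
      sp <- config$scales[[sc_name]]
      for (rep in reporters) {
        base <- exclude_incomplete(sub, rep, sp$scale,
                                   scale_reporter = sp$reporter,
                                   missing_policy = config$missing_policy)
        note_log(sc_name, " x ", rep, " (", grp, "): excluded ",
                 nrow(sub) - nrow(base), " incomplete, analysable ",
                 nrow(base))
        for (kind in config$contrasts) {
          i_row <- i_row + 1L
          row <- data.frame(
            contrast = kind, reporter = rep, scale = sc_name, group = grp,
            n_pos = NA_integer_, n_neg = NA_integer_, ratio_met = NA,
            threshold = config$threshold, auc = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_,
            p_one_sided = NA_real_, p_one_floor = NA,
            p_two_sided = NA_real_, p_two_floor = NA,
            note = "", stringsAsFactors = FALSE)
          cs <- tryCatch(build_contrast(base, kind, rep),
                         error = function(e) conditionMessage(e))
          if (is.character(cs)) {
            row$note <- cs
            note_log("row ", i_row, " (", kind, "): ", cs)
            rows[[i_row]] <- row
            next
          }
          bal_seed <- stage_seed(config$seed, 100L + i_row)
          cs <- balance_to_ratio(cs, config$target_ratio, seed = bal_seed)
          note_log("row ", i_row, " (", kind, "): ",
                   length(cs$positives), " pos / ", length(cs$negatives),
                   " neg, balance seed ", bal_seed,
                   if (!cs$ratio_met) " [ratio not met: all controls kept]"
                   else "")
          scores_tab <- score_scale(base, sp$scale, sp$reporter,
                                    missing_policy = config$missing_policy)
          lab <- contrast_labels(cs)
          m <- merge(lab, scores_tab[, c("id", "raw_score")], by = "id")
          boot_seed <- stage_seed(config$seed, 500L + i_row)
          res <- roc_test(m$raw_score, m$label,
                          threshold = config$threshold,
                          n_boot = config$n_boot,
                          ci_level = config$ci_level,
                          seed = boot_seed)
          note_log("row ", i_row, ": bootstrap seed ", boot_seed)
          row$n_pos <- res$n_positives
          row$n_neg <- res$n_negatives
          row$ratio_met <- cs$ratio_met
          row$auc <- res$auc
          row$ci_low <- res$ci[1]
          row$ci_high <- res$ci[2]
          row$p_one_sided <- res$p_one_sided$p
          row$p_one_floor <- res$p_one_sided$at_floor
          row$p_two_sided <- res$p_two_sided$p
          row$p_two_floor <- res$p_two_sided$at_floor
          rows[[i_row]] <- row
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "log") <- log
  attr(report, "n_boot") <- config$n_boot
  class(report) <- c("validation_report", "data.frame")
  report
}

#' Retrieve the sidecar log of a validation run
#' @param report A `validation_report`.
#' @return Character vector of log lines (exclusion counts, seeds).
#' @export
validation_log <- function(report) attr(report, "log")

format_report_p <- function(p, floor) {
  ifelse(is.na(p), "NA",
         ifelse(floor, paste0("<", formatC(p, format = "f", digits = 3)),
                formatC(p, format = "f", digits = 3)))
}

#' Render a validation report as text and a delimited file
#'
#' The text rendering mirrors a results-table layout: one row per
#' analysis with class sizes, threshold, `AUCROC (CI low, CI high)` at 3
#' decimals, and one-/two-sided p-values with the `"<"` floor notation
#' preserved. The delimited file keeps full numeric precision plus the
#' floor-flag columns so it round-trips through [read_report()].
#'
#' @param report A `validation_report` (may have zero rows).
#' @param file Optional path for the delimited output.
#' @param sep Field separator for the file (default tab).
#' @return Character vector of text lines, invisibly; printed when called
#'   interactively via `print`.
#' @export
render_report <- function(report, file = NULL, sep = "\t") {
  stopifnot(inherits(report, "validation_report"))
  header <- paste("Contrast", "Reporter", "Scale", "Group", "N Pos",
                  "N Neg", "Thresh.", "AUCROC (95% CI)", "p (two-sided)",
                  "p (one-sided)", "Note", sep = " | ")
  lines <- header
  if (nrow(report)) {
    fmt_num <- function(x) ifelse(is.na(x), "NA",
                                  formatC(x, format = "f", digits = 3))
    body <- paste(
      report$contrast, report$reporter, report$scale, report$group,
      ifelse(is.na(report$n_pos), "NA", report$n_pos),
      ifelse(is.na(report$n_neg), "NA", report$n_neg),
      fmt_num(report$threshold),
      ifelse(is.na(report$auc), "NA",
             sprintf("%s (%s, %s)", fmt_num(report$auc),
                     fmt_num(report$ci_low), fmt_num(report$ci_high))),
      format_report_p(report$p_two_sided, report$p_two_floor),
      format_report_p(report$p_one_sided, report$p_one_floor),
      report$note, sep = " | ")
    lines <- c(lines, body)
  }
  if (!is.null(file)) {
    out <- as.data.frame(report)
    write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                file, sep = sep, na = "NA", row.names = FALSE,
                quote = TRUE)
  }
  invisible(lines)
}

#' @rdname render_report
#' @param path Path of a file written by [render_report()].
#' @export
read_report <- function(path, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, na.strings = "NA",
                   stringsAsFactors = FALSE, quote = "\"",
                   check.names = TRUE)
  df$note[is.na(df$note)] <- ""
  class(df) <- c("validation_report", "data.frame")
  df
}

#' @export
print.validation_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
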