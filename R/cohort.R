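#' Construct / validate a cohort table
#'
#' A cohort table is a data.frame with one row per participant and columns
#' `id` (unique strings), `age` (years), `sex` (`"F"`/`"M"`), ordinal item
#' responses `reporter.item_NN` in \{0, 1, 2\} (NA = missing), and binary
#' diagnosis flags `reporter.dx_DISORDER`. Recognised reporters are
#' `parent`, `child` and `clinician`.
#'
#' @param df A data.frame following the column naming convention.
#' @return The validated data.frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("id", "age", "sex") %in% names(df))) {
    stop_scaleval("cohort needs columns id, age, sex")
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop_scaleval("duplicate participant id: ",
                  df$id[anyDuplicated(df$id)][1])
  }
  extra <- setdiff(names(df), c("id", "age", "sex"))
  known <- grepl("^(parent|child|clinician)\\.(item_[A-Za-z0-9_]+|dx_[A-Za-z0-9_]+)$",
                 extra)
  if (any(!known)) {
    stop_scaleval("unknown reporter column: ", extra[!known][1])
  }
  for (col in grep("\\.item_", names(df), value = TRUE)) {
    v <- df[[col]]
    if (!all(is.na(v) | v %in% c(0, 1, 2))) {
      stop_scaleval("malformed ordinal value in ", col,
                    ": responses must be 0, 1 or 2")
    }
    df[[col]] <- as.integer(v)
  }
  for (col in grep("\\.dx_", names(df), value = TRUE)) {
    v <- df[[col]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop_scaleval("diagnosis flags in ", col, " must be 0/1")
    }
    df[[col]] <- as.integer(v)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x), "participants,",
      length(grep("\\.item_", names(x))), "item columns,",
      length(grep("\\.dx_", names(x))), "diagnosis columns\n")
  if (nrow(x)) {
    cat("  reporters:", paste(cohort_reporters(x), collapse = ", "), "\n")
    cat("  ages:", min(x$age), "-", max(x$age), "\n")
  }
  invisible(x)
}

#' Reporters present in a cohort
#' @param cohort A `cohort_table`.
#' @return Character vector of reporter prefixes found among the columns.
#' @export
cohort_reporters <- function(cohort) {
  pref <- sub("\\..*$", "", grep("\\.", names(cohort), value = TRUE))
  intersect(c("parent", "child", "clinician"), unique(pref))
}

item_columns <- function(cohort, reporter) {
  grep(paste0("^", reporter, "\\.item_"), names(cohort), value = TRUE)
}

dx_columns <- function(cohort, reporter) {
  grep(paste0("^", reporter, "\\.dx_"), names(cohort), value = TRUE)
}

#' Simulate a multi-informant cohort
#'
#' Draws a cohort from the latent-liability model described in
#' [sim_config()]:
#' \enumerate{
#'   \item true liabilities `L` ~ multivariate standard normal with the
#'     configured comorbidity correlation;
#'   \item perceived liabilities per reporter
#'     `P = rho * L + sqrt(1 - rho^2) * eps`, `eps` standard normal;
#'   \item a reporter flags disorder `d` when `P_d` exceeds
#'     `qnorm(1 - prevalence_d)`;
#'   \item clinician consensus
#'     `C = w * P_parent + (1 - w) * P_child + noise`, thresholded at the
#'     same quantile;
#'   \item parent (child) item responses from a graded cumulative-logistic
#'     model on the parent's (child's) perceived depression liability:
#'     `P(response >= k) = plogis(a_j * (P - b_jk))`.
#' }
#' All sub-draws are seeded from `config$seed` through a fixed
#' stage-offset scheme, so the cohort is fully reproducible and any stage
#' can be re-derived in isolation. Sex is assigned 50/50 independently of
#' liability; age is uniform over the configured range.
#'
#' @param config A [sim_config()] object.
#' @return A [cohort_table()] with parent/child items, parent/child/
#'   clinician diagnosis flags.
#' @examples
#' cohort <- sample_cohort(sim_config(n_participants = 200, seed = 7))
#' mean(cohort$parent.dx_depression)
#' @export
sample_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_scaleval("config must be a sim_config object")
  }
  n <- config$n_participants
  dis <- sim_disorders()
  prev <- config$disorder_prevalences
  tau <- qnorm(1 - prev)
  seed <- config$seed

  # stage 1: true liabilities
  set.seed(stage_seed(seed, 1L))
  L <- MASS::mvrnorm(n, mu = rep(0, 3), Sigma = config$liability_correlations)
  if (n == 1L) L <- matrix(L, nrow = 1L)
  colnames(L) <- dis

  # stages 2-3: reporter perceptions
  perceived <- list()
  for (i in seq_along(c("parent", "child"))) {
    r <- c("parent", "child")[i]
    rho <- config$informant_fidelities[[r]]
    set.seed(stage_seed(seed, 1L + i))
    eps <- matrix(rnorm(n * 3), n, 3)
    perceived[[r]] <- rho * L + sqrt(1 - rho^2) * eps
    colnames(perceived[[r]]) <- dis
  }

  # stage 4: clinician consensus
  w <- config$clinician_parent_weight
  set.seed(stage_seed(seed, 4L))
  cl_noise <- matrix(rnorm(n * 3, sd = config$clinician_noise_sd), n, 3)
  consensus <- w * perceived$parent + (1 - w) * perceived$child + cl_noise
  colnames(consensus) <- dis

  dx <- list(parent = sweep(perceived$parent, 2, tau, ">"),
             child = sweep(perceived$child, 2, tau, ">"),
             clinician = sweep(consensus, 2, tau, ">"))

  # stages 5-6: graded item responses from perceived depression liability
  ip <- config$item_params
  items <- list()
  for (i in seq_along(c("parent", "child"))) {
    r <- c("parent", "child")[i]
    p_dep <- perceived[[r]][, "depression"]
    set.seed(stage_seed(seed, 4L + i))
    u <- matrix(runif(n * nrow(ip)), n, nrow(ip))
    resp <- matrix(0L, n, nrow(ip))
    for (j in seq_len(nrow(ip))) {
      p_ge1 <- plogis(ip$loading[j] * (p_dep - ip$b1[j]))
      p_ge2 <- plogis(ip$loading[j] * (p_dep - ip$b2[j]))
      resp[, j] <- (u[, j] <= p_ge1) + (u[, j] <= p_ge2)
    }
    colnames(resp) <- paste0(r, ".", ip$item)
    items[[r]] <- resp
  }

  # stage 7: demographics
  set.seed(stage_seed(seed, 7L))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)

  # stage 8: completely-at-random item missingness
  if (config$missing_rate > 0) {
    set.seed(stage_seed(seed, 8L))
    for (r in c("parent", "child")) {
      drop <- matrix(runif(n * nrow(ip)) < config$missing_rate,
                     n, nrow(ip))
      items[[r]][drop] <- NA_integer_
    }
  }

  df <- data.frame(
    id = sprintf("S%06d", seq_len(n)),
    age = age,
    sex = sex,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(items$parent), as.data.frame(items$child))
  for (r in names(dx)) {
    flags <- as.data.frame(ifelse(dx[[r]], 1L, 0L))
    names(flags) <- paste0(r, ".dx_", dis)
    df <- cbind(df, flags)
  }
  cohort_table(df)
}

#' Write / read a cohort as delimited text
#'
#' Delimited text with a header row, missing values marked `NA`, columns
#' named per the `reporter.item_NN` / `reporter.dx_DISORDER` convention.
#' `read_cohort(write_cohort(x))` is an identity, including missing-value
#' markers.
#'
#' @param cohort A `cohort_table`.
#' @param path Destination / source file path.
#' @param sep Field separator: `","` (default) or `"\t"`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `cohort_table`.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "cohort_table"))
  write.table(cohort, path, sep = sep, na = "NA",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep, na.strings = "NA",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = NA)
  if (nrow(df)) df$id <- as.character(df$id)
  else df$id <- character(0)
  cohort_table(df)
}
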