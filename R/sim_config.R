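#' Disorders modelled by the cohort simulator
#'
#' @return Character vector `c("depression", "anxiety", "adhd")`.
#' @export
sim_disorders <- function() c("depression", "anxiety", "adhd")

#' Default graded-response item parameters
#'
#' Fixed parameters for a 13-item scale: discrimination (loading) `a` and
#' two ordered thresholds `b1 < b2` per item, giving three ordinal response
#' levels (0/1/2). Loadings span 1.0--2.5 and thresholds sit in the upper
#' tail of the liability scale, so that in a general-population cohort most
#' responses are 0 and the summed score is right-skewed — the shape raw
#' problem-checklist scores take in unselected samples.
#'
#' @param n_items Number of items (default 13).
#' @return A data.frame with columns `item`, `loading`, `b1`, `b2`.
#' @export
default_item_params <- function(n_items = 13L) {
  n_items <- as.integer(n_items)
  if (n_items < 1L) stop_scaleval("n_items must be >= 1")
  idx <- seq_len(n_items)
  data.frame(
    item = sprintf("item_%02d", idx),
    loading = 1.0 + 1.5 * (idx - 1) %% 5 / 4,
    b1 = 0.6 + 0.9 * ((idx - 1) %% 7) / 6,
    b2 = 1.6 + 0.9 * ((idx - 1) %% 7) / 6,
    stringsAsFactors = FALSE
  )
}

#' Configure the latent-liability cohort simulator
#'
#' Defines the generative model for a synthetic multi-informant cohort.
#' Each participant has a true liability vector for depression, anxiety and
#' ADHD, drawn from a multivariate standard normal with the given
#' correlation (comorbidity) structure. Each reporter (parent, child)
#' perceives a noisy version of each liability, with fidelity `rho` (the
#' correlation between true and perceived liability); a diagnosis is
#' flagged when perceived liability exceeds the quantile implied by the
#' disorder's prevalence (liability-threshold model). A clinician consensus
#' combines parent and child perceptions with weight
#' `clinician_parent_weight` plus independent noise. Ordinal item responses
#' (0/1/2) follow a graded cumulative-logistic model on the reporter's
#' perceived depression liability.
#'
#' The defaults emulate a general-population developmental cohort: low
#' depression prevalence, strong parent fidelity, weak child fidelity
#' (hence rare concordant parent-child positives), and moderate comorbidity
#' among the three disorders.
#'
#' @param n_participants Cohort size.
#' @param disorder_prevalences Named fractions in (0,1) for
#'   `depression`, `anxiety`, `adhd`.
#' @param liability_correlations Symmetric positive-semidefinite 3x3
#'   correlation matrix (unit diagonal), rows/columns ordered as
#'   [sim_disorders()].
#' @param informant_fidelities Named values in \[0,1\] for `parent` and
#'   `child`: correlation between true and perceived liability.
#' @param clinician_parent_weight Weight in \[0,1\] on the parent's
#'   perceived liability in the clinician consensus.
#' @param clinician_noise_sd Non-negative SD of the clinician's own noise.
#' @param item_params Data frame as from [default_item_params()]:
#'   per item a positive `loading` and ordered thresholds `b1 < b2`.
#' @param age_range Inclusive integer age bounds, e.g. `c(8, 11)`.
#' @param missing_rate Completely-at-random per-item missingness rate
#'   in \[0,1) (default 0).
#' @param seed Integer master seed; all sub-draws derive from it via a
#'   fixed stage-offset scheme.
#' @return An object of class `sim_config`.
#' @seealso [sample_cohort()]
#' @examples
#' cfg <- sim_config(n_participants = 500, seed = 42)
#' cohort <- sample_cohort(cfg)
#' @export
sim_config <- function(n_participants = 6000L,
                       disorder_prevalences = c(depression = 0.02,
                                                anxiety = 0.06,
                                                adhd = 0.07),
                       liability_correlations = default_liability_correlations(),
                       informant_fidelities = c(parent = 0.9, child = 0.3),
                       clinician_parent_weight = 0.7,
                       clinician_noise_sd = 0.3,
                       item_params = default_item_params(),
                       age_range = c(8L, 11L),
                       missing_rate = 0,
                       seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L) {
    stop_scaleval("n_participants must be a positive integer")
  }

  dis <- sim_disorders()
  if (!all(dis %in% names(disorder_prevalences))) {
    stop_scaleval("disorder_prevalences must name all of: ",
                  paste(dis, collapse = ", "))
  }
  disorder_prevalences <- disorder_prevalences[dis]
  if (any(disorder_prevalences <= 0 | disorder_prevalences >= 1)) {
    stop_scaleval("every prevalence must lie strictly inside (0, 1)")
  }

  R <- as.matrix(liability_correlations)
  if (!identical(dim(R), c(3L, 3L)) || any(abs(R - t(R)) > 1e-8)) {
    stop_scaleval("liability_correlations must be a symmetric 3x3 matrix")
  }
  if (any(abs(diag(R) - 1) > 1e-8)) {
    stop_scaleval("liability_correlations must have unit diagonal")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop_scaleval("liability_correlations is not positive semidefinite")
  }
  dimnames(R) <- list(dis, dis)

  if (!all(c("parent", "child") %in% names(informant_fidelities))) {
    stop_scaleval("informant_fidelities must name 'parent' and 'child'")
  }
  informant_fidelities <- informant_fidelities[c("parent", "child")]
  if (any(informant_fidelities < 0 | informant_fidelities > 1)) {
    stop_scaleval("informant fidelities must lie in [0, 1]")
  }

  assert_prob(clinician_parent_weight, "clinician_parent_weight",
              open = FALSE)
  if (!is.numeric(clinician_noise_sd) || clinician_noise_sd < 0) {
    stop_scaleval("clinician_noise_sd must be non-negative")
  }

  item_params <- as.data.frame(item_params)
  need <- c("item", "loading", "b1", "b2")
  if (!all(need %in% names(item_params)) || nrow(item_params) < 1L) {
    stop_scaleval("item_params needs columns item, loading, b1, b2")
  }
  if (anyDuplicated(item_params$item)) {
    stop_scaleval("item identifiers must be unique")
  }
  if (any(item_params$loading <= 0)) {
    stop_scaleval("item loadings must be positive")
  }
  if (any(item_params$b1 >= item_params$b2)) {
    stop_scaleval("item thresholds must be strictly ordered (b1 < b2)")
  }

  age_range <- as.integer(age_range)
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    stop_scaleval("age_range must be inclusive integer bounds c(lo, hi)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_scaleval("missing_rate must lie in [0, 1)")
  }

  structure(
    list(
      n_participants = n_participants,
      disorder_prevalences = disorder_prevalences,
      liability_correlations = R,
      informant_fidelities = informant_fidelities,
      clinician_parent_weight = clinician_parent_weight,
      clinician_noise_sd = clinician_noise_sd,
      item_params = item_params,
      age_range = age_range,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default comorbidity (liability correlation) structure
#'
#' Moderate positive correlations among depression, anxiety and ADHD
#' liabilities, strongest for depression-anxiety.
#'
#' @return A 3x3 correlation matrix.
#' @export
default_liability_correlations <- function() {
  R <- matrix(c(1, 0.45, 0.25,
                0.45, 1, 0.30,
                0.25, 0.30, 1), 3, 3)
  dimnames(R) <- list(sim_disorders(), sim_disorders())
  R
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Cohort simulator configuration\n")
  cat("  participants:", x$n_participants,
      " ages:", paste(x$age_range, collapse = "-"),
      " seed:", x$seed, "\n")
  cat("  prevalences: ",
      paste(sprintf("%s=%.3f", names(x$disorder_prevalences),
                    x$disorder_prevalences), collapse = ", "), "\n")
  cat("  informant fidelities: ",
      paste(sprintf("%s=%.2f", names(x$informant_fidelities),
                    x$informant_fidelities), collapse = ", "), "\n")
  cat("  clinician: parent weight", x$clinician_parent_weight,
      ", noise sd", x$clinician_noise_sd, "\n")
  cat("  items:", nrow(x$item_params),
      " missing rate:", x$missing_rate, "\n")
  invisible(x)
}

#' Read a simulator configuration from a flat key:value file
#'
#' The file is YAML-compatible flat `key: value` text. Recognised keys
#' match the arguments of [sim_config()]; `disorder_prevalences`,
#' `informant_fidelities` and `age_range` are given as nested keys or
#' two-element lists, and `liability_correlations` as the lower-triangle
#' entries `cor_dep_anx`, `cor_dep_adhd`, `cor_anx_adhd`.
#'
#' @param path Path to the configuration file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("n_participants", "clinician_parent_weight",
                "clinician_noise_sd", "missing_rate", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$disorder_prevalences)) {
    args$disorder_prevalences <- unlist(raw$disorder_prevalences)
  }
  if (!is.null(raw$informant_fidelities)) {
    args$informant_fidelities <- unlist(raw$informant_fidelities)
  }
  if (!is.null(raw$age_range)) args$age_range <- unlist(raw$age_range)
  if (!is.null(raw$n_items)) {
    args$item_params <- default_item_params(raw$n_items)
  }
  cors <- c("cor_dep_anx", "cor_dep_adhd", "cor_anx_adhd")
  if (any(cors %in% names(raw))) {
    R <- default_liability_correlations()
    if (!is.null(raw$cor_dep_anx)) R[1, 2] <- R[2, 1] <- raw$cor_dep_anx
    if (!is.null(raw$cor_dep_adhd)) R[1, 3] <- R[3, 1] <- raw$cor_dep_adhd
    if (!is.null(raw$cor_anx_adhd)) R[2, 3] <- R[3, 2] <- raw$cor_anx_adhd
    args$liability_correlations <- R
  }
  do.call(sim_config, args)
}
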