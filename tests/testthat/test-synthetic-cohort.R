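test_that("sim_config rejects invalid generative parameters", {
  expect_error(sim_config(disorder_prevalences = c(depression = 0,
                                                   anxiety = 0.05,
                                                   adhd = 0.05)),
               "strictly inside")
  bad_R <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(sim_config(liability_correlations = bad_R),
               "positive semidefinite")
  expect_error(sim_config(liability_correlations = diag(3) * 2),
               "unit diagonal")
  ip <- default_item_params()
  ip$b2[3] <- ip$b1[3]
  expect_error(sim_config(item_params = ip), "strictly ordered")
  expect_error(sim_config(informant_fidelities = c(parent = 1.2, child = 0.3)),
               "fidelities")
})

test_that("cohorts are deterministic given the seed", {
  cfg <- sim_config(n_participants = 300, seed = 123)
  expect_identical(sample_cohort(cfg), sample_cohort(cfg))
  other <- sample_cohort(sim_config(n_participants = 300, seed = 124))
  expect_false(identical(sample_cohort(cfg), other))
})

test_that("perfect fidelity collapses all informants onto one diagnosis", {
  cfg <- sim_config(n_participants = 1500,
                    informant_fidelities = c(parent = 1, child = 1),
                    clinician_noise_sd = 0, seed = 8)
  cohort <- sample_cohort(cfg)
  for (d in sim_disorders()) {
    expect_identical(cohort[[paste0("parent.dx_", d)]],
                     cohort[[paste0("child.dx_", d)]])
    expect_identical(cohort[[paste0("parent.dx_", d)]],
                     cohort[[paste0("clinician.dx_", d)]])
  }
  tab <- cross_tabulate(cohort$parent.dx_depression,
                        cohort$child.dx_depression)
  expect_equal(tab[1, 2] + tab[2, 1], 0)  # off-diagonals empty
})

test_that("diagnosis rates converge to the configured prevalences", {
  cfg <- sim_config(n_participants = 10000, seed = 31)
  cohort <- sample_cohort(cfg)
  for (d in sim_disorders()) {
    p <- cfg$disorder_prevalences[[d]]
    se <- sqrt(p * (1 - p) / 10000)
    for (rep in c("parent", "child")) {
      expect_lt(abs(mean(cohort[[paste0(rep, ".dx_", d)]]) - p), 3 * se)
    }
  }
})

test_that("identity liability correlations give comorbidity OR near 1", {
  cfg <- sim_config(n_participants = 10000,
                    liability_correlations = diag(3), seed = 47)
  cohort <- sample_cohort(cfg)
  pairs <- list(c("depression", "anxiety"), c("depression", "adhd"),
                c("anxiety", "adhd"))
  for (pr in pairs) {
    a <- cohort[[paste0("parent.dx_", pr[1])]]
    b <- cohort[[paste0("parent.dx_", pr[2])]]
    tab <- table(factor(a, 0:1), factor(b, 0:1)) + 0.5  # Haldane correction
    log_or <- log(tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1]))
    se <- sqrt(sum(1 / tab))
    expect_lt(abs(log_or), 3 * se)
  }
})

test_that("parent-scale discrimination is monotone in parent fidelity", {
  scale_auc <- function(rho, dx_reporter) {
    cfg <- sim_config(n_participants = 5000,
                      informant_fidelities = c(parent = rho, child = 1),
                      disorder_prevalences = c(depression = 0.05,
                                               anxiety = 0.06, adhd = 0.07),
                      seed = 90)
    cohort <- sample_cohort(cfg)
    sc <- score_scale(cohort, default_depression_scale(), "parent")
    res <- auc(sc$raw_score, cohort[[paste0(dx_reporter, ".dx_depression")]])
    c(res, auc_se(res, sum(cohort[[paste0(dx_reporter, ".dx_depression")]]),
                  sum(1 - cohort[[paste0(dx_reporter, ".dx_depression")]])))
  }
  rhos <- c(0.2, 0.5, 0.9)
  # against the parent's own diagnosis both score and flag condition on the
  # same perceived liability, so the AUC cannot decrease with fidelity
  # beyond Monte-Carlo noise: non-decreasing within 2 SEs
  own <- vapply(rhos, scale_auc, numeric(2), dx_reporter = "parent")
  expect_true(all(diff(own[1, ]) > -2 * own[2, -1]))
  # against a perfect-fidelity informant (diagnosis thresholded on the true
  # liability itself) discrimination strictly increases with fidelity
  truth <- vapply(rhos, scale_auc, numeric(2), dx_reporter = "child")
  expect_true(all(diff(truth[1, ]) > 0))
})

test_that("perfect-fidelity liability scores separate their own diagnosis", {
  # with rho = 1 the perceived liability equals the true liability that is
  # thresholded into the diagnosis, so discrimination is exact
  cfg <- sim_config(n_participants = 4000,
                    informant_fidelities = c(parent = 1, child = 1),
                    clinician_noise_sd = 0,
                    item_params = default_item_params(13),
                    seed = 55)
  cohort <- sample_cohort(cfg)
  # reconstruct the perceived liability via the seed-splitting scheme is
  # internal; instead use a very discriminative summed score as proxy and
  # check the diagnosis flags are internally consistent with thresholding:
  # every parent-diagnosed participant must outrank chance on the scale
  sc <- score_scale(cohort, default_depression_scale(), "parent")
  a <- auc(sc$raw_score, cohort$parent.dx_depression)
  expect_gt(a, 0.95)
})

test_that("cohort files round-trip exactly, including missing markers", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  # empty cohort -> header-only file -> empty cohort
  empty <- cohort_table(data.frame(id = character(0), age = integer(0),
                                   sex = character(0)))
  write_cohort(empty, tmp)
  expect_equal(nrow(read_cohort(tmp)), 0L)

  # one missing item response survives the round trip
  one <- make_dx_cohort(list("depression", character(0)), n_items = 2)
  one$parent.item_02[1] <- NA_integer_
  write_cohort(one, tmp)
  expect_identical(as.data.frame(read_cohort(tmp)), as.data.frame(one))

  # seeded 100-row cohort, field-by-field equality, both separators
  cohort <- sample_cohort(sim_config(n_participants = 100,
                                     missing_rate = 0.05, seed = 12))
  for (sep in c(",", "\t")) {
    write_cohort(cohort, tmp, sep = sep)
    back <- read_cohort(tmp, sep = sep)
    expect_identical(as.data.frame(back), as.data.frame(cohort))
  }
})

test_that("malformed cohort files are rejected with clear errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,age,sex,parent.item_01,parent.dx_depression",
               "A,9,F,3,0"), tmp)      # ordinal value out of range
  expect_error(read_cohort(tmp), "malformed ordinal")
  writeLines(c("id,age,sex,parent.item_01,parent.dx_depression",
               "A,9,F,1,0", "A,10,M,0,1"), tmp)
  expect_error(read_cohort(tmp), "duplicate")
  writeLines(c("id,age,sex,teacher.item_01", "A,9,F,1"), tmp)
  expect_error(read_cohort(tmp), "unknown reporter")
})

test_that("flat key:value simulator configs are honoured", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_participants: 250",
               "seed: 77",
               "missing_rate: 0.1",
               "cor_dep_anx: 0.2",
               "disorder_prevalences:",
               "  depression: 0.03",
               "  anxiety: 0.05",
               "  adhd: 0.05",
               "informant_fidelities:",
               "  parent: 0.8",
               "  child: 0.4"), tmp)
  cfg <- read_sim_config(tmp)
  expect_equal(cfg$n_participants, 250L)
  expect_equal(cfg$seed, 77L)
  expect_equal(cfg$missing_rate, 0.1)
  expect_equal(cfg$liability_correlations[1, 2], 0.2)
  expect_equal(unname(cfg$informant_fidelities["parent"]), 0.8)
  cohort <- sample_cohort(cfg)
  expect_equal(nrow(cohort), 250L)
  expect_true(anyNA(cohort$parent.item_01) || anyNA(cohort$child.item_01))
})
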