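test_that("the published equation reproduces hand arithmetic on printed medians", {
  m <- published_model()
  expect_equal(m$genes, c("AMPD3", "NRN1", "TBX15"))
  expect_equal(unname(m$beta), c(-0.47, -0.41, -0.57))
  expect_equal(m$epsilon, 6.38)
  expect_equal(m$cutoff, 0.73)

  oc <- risk_score(m, c(AMPD3 = 2.0, NRN1 = 0.4, TBX15 = 4.9))
  nl <- risk_score(m, c(AMPD3 = 3.6, NRN1 = 4.2, TBX15 = 7.6))
  expect_equal(oc, 2.483, tolerance = 1e-9)
  expect_equal(nl, -1.366, tolerance = 1e-9)
  expect_equal(classify_risk(m, oc), "OC")
  expect_equal(classify_risk(m, nl), "normal")
  expect_equal(risk_score(m, c(AMPD3 = 0, NRN1 = 0, TBX15 = 0)), 6.38)
})

test_that("scoring is affine, order-invariant, monotone, and strict about inputs", {
  m <- published_model()
  x <- c(AMPD3 = 3, NRN1 = 2, TBX15 = 6)
  # permuting gene order changes nothing
  expect_equal(risk_score(m, x[c(3, 1, 2)]), risk_score(m, x))
  # lowering any delta-Cp (more methylation) never lowers the score
  for (g in m$genes) {
    x2 <- x
    x2[g] <- x2[g] - 1
    expect_gt(risk_score(m, x2), risk_score(m, x))
  }
  # affine in each coordinate
  x3 <- x; x3["NRN1"] <- x["NRN1"] + 2
  expect_equal(risk_score(m, x3) - risk_score(m, x), 2 * m$beta[["NRN1"]])
  # boundary convention: exactly at the cutoff is positive
  expect_equal(classify_risk(m, m$cutoff), "OC")
  expect_equal(classify_risk(m, m$cutoff - 1e-9), "normal")
  expect_error(risk_score(m, c(AMPD3 = 1, NRN1 = 2)), "TBX15")
})

test_that("cross-validated fitting is deterministic and recovers coefficient signs", {
  set.seed(51)
  n <- 60
  labels <- rep(c("OC", "normal"), each = n / 2)
  dcp <- cbind(
    AMPD3 = ifelse(labels == "OC", 2.5, 4) + rnorm(n, sd = 0.8),
    TBX15 = ifelse(labels == "OC", 5, 7.5) + rnorm(n, sd = 0.8)
  )
  m1 <- fit_cv_model(dcp, labels, replications = 20, seed = 9)
  m2 <- fit_cv_model(dcp, labels, replications = 20, seed = 9)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$cutoff, m2$cutoff)
  expect_true(all(m1$beta < 0))
  expect_equal(m1$provenance$n_fits, 200)
  expect_true(all(c("coef_mean", "coef_median") %in% names(m1$provenance)))

  # degenerate config: 1 replication with leave-pair-out-sized folds runs
  idx <- c(1:12, 31:42) # 12 cases + 12 controls
  small <- fit_cv_model(dcp[idx, ], labels[idx], folds = 12, replications = 1,
                        seed = 1)
  expect_true(all(is.finite(small$beta)))

  expect_error(fit_cv_model(dcp[1:12, ], labels[1:12], folds = 10),
               "at least")
})

test_that("evaluation applies the frozen cutoff and flags one-class cohorts", {
  set.seed(52)
  labels <- rep(c("OC", "normal"), each = 20)
  dcp <- cbind(G = ifelse(labels == "OC", 2, 8))
  m <- fit_cv_model(dcp + rnorm(40, sd = 0.1), labels, folds = 5,
                    replications = 5, seed = 2)
  ev <- evaluate_risk_model(m, dcp, labels, B = 50, seed = 3)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$auc, 1)

  ev_n <- evaluate_risk_model(m, dcp[21:40, , drop = FALSE], labels[21:40],
                              B = 0)
  expect_true(ev_n$one_class_only)
  expect_true(is.na(ev_n$sensitivity))
  expect_equal(ev_n$specificity, 1)
  expect_error(evaluate_risk_model(m, dcp[0, , drop = FALSE], labels[0]),
               "empty")
})

test_that("aggregated CV coefficients are stable across independent seeds", {
  set.seed(53)
  n <- 62
  labels <- rep(c("OC", "normal"), each = n / 2)
  dcp <- cbind(
    AMPD3 = ifelse(labels == "OC", 2.7, 3.8) + rnorm(n, sd = 1.5),
    TBX15 = ifelse(labels == "OC", 5.1, 7.6) + rnorm(n, sd = 1.5)
  )
  betas <- t(vapply(1:10, function(s) {
    fit_cv_model(dcp, labels, replications = 20, seed = s)$beta
  }, numeric(2)))
  expect_lt(max(apply(betas, 2, sd)), 0.1)
})

test_that("the AUC sample-size planner solves the stated variance inequality", {
  # binomial-variance building blocks at theta = 0.75
  theta <- 0.75
  expect_equal(theta / (2 - theta), 0.6)
  expect_equal(2 * theta^2 / (1 + theta), 9 / 14)

  expect_equal(auc_sample_size(0.75), 20)

  # stronger alternatives need fewer samples
  sweep <- vapply(c(0.65, 0.7, 0.75, 0.8, 0.9, 0.95), auc_sample_size,
                  numeric(1))
  expect_true(all(diff(sweep) < 0))

  expect_error(auc_sample_size(0.4), "theta")
})

test_that("study planning derives the enrolled set sizes from the base n", {
  plan <- plan_study(19)
  expect_equal(plan$test_per_group, 21)
  expect_equal(plan$test_total, 42)
  expect_equal(plan$train_per_group, 31) # half rounds up: 28.5 -> 29, + 2
  expect_equal(plan$train_total, 62)

  expect_equal(plan_study(10, train_to_test_ratio = 1, pad_per_group = 0)$train_per_group,
               10)
  expect_equal(plan_study(1)$test_per_group, 3)
})

test_that("CV aggregates recover generating coefficients within 2 SE at n = 500", {
  gen <- generate_logistic_cohort(
    beta = c(AMPD3 = -0.47, NRN1 = -0.41, TBX15 = -0.57),
    epsilon = 6.38, n = 500, dcp_mean = c(3, 2, 6), dcp_sd = 1.5, seed = 54
  )
  m <- fit_cv_model(gen$delta_cp, gen$labels, replications = 50, seed = 54)
  ml <- glm(gen$labels ~ gen$delta_cp, family = binomial)
  se <- summary(ml)$coefficients[, "Std. Error"]
  est <- c(m$epsilon, m$beta)
  truth <- c(gen$epsilon, gen$beta)
  expect_true(all(abs(est - truth) < 2 * se))
})

test_that("risk models serialize to JSON and back without loss", {
  m <- published_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(m, path)
  m2 <- read_risk_model(path)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$epsilon, m$epsilon)
  expect_equal(m2$cutoff, m$cutoff)
  expect_equal(risk_score(m2, c(AMPD3 = 2, NRN1 = 0.4, TBX15 = 4.9)),
               risk_score(m, c(AMPD3 = 2, NRN1 = 0.4, TBX15 = 4.9)))
})
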