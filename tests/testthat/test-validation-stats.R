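test_that("exact Mann-Whitney p matches full enumeration on small groups", {
  res <- mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1) # 2 / choose(6, 3)
  expect_true(res$exact)

  set.seed(42)
  for (n1 in 2:7) {
    for (n2 in 2:7) {
      x <- rnorm(n1)
      y <- rnorm(n2, mean = runif(1, -1, 1))
      expect_equal(
        mann_whitney_two_tailed(x, y)$p_value,
        oracle_mw_p(x, y),
        tolerance = 1e-12,
        info = sprintf("n1=%d n2=%d", n1, n2)
      )
    }
  }
})

test_that("one swap away from complete separation doubles the enumeration mass", {
  # full separation: p = 2/20; swapping the two middle values: U = 1
  x <- c(1, 2, 4)
  y <- c(3, 5, 6)
  expect_equal(mann_whitney_two_tailed(x, y)$p_value, oracle_mw_p(x, y))
  expect_equal(mann_whitney_two_tailed(x, y)$p_value, 4 / 20)
})

test_that("tied / large-group data takes the corrected normal approximation", {
  x <- c(1, 1, 2, 2, 3)
  res <- mann_whitney_two_tailed(x, x)
  expect_false(res$exact)
  expect_gt(res$p_value, 0.9)
  big <- mann_whitney_two_tailed(rnorm(30), rnorm(9))
  expect_false(big$exact)
})

test_that("roc_auc equals brute-force pair counting on random instances", {
  d <- two_group_values(c(1, 3), c(2, 4))
  expect_equal(roc_auc(d$values, d$labels, direction = "lower_is_positive"), 0.75)
  expect_equal(roc_auc(d$values, d$labels, direction = "higher_is_positive"), 0.25)

  set.seed(7)
  for (i in 1:300) {
    n1 <- sample(2:30, 1)
    n0 <- sample(2:30, 1)
    case <- round(rnorm(n1, 0.3), sample(0:2, 1)) # rounding induces ties
    control <- round(rnorm(n0), sample(0:2, 1))
    d <- two_group_values(case, control)
    expect_equal(
      roc_auc(d$values, d$labels, direction = "higher_is_positive"),
      oracle_auc(case, control),
      tolerance = 1e-12
    )
  }
})

test_that("roc_auc is invariant under strictly monotone transforms", {
  set.seed(8)
  d <- two_group_values(rnorm(15, 1), rnorm(12))
  a <- roc_auc(d$values, d$labels)
  expect_equal(roc_auc(exp(d$values), d$labels), a)
  expect_equal(roc_auc(qlogis(plogis(d$values)), d$labels), a, tolerance = 1e-9)
  expect_equal(roc_auc(-d$values, d$labels, direction = "lower_is_positive"), a)
})

test_that("perfectly separated data yields AUC 1 and a perfect cutoff", {
  d <- two_group_values(c(1.0, 1.2, 0.9), c(2.0, 2.4, 3.0))
  expect_equal(roc_auc(d$values, d$labels, direction = "lower_is_positive"), 1)
  ct <- closest_topleft_cutoff(d$values, d$labels, direction = "lower_is_positive")
  expect_equal(ct$sensitivity, 1)
  expect_equal(ct$specificity, 1)
  expect_true(ct$cutoff > 1.2 && ct$cutoff < 2.0)
})

test_that("closest_topleft_cutoff matches the exhaustive-scan oracle", {
  set.seed(9)
  for (i in 1:300) {
    n1 <- sample(3:25, 1)
    n0 <- sample(3:25, 1)
    values <- round(c(rnorm(n1, 1), rnorm(n0)), sample(1:2, 1))
    pos <- c(rep(TRUE, n1), rep(FALSE, n0))
    lower <- i %% 2 == 0
    got <- closest_topleft_cutoff(
      values, pos,
      direction = if (lower) "lower_is_positive" else "higher_is_positive"
    )
    want <- oracle_topleft(values, pos, lower_is_positive = lower)
    expect_equal(got$cutoff, want$cut)
    expect_equal(got$sensitivity, want$se)
    expect_equal(got$specificity, want$sp)
  }
})

test_that("bootstrap_ci is reproducible, degenerate-safe, and covers the estimate", {
  d <- two_group_values(rnorm(12, 1), rnorm(12))
  metric <- function(v, l) roc_auc(v, l)
  ci1 <- bootstrap_ci(d$values, d$labels, metric, B = 200, seed = 5)
  ci2 <- bootstrap_ci(d$values, d$labels, metric, B = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] <= ci1[2])

  const <- bootstrap_ci(d$values, d$labels, function(v, l) 0.5, B = 50, seed = 1)
  expect_equal(const, c(0.5, 0.5))

  # stratified resampling keeps both classes: a 2-case dataset never errors
  tiny <- two_group_values(c(1, 2), c(3, 4, 5))
  expect_no_error(bootstrap_ci(tiny$values, tiny$labels, metric, B = 50, seed = 2))

  # percentile interval contains the point estimate in nearly all draws
  set.seed(10)
  hits <- 0
  for (i in 1:40) {
    d <- two_group_values(rnorm(15, 1.2), rnorm(15))
    a <- roc_auc(d$values, d$labels)
    ci <- bootstrap_ci(d$values, d$labels, metric, B = 200, seed = i)
    if (a >= ci[1] && a <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("roc machinery agrees with pROC on a fixed instance", {
  skip_if_not_installed("pROC")
  set.seed(11)
  d <- two_group_values(rnorm(20, 1), rnorm(20))
  r <- pROC::roc(d$labels, d$values, direction = "<", quiet = TRUE)
  expect_equal(roc_auc(d$values, d$labels), as.numeric(pROC::auc(r)))
  best <- pROC::coords(r, "best", best.method = "closest.topleft",
                       transpose = FALSE)
  got <- closest_topleft_cutoff(d$values, d$labels)
  expect_equal(got$sensitivity, best$sensitivity[1])
  expect_equal(got$specificity, best$specificity[1])
})

test_that("logistic combination reduces to the single gene's AUC and recovers signs", {
  set.seed(12)
  n <- 40
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  dcp <- cbind(TBX15 = ifelse(labels, 5, 7.5) + rnorm(n, sd = 1.2))
  fit1 <- combine_genes_logistic(dcp, labels)
  expect_equal(
    roc_auc(fit1$scores, labels),
    roc_auc(dcp[, 1], labels, direction = "lower_is_positive")
  )

  dcp3 <- cbind(
    AMPD3 = ifelse(labels, 2.5, 4) + rnorm(n, sd = 1),
    NRN1 = ifelse(labels, 0.5, 2.5) + rnorm(n, sd = 1),
    TBX15 = ifelse(labels, 5, 7.5) + rnorm(n, sd = 1)
  )
  fit3 <- combine_genes_logistic(dcp3, labels)
  expect_true(all(fit3$coefficients[-1] < 0))

  # a label-independent noise gene's coefficient shrinks with n
  coef_at_n <- function(n) {
    set.seed(100 + n)
    lab <- rep(c(TRUE, FALSE), each = n / 2)
    x <- cbind(signal = ifelse(lab, 1, 3) + rnorm(n), noise = rnorm(n))
    abs(combine_genes_logistic(x, lab)$coefficients["noise"])
  }
  expect_lt(median(sapply(1:5, function(i) coef_at_n(2000))), 0.25)
})

test_that("separated logistic fits fall back to ridge and are flagged", {
  labels <- rep(c(TRUE, FALSE), each = 5)
  dcp <- cbind(g = c(1:5, 11:15))
  fit <- combine_genes_logistic(dcp, labels)
  expect_true(fit$ridged)
  expect_true(all(is.finite(fit$coefficients)))
  expect_equal(roc_auc(fit$scores, labels), 1)
})

test_that("group_comparison matches Kruskal-Wallis behavior and flags shifted groups", {
  x <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- group_comparison(x[order(rep(1:4, 3))], rep(c("a", "b", "c"), 4))
  expect_gt(res$p_value, 0.9)
  expect_equal(nrow(res$posthoc), 0)

  set.seed(13)
  scores <- c(rnorm(8), rnorm(8), rnorm(8, mean = 6))
  grp <- rep(c("Ser", "En", "Mu"), each = 8)
  res <- group_comparison(scores, grp)
  expect_lt(res$p_value, 0.05)
  flagged <- res$posthoc[res$posthoc$flag, ]
  expect_true(all(apply(flagged[, c("group1", "group2")], 1, function(p) "Mu" %in% p)))

  # two groups: H equals the squared tie-corrected Mann-Whitney z
  x1 <- rnorm(10)
  x2 <- rnorm(12, 0.8)
  res2 <- group_comparison(c(x1, x2), rep(c("a", "b"), c(10, 12)))
  n1 <- 10; n2 <- 12; N <- n1 + n2
  r <- rank(c(x1, x2))
  u <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(res2$H, z^2, tolerance = 1e-9)

  expect_error(group_comparison(1:5, rep("a", 5)), "two groups")
})
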