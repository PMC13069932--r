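test_that("AUC equals exhaustive pair counting on small inputs with ties", {
  set.seed(101)
  for (rep in 1:30) {
    cs <- random_tied_case(sample(4:12, 1))
    r <- roc_curve(cs$scores, cs$labels)
    expect_equal(r$auc, auc_pairs_oracle(cs$scores, cs$labels))
  }
})

test_that("ROC handles the separability extremes", {
  r <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")

  set.seed(5)
  scores <- rnorm(2000)
  labels <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  r0 <- roc_curve(scores, labels)
  expect_lt(abs(r0$auc - 0.5), 0.05)
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- c(rnorm(40, 1), rnorm(60))
  labels <- rep(c(TRUE, FALSE), c(40, 60))
  r <- roc_curve(scores, labels)
  pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$auc_ci95, ci[c(1, 3)], tolerance = 1e-8)
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- rnorm(80)
  labels <- sample(c(TRUE, FALSE), 80, replace = TRUE, prob = c(0.3, 0.7))
  r1 <- roc_curve(scores, labels)
  r2 <- roc_curve(exp(scores / 3), labels)
  expect_equal(r2$auc, r1$auc)
  expect_equal(r2$auc_se, r1$auc_se)
  expect_equal(r2$sensitivity, r1$sensitivity)
  expect_equal(r2$youden_cutoff, exp(r1$youden_cutoff / 3))
})

test_that("negating scores reflects the AUC about one half", {
  set.seed(14)
  for (rep in 1:10) {
    cs <- random_tied_case(15)
    a <- roc_curve(cs$scores, cs$labels)$auc
    b <- roc_curve(-cs$scores, cs$labels)$auc
    expect_equal(a + b, 1)
  }
})

test_that("DeLong SE shrinks with sample size at fixed separation", {
  ses <- vapply(c(50, 500, 5000), function(n) {
    withr::with_seed(n, {
      scores <- c(rnorm(n / 10, 1), rnorm(n - n / 10))
      labels <- rep(c(TRUE, FALSE), c(n / 10, n - n / 10))
      roc_curve(scores, labels)$auc_se
    })
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_lt(ses[3], ses[1] / 5)
})

test_that("the Youden cutoff matches exhaustive search", {
  r <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  y <- youden_cutoff(r)
  expect_equal(y$cutoff, 3)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)

  # perfect separation: smallest candidate inside the gap attains J = 1
  r2 <- roc_curve(c(1, 2, 5, 6), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(youden_cutoff(r2)$cutoff, 5)

  set.seed(77)
  for (rep in 1:30) {
    cs <- random_tied_case(sample(4:12, 1))
    r <- roc_curve(cs$scores, cs$labels)
    expect_equal(youden_cutoff(r)$cutoff, youden_oracle(cs$scores, cs$labels))
  }
})

test_that("logistic association recovers a known slope and prevalence", {
  withr::local_seed(21)
  n <- 5000
  h <- rnorm(n, 2.65, 0.88)
  y <- rbinom(n, 1, plogis(-3 + 1.0 * h))
  coh <- data.frame(hscore = h, fish_status = ifelse(y == 1, "positive", "negative"))
  fit <- logistic_association(coh)
  or <- fit$terms$or[fit$terms$term == "hscore"]
  expect_lt(abs(or - exp(1)) / exp(1), 0.10)
  expect_true(fit$converged)
  expect_true(fit$terms$ci_lo[2] < or & or < fit$terms$ci_hi[2])

  # intercept-only fit reproduces the closed-form MLE: the prevalence
  coh2 <- data.frame(one = rep(1, 182),
                     fish_status = rep(c("positive", "negative"), c(13, 169)))
  fit2 <- logistic_association(coh2, predictors = "1")
  expect_equal(plogis(fit2$terms$estimate[1]), 13 / 182)
})

test_that("degenerate predictors are flagged, not silently estimated", {
  coh <- data.frame(hscore = rep(0, 40), x = rnorm(40),
                    fish_status = rep(c("positive", "negative"), 20))
  expect_warning(logistic_association(coh, predictors = c("x", "hscore")),
                 "dropped")
})

test_that("cutpoint scan applies Bonferroni exactly and finds obvious splits", {
  set.seed(31)
  scores <- rnorm(40)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  scan <- cutpoint_scan(scores, labels)
  tested <- !scan$table$skipped
  expect_equal(scan$n_tested, sum(tested))
  expect_equal(scan$table$p_adj[tested],
               pmin(1, scan$table$p_raw[tested] * scan$n_tested))
  expect_true(all(scan$table$p_adj[tested] >= scan$table$p_raw[tested]))

  # perfectly separated data: best cutpoint falls between the classes
  s2 <- c(rnorm(10, 0), rnorm(10, 8))
  l2 <- rep(c(FALSE, TRUE), each = 10)
  scan2 <- cutpoint_scan(s2, l2)
  expect_gt(scan2$best_cutpoint, max(s2[1:10]))
  expect_lt(scan2$best_cutpoint, min(s2[11:20]))
  expect_lt(scan2$best_p_adj, 0.05)

  # grid candidates splitting off an empty group are skipped and recorded
  scan3 <- cutpoint_scan(scores, labels, grid = c(-100, 0, 100))
  expect_equal(scan3$table$skipped, c(TRUE, FALSE, TRUE))
  expect_equal(scan3$n_tested, 1)

  expect_error(cutpoint_scan(rep(1, 10), rep(c(TRUE, FALSE), 5)), "distinct")
})

test_that("chi-squared and Fisher variants run on the same scan surface", {
  set.seed(41)
  scores <- rnorm(60)
  labels <- scores + rnorm(60) > 0
  for (tst in c("chisq", "fisher")) {
    scan <- cutpoint_scan(scores, labels, test = tst)
    expect_true(is.finite(scan$best_cutpoint))
    expect_true(all(scan$table$p_adj >= scan$table$p_raw, na.rm = TRUE))
  }
})

test_that("family-wise error of the scan stays at or below nominal under the null", {
  # 500 independent null cohorts: scores and labels unrelated; declaring any
  # Bonferroni-adjusted candidate significant at 0.05 should happen in at
  # most ~5% of them (binomial slack at 500 reps)
  withr::local_seed(55)
  hits <- 0
  for (r in 1:500) {
    scores <- rnorm(100)
    labels <- sample(rep(c(TRUE, FALSE), 50))
    scan <- cutpoint_scan(scores, labels)
    if (is.finite(scan$best_p_adj) && scan$best_p_adj < 0.05) hits <- hits + 1
  }
  expect_lte(hits / 500, 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("pairwise group AUCs have the reference table layout and null behavior", {
  coh <- generate_cohort(synthetic_spec(include_controls = TRUE, seed = 3))
  coh <- score_cohort(coh)
  tab <- pairwise_group_auc(coh)
  expect_equal(tab$group,
               c("1 vs 0", "2 vs 0", "3 vs 0", "2 vs 1", "3 vs 1", "3 vs 2"))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$ci_lo <= tab$auc & tab$auc <= tab$ci_hi))

  # identical distributions: AUC within 3 SE of 0.5
  withr::local_seed(8)
  null_coh <- data.frame(ihc_category = rep(c(1L, 2L), each = 200),
                         hscore = rnorm(400, 2.65, 0.88))
  nt <- pairwise_group_auc(null_coh)
  expect_lt(abs(nt$auc - 0.5), 3 * nt$se)

  # stochastic dominance: shifted category scores AUC >= 0.5
  dom <- data.frame(ihc_category = rep(c(2L, 3L), each = 100),
                    hscore = c(rnorm(100, 2.65, 0.5), rnorm(100, 4.0, 0.5)))
  expect_gte(pairwise_group_auc(dom)$auc, 0.5)

  # a category with fewer than 2 cases is skipped with a warning
  tiny <- data.frame(ihc_category = c(2L, 2L, 3L), hscore = c(2, 3, 4))
  expect_warning(expect_null(pairwise_group_auc(tiny)), "skipped")
})

test_that("simulated 3+ vs 2+ AUC matches an independent Monte-Carlo oracle", {
  # implementation route: 500 small cohorts through pairwise_group_auc
  withr::local_seed(60)
  aucs <- numeric(500)
  for (r in 1:500) {
    coh <- data.frame(
      ihc_category = rep(c(2L, 3L), c(182, 10)),
      hscore = c(rtruncnorm(182, 2.65, 0.88, 1.16, 6.43),
                 rtruncnorm(10, 4.02, 1.43, 2.46, 6.75)))
    aucs[r] <- pairwise_group_auc(coh)$auc
  }
  # oracle route: P(score_3 > score_2) by direct large-sample comparison of
  # draws from the same truncated normals
  x2 <- rtruncnorm(2e5, 2.65, 0.88, 1.16, 6.43)
  x3 <- rtruncnorm(2e5, 4.02, 1.43, 2.46, 6.75)
  oracle <- mean(x3 > x2)
  expect_lt(abs(mean(aucs) - oracle), 0.08)
})

test_that("group_summary reports moments per group and degenerate groups honestly", {
  coh <- data.frame(ihc_category = c(2, 2, 2, 3),
                    hscore = c(2.0, 2.5, 3.0, 4.0))
  gs <- group_summary(coh)
  expect_equal(gs$n, c(3, 1))
  expect_equal(gs$hscore_mean, c(2.5, 4.0))
  expect_true(is.na(gs$hscore_sd[2]))
  expect_equal(gs$hscore_min[2], gs$hscore_max[2])
})
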