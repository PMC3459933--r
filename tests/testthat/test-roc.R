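test_that("AUC equals the concordant-pair oracle, including ties", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 5, 0.5), n, replace = TRUE)  # forces ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, o_auc(scores, labels))
    # complementarity: reversing orientation flips the AUC
    expect_equal(roc_auc(scores, labels, "less")$auc,
                 1 - roc_auc(scores, labels, "greater")$auc)
  }
})

test_that("AUC limits: perfect separation and null", {
  r1 <- roc_auc(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(r1$auc, 1)
  expect_true(r1$ci95[1] <= r1$auc && r1$auc <= r1$ci95[2])
  set.seed(23)
  expect_lt(abs(roc_auc(rnorm(2000), rep(c(TRUE, FALSE), 1000))$auc - 0.5),
            0.05)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC and CI agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(80)
  labels <- runif(80) < plogis(scores)
  ours <- roc_auc(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Youden cutoff maximises J with the documented rule", {
  scores <- c(1, 2, 3, 4, 10, 11, 12)
  labels <- c(F, F, F, F, T, T, T)
  y <- youden_cutoff(scores, labels)
  expect_equal(y$youden_j, 1)
  expect_equal(y$cutoff, 10)
  expect_equal(y$rule, "score >= cutoff")
  expect_equal(y$sensitivity, 100)
  expect_equal(y$specificity, 100)
  # negatively oriented predictor reports a <= rule on the original scale
  yl <- youden_cutoff(-scores, labels, "less")
  expect_equal(yl$rule, "score <= cutoff")
  expect_equal(yl$youden_j, 1)
})

test_that("cutoff sweep recovers a built-in changepoint", {
  set.seed(61)
  hits <- 0
  for (rep in 1:20) {
    n <- 100
    sdv <- runif(n, 1, 5)
    index <- (sdv >= 3) * 2 + rnorm(n, 0, 0.8)  # coupling switches at SD = 3
    tab <- tibble::tibble(sd = sdv, idx = index)
    sw <- cutoff_sweep(tab, "idx")
    if (abs(sw$sd_threshold - 3) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})

test_that("sweep AUC is invariant to monotone transforms of the index", {
  set.seed(3)
  tab <- tibble::tibble(sd = runif(60, 1, 5), idx = rnorm(60))
  s1 <- cutoff_sweep(tab, "idx")
  tab$idx <- exp(tab$idx)
  s2 <- cutoff_sweep(tab, "idx")
  expect_equal(s1$sweep$auc, s2$sweep$auc)
  expect_equal(s1$sd_threshold, s2$sd_threshold)
})

test_that("index equal to SD itself yields AUC 1 at every grid point", {
  tab <- tibble::tibble(sd = seq(1, 5, length.out = 50))
  tab$idx <- tab$sd
  sw <- cutoff_sweep(tab, "idx")
  expect_true(all(sw$sweep$auc == 1))
})

test_that("permutation assessment flags sweep optimism on null data", {
  set.seed(29)
  tab <- tibble::tibble(sd = runif(100, 1, 5), idx = rnorm(100))
  sw <- cutoff_sweep(tab, "idx", n_permutations = 100)
  expect_true(sw$optimistic)
  expect_gt(sw$optimism, 0)              # maximisation inflates the null AUC
  expect_gt(sw$p_permutation, 0.05)      # but the observed AUC is not special
})

test_that("combined criterion contrasts the definite groups", {
  set.seed(41)
  n <- 120
  v <- runif(n, 1, 5)
  tab <- tibble::tibble(
    sd = v,
    ga_a1c_ratio = 2.8 + 0.3 * (v - 3) + rnorm(n, 0, 0.3),
    fcpr_index = 3.0 - 1.5 * (v - 3) + rnorm(n, 0, 1))
  cc <- combined_criterion_analysis(tab)
  expect_equal(cc$n_high + cc$n_low + cc$n_indeterminate, n)
  expect_gt(cc$group_stats$sd_mean[1], cc$group_stats$sd_mean[2])
  expect_lt(cc$t_test$p.value, 0.05)
  expect_true(cc$roc$auc >= 0 && cc$roc$auc <= 1)
  # degenerate: everyone in one cell -> flagged, no contrast
  tab1 <- tibble::tibble(sd = runif(10, 1, 5),
                         ga_a1c_ratio = rep(4, 10), fcpr_index = rep(1, 10))
  cc1 <- combined_criterion_analysis(tab1)
  expect_true(cc1$degenerate)
  expect_null(cc1$t_test)
})
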