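test_that("ROC curve hits the corners for separable and degenerate data", {
  d <- tibble::tibble(score = c(0.9, 0.8, 0.1, 0.2),
                      group = rep(c("case", "control"), each = 2))
  roc <- roc_curve(d, score, group)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect separation
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(roc_auc(roc), 1)

  tied <- tibble::tibble(score = rep(2, 6),
                         group = rep(c("case", "control"), 3))
  expect_equal(roc_auc(roc_curve(tied, score, group)), 0.5)
  expect_error(roc_curve(dplyr::filter(d, group == "case"), score, group),
               class = "sweshell_validation_error")
})

test_that("ROC points match exhaustive threshold enumeration", {
  for (seed in 1:5) {
    d <- rand_scores(8, 9, seed = 200 + seed, ties = seed %% 2 == 0)
    roc <- roc_curve(d, score, group)
    is_case <- d$group == "case"
    for (k in seq_len(nrow(roc))) {
      t <- roc$threshold[k]
      expect_equal(roc$tpr[k], mean(d$score[is_case] > t))
      expect_equal(roc$fpr[k], mean(d$score[!is_case] > t))
    }
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney pairwise statistic", {
  d <- tibble::tibble(score = c(0.8, 0.4, 0.4, 0.2),
                      group = c("case", "case", "control", "control"))
  expect_equal(roc_auc(roc_curve(d, score, group)), 0.875)  # 3.5 / 4
  for (seed in 1:25) {
    d <- rand_scores(sample(2:15, 1), sample(2:15, 1), seed = 300 + seed,
                     ties = seed %% 2 == 0)
    a <- roc_auc(roc_curve(d, score, group))
    b <- oracle_pairwise_auc(d$score[d$group == "case"],
                             d$score[d$group == "control"])
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("AUC respects label-swap antisymmetry and monotone invariance", {
  for (seed in 1:10) {
    d <- rand_scores(7, 11, seed = 500 + seed, ties = seed %% 3 == 0)
    a <- roc_auc(roc_curve(d, score, group))
    swapped <- dplyr::mutate(d, group = ifelse(group == "case", "control", "case"))
    expect_equal(roc_auc(roc_curve(swapped, score, group)), 1 - a,
                 tolerance = 1e-12)
    trans <- dplyr::mutate(d, score = exp(3 * score) + 1)
    expect_equal(roc_auc(roc_curve(trans, score, group)), a, tolerance = 1e-12)
  }
})

test_that("Youden threshold maximizes J over midpoint cutoffs", {
  d <- tibble::tibble(score = c(3, 4, 1, 2),
                      group = c("case", "case", "control", "control"))
  y <- youden_threshold(d, score, group)
  expect_equal(y$threshold, 2.5)
  expect_equal(y$sensitivity, 1); expect_equal(y$specificity, 1)
  expect_equal(y$youden_j, 1)

  same <- tibble::tibble(score = c(1, 2, 3, 1, 2, 3),
                         group = rep(c("case", "control"), each = 3))
  expect_equal(youden_threshold(same, score, group)$youden_j, 0)

  # exhaustive search over the midpoint cutoffs
  for (seed in 1:8) {
    d <- rand_scores(6, 7, seed = 700 + seed, ties = seed %% 2 == 0)
    y <- youden_threshold(d, score, group)
    is_case <- d$group == "case"
    u <- sort(unique(d$score))
    mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    js <- vapply(mids, function(t) {
      mean(d$score[is_case] > t) + mean(d$score[!is_case] <= t) - 1
    }, numeric(1))
    expect_equal(y$youden_j, max(js), tolerance = 1e-12)
    expect_equal(y$threshold, mids[which(js >= max(js) - 1e-12)][1])
  }
})

test_that("stage summary reports two-decimal percentages summing to ~100", {
  tab <- stage_summary(c(edema = 7, sclerotic = 42, atrophic = 47))
  expect_equal(tab$percent, c(7.29, 43.75, 48.96))
  expect_lte(abs(sum(tab$percent) - 100), 0.02)
  expect_equal(stage_summary(c(only = 12))$percent, 100)
  expect_equal(stage_summary(c(a = 1, b = 1, c = 1))$percent,
               rep(33.33, 3))
  expect_error(stage_summary(c(a = 0, b = 0)),
               class = "sweshell_validation_error")
})

test_that("group comparison gates on normality and degenerates sensibly", {
  ident <- tibble::tibble(v = c(1, 2, 3, 1, 2, 3),
                          g = rep(c("a", "b"), each = 3))
  res <- compare_groups(ident, v, g)
  expect_equal(res$method, "welch_t")
  expect_equal(res$statistic, 0)

  set.seed(42)
  skewed <- tibble::tibble(
    v = c(exp(rnorm(30, 0, 1.5)), exp(rnorm(30, 0, 1.5))),
    g = rep(c("a", "b"), each = 30))
  expect_equal(compare_groups(skewed, v, g)$method, "wilcoxon")
  expect_error(compare_groups(tibble::tibble(v = c(1, 2), g = c("a", "b")),
                              v, g),
               class = "sweshell_validation_error")
})

test_that("diagnostic_eval bundles ROC, AUC and the cutoff with tidiers", {
  d <- rand_scores(20, 20, seed = 900)
  d$score[d$group == "case"] <- d$score[d$group == "case"] + 2
  res <- diagnostic_eval(d, score, group)
  expect_s3_class(res, "diag_result")
  g <- glance(res)
  expect_equal(g$auc, roc_auc(roc_curve(d, score, group)))
  expect_equal(g$n_case, 20L)
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("AUC agrees with an independent ROC implementation", {
  for (seed in 1:6) {
    d <- rand_scores(12, 15, seed = 1100 + seed, ties = seed %% 2 == 0)
    ours <- roc_auc(roc_curve(d, score, group))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = d$group, predictor = d$score,
      levels = c("control", "case"), direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})
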