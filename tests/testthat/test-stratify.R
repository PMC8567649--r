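test_that("maxstat separates a perfectly split cohort at the largest candidate below the gap", {
  # 15 early deaths (all at t = 1) with biomarker < 5, 15 long censored
  # survivors > 5: the perfect split maximizes |Z|
  values <- c(seq(0.25, 3.75, by = 0.25), seq(6, 20, by = 1))
  time <- c(rep(1, 15), rep(100, 15))
  event <- c(rep(1, 15), rep(0, 15))
  ms <- maxstat_cutpoint(values, time, event, minprop = 0.1)
  expect_equal(ms$cutpoint, 3.75)
  oracle <- brute_maxstat(values, time, event, 0.1)
  expect_equal(ms$cutpoint, oracle$cutpoint)
  expect_equal(ms$statistic, oracle$statistic, tolerance = 1e-8)
  expect_error(maxstat_cutpoint(rep(1, 30), time, event), "candidate")
})

test_that("maxstat equals an exhaustive survdiff scan and is order-invariant", {
  set.seed(101)
  for (i in 1:10) {
    co <- rand_survival_cohort(sample(30:80, 1))
    ms <- maxstat_cutpoint(co$values, co$time, co$event)
    oracle <- brute_maxstat(co$values, co$time, co$event)
    expect_equal(ms$cutpoint, oracle$cutpoint)
    expect_equal(ms$statistic, oracle$statistic, tolerance = 1e-8)
    # invariance to input ordering
    perm <- sample(length(co$values))
    ms2 <- maxstat_cutpoint(co$values[perm], co$time[perm], co$event[perm])
    expect_equal(ms2$cutpoint, ms$cutpoint)
  }
})

test_that("Youden threshold maximizes sensitivity + specificity - 1", {
  y <- youden_cutpoint(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(y$threshold, 2)
  expect_equal(y$youden_j, 1)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  expect_error(youden_cutpoint(1:4, c(1, 1, 1, 1)), "both outcome classes")

  set.seed(7)
  for (i in 1:10) {
    n <- sample(30:150, 1)
    scores <- round(stats::rnorm(n), 2)
    outcome <- stats::rbinom(n, 1, stats::plogis(scores))
    if (length(unique(outcome)) < 2) next
    y <- youden_cutpoint(scores, outcome)
    oracle <- brute_youden(scores, outcome)
    expect_equal(y$threshold, oracle$threshold)
    expect_equal(y$youden_j, oracle$j, tolerance = 1e-12)
    # reported operating point is consistent with the chosen threshold
    expect_equal(y$sensitivity,
                 mean(scores[outcome == 1] > y$threshold))
  }
})

test_that("Youden agrees with pROC on a fixed cohort", {
  set.seed(12)
  scores <- round(stats::rnorm(80), 3)
  outcome <- stats::rbinom(80, 1, stats::plogis(1.5 * scores))
  y <- youden_cutpoint(scores, outcome)
  roc <- pROC::roc(outcome, scores, quiet = TRUE, direction = "<")
  best <- pROC::coords(roc, "best", best.method = "youden",
                       transpose = FALSE)
  # pROC places the threshold between observed scores; J must agree
  expect_equal(y$youden_j,
               max(best$sensitivity + best$specificity - 1),
               tolerance = 1e-9)
  expect_equal(y$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-9)
})

test_that("joint HED x TMB groups follow the strict-greater convention", {
  expect_equal(as.character(assign_joint_group(9.0, 6.0)), "both_high")
  expect_equal(as.character(assign_joint_group(9.0, 5.22)), "single_high")
  expect_equal(as.character(assign_joint_group(8.61, 5.22)), "both_low")
  expect_equal(as.character(assign_joint_group(8.61, 6.0)), "single_high")
  expect_warning(out <- assign_joint_group(c(9, NA), c(6, 1)), "missing")
  expect_true(is.na(out[2]))
})

test_that("DCB contingency test matches closed-form hypergeometric probabilities", {
  g <- rep(c("both_high", "both_low"), c(9, 31))
  d <- c(rep(c("DCB", "NDB"), c(6, 3)), rep(c("DCB", "NDB"), c(5, 26)))
  res <- dcb_contingency_test(g, d, method = "fisher")
  expect_equal(res$p, fisher.test(matrix(c(6, 3, 5, 26), 2, 2,
                                         byrow = TRUE))$p.value)
  expect_lt(res$p, 0.05)
  expect_equal(unname(res$proportions), c(6 / 9, 5 / 31))

  # identical proportions give p = 1
  g2 <- rep(c("a", "b"), each = 10)
  d2 <- rep(rep(c("DCB", "NDB"), each = 5), 2)
  expect_equal(dcb_contingency_test(g2, d2, method = "fisher")$p, 1)

  # perfectly separated 0/10 vs 10/10: both extreme tables are equally
  # probable, so the two-sided p is 2 / choose(20, 10)
  g3 <- rep(c("a", "b"), each = 10)
  d3 <- rep(c("NDB", "DCB"), each = 10)
  expect_equal(dcb_contingency_test(g3, d3, method = "fisher")$p,
               2 / choose(20, 10), tolerance = 1e-12)

  # chi-square path: Pearson statistic without continuity correction
  res4 <- dcb_contingency_test(g, d, method = "chi2")
  tab <- matrix(c(6, 3, 5, 26), 2, 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res4$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_error(dcb_contingency_test(rep("a", 5), rep("DCB", 5)), "two levels")
})

test_that("chi-square DCB test holds its nominal size under the null", {
  set.seed(33)
  reps <- 2000
  rej <- 0
  for (i in seq_len(reps)) {
    g <- rep(c("high", "low"), each = 30)
    d <- ifelse(stats::runif(60) < 0.4, "DCB", "NDB")
    p <- tryCatch(dcb_contingency_test(g, d, method = "chi2")$p,
                  error = function(e) NA)
    if (!is.na(p) && p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.03)
  expect_lt(rej / reps, 0.07)
})

test_that("Spearman association uses midranks and the t-approximation", {
  expect_equal(spearman_assoc(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10))$rho, -1)
  # hand rank computation: d = (-1, 1, -1, 1, 0), rho = 1 - 6*4/120 = 0.8
  expect_equal(spearman_assoc(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_error(spearman_assoc(rep(1, 6), 1:6), "constant")
  expect_error(spearman_assoc(1:3, 1:3), "at least 4")
})

test_that("driver-gene comparison runs per-gene Fisher tests and skips genes without contrast", {
  flags <- rbind(
    GENE_A = rep(c(TRUE, FALSE), c(8, 32)),               # 8/20 low, 0/20 high
    GENE_B = rep(c(TRUE, FALSE, TRUE, FALSE), each = 10), # balanced 10 vs 10
    GENE_C = rep(TRUE, 40))                               # no contrast
  colnames(flags) <- paste0("P", 1:40)
  grp <- rep(c("low", "high"), each = 20)
  res <- compare_driver_genes(flags, grp)
  expect_identical(attr(res, "skipped"), "GENE_C")
  a <- res[res$gene == "GENE_A", ]
  expect_equal(a$p, fisher.test(matrix(c(0, 20, 8, 12), 2, 2))$p.value)
  expect_equal(a$mut_low, 8L)
  b <- res[res$gene == "GENE_B", ]
  expect_equal(b$p, 1)
  expect_equal(b$odds_ratio, 1, tolerance = 1e-6)
  expect_true(!is.unsorted(res$p))
})

test_that("Kruskal-Wallis wrapper matches the hand-computed rank statistic", {
  res <- kruskal_test(c(1, 2, 3, 4), rep(c("a", "b"), each = 2))
  expect_equal(res$h, 2.4)   # no ties: 12/(4*5) * (3+49)/2 ... rank-sum form
  expect_equal(res$df, 1L)
  res2 <- kruskal_test(rep(3, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(res2$h, 0)
  expect_equal(res2$p, 1)
  expect_error(kruskal_test(1:5, rep("a", 5)), "two groups")
})
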