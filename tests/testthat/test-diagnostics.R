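test_that("metric panel reproduces known operating points exactly", {
  m <- metrics_from_table(contingency_2x2(tp = 175, fp = 58, fn = 25,
                                          tn = 254))
  got <- setNames(m$percent, m$metric)
  expect_identical(got[["sensitivity"]], "87.5")
  expect_identical(got[["specificity"]], "81.4")
  expect_identical(got[["ppv"]], "75.1")
  expect_identical(got[["npv"]], "91.0")
  expect_identical(got[["accuracy"]], "83.8")

  m2 <- metrics_from_table(contingency_2x2(tp = 190, fp = 137, fn = 10,
                                           tn = 175))
  got2 <- setNames(m2$percent, m2$metric)
  expect_identical(got2[["sensitivity"]], "95.0")
  expect_identical(got2[["specificity"]], "56.1")

  perfect <- metrics_from_table(contingency_2x2(10, 0, 0, 10))
  expect_true(all(perfect$percent == "100.0"))
})

test_that("metric ratios are exact and zero denominators are flagged", {
  set.seed(7)
  for (i in 1:25) {
    cnt <- sample(0:40, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    t <- contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    m <- metrics_from_table(t)
    sens <- m$proportion[m$metric == "sensitivity"]
    if (!is.na(sens)) {
      expect_equal(sens * (t$tp + t$fn), as.numeric(t$tp),
                   tolerance = 1e-12)
    }
  }
  m0 <- metrics_from_table(contingency_2x2(tp = 0, fp = 5, fn = 0, tn = 5))
  expect_true("sensitivity" %in% attr(m0, "undefined"))
  expect_true(is.na(m0$proportion[m0$metric == "sensitivity"]))
  expect_false(is.na(m0$proportion[m0$metric == "specificity"]))
})

test_that("McNemar exact p equals binomial-mass summation", {
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  expect_equal(mcnemar_test(5, 5, mode = "exact")$p_value, 1)
  expect_equal(mcnemar_test(15, 5, mode = "exact")$p_value, 0.04138947,
               tolerance = 1e-6)
  for (b in 0:12) {
    for (cc in 0:12) {
      expect_equal(mcnemar_test(b, cc, mode = "exact")$p_value,
                   brute_mcnemar_exact(b, cc), tolerance = 1e-12)
    }
  }
  expect_error(mcnemar_test(-1, 3), "non-negative")
})

test_that("asymptotic McNemar matches stats::mcnemar.test", {
  # b != c: at b == c R's mcnemar.test caps the continuity correction at
  # |b - c| while this package applies the plain (|b - c| - 1)^2 form
  for (bc in list(c(30, 12), c(50, 49), c(17, 40))) {
    ours <- mcnemar_test(bc[1], bc[2], mode = "asymptotic")
    ref <- stats::mcnemar.test(matrix(c(5, bc[1], bc[2], 5), 2),
                               correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
  # auto switches at 25 discordant pairs
  expect_match(mcnemar_test(12, 12)$method, "exact")
  expect_match(mcnemar_test(13, 12)$method, "continuity")
})

test_that("Cohen's kappa matches the study pairings and its invariants", {
  k1 <- cohen_kappa(agreement_counts(pp = 141, pn = 33, np = 55, nn = 283))
  expect_equal(k1$kappa_rounded, 0.63)
  expect_identical(k1$band, "good")

  k2 <- cohen_kappa(agreement_counts(pp = 121, pn = 53, np = 46, nn = 292))
  expect_equal(k2$kappa, 0.5648, tolerance = 5e-5)
  expect_equal(k2$p_o, 413 / 512)
  expect_equal(k2$p_e, 145668 / 262144)

  expect_equal(cohen_kappa(agreement_counts(50, 0, 0, 50))$kappa, 1)

  set.seed(21)
  for (i in 1:20) {
    cnt <- sample(0:60, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    k <- cohen_kappa(agreement_counts(cnt[1], cnt[2], cnt[3], cnt[4]))
    # transposing the table (swapping the raters) leaves kappa unchanged
    kt <- cohen_kappa(agreement_counts(cnt[1], cnt[3], cnt[2], cnt[4]))
    expect_equal(k$kappa, kt$kappa)
    if (!is.na(k$kappa) && k$kappa == 1) {
      expect_true(cnt[2] == 0 && cnt[3] == 0)
    }
  }
})

test_that("kappa agrees with e1071::classAgreement", {
  skip_if_not_installed("e1071")
  set.seed(5)
  for (i in 1:10) {
    cnt <- sample(1:50, 4, replace = TRUE)
    ours <- cohen_kappa(agreement_counts(cnt[1], cnt[2], cnt[3], cnt[4]))
    ref <- e1071::classAgreement(matrix(cnt, 2, byrow = TRUE))$kappa
    expect_equal(ours$kappa, ref, tolerance = 1e-12)
  }
})

test_that("empirical ROC endpoints, ties and pairwise AUC identity hold", {
  truth6 <- rep(c("malignant", "benign"), each = 3)
  sep <- empirical_roc(c(5, 5, 4, 1, 0, 0), truth6)
  expect_equal(sep$auc, 1)
  flat <- empirical_roc(rep(2, 6), truth6)
  expect_equal(flat$auc, 0.5)
  # pos {3,2,2} vs neg {1,2,0}: 7 concordant pairs + 2 ties at 1/2 = 8/9
  ex <- empirical_roc(c(3, 2, 2, 1, 2, 0), truth6)
  expect_equal(ex$auc, brute_auc(c(3, 2, 2), c(1, 2, 0)))
  expect_equal(ex$auc, 8 / 9)
  expect_equal(ex$points$fpr[1], 0)
  expect_equal(ex$points$tpr[nrow(ex$points)], 1)
  expect_error(empirical_roc(1:3, rep("benign", 3)), "both classes")

  set.seed(33)
  for (i in 1:40) {
    inst <- random_roc_instance()
    roc <- empirical_roc(c(inst$pos, inst$neg),
                         rep(c("malignant", "benign"),
                             c(length(inst$pos), length(inst$neg))))
    expect_equal(roc$auc, brute_auc(inst$pos, inst$neg), tolerance = 1e-12)
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
  }
})

test_that("AUC agrees with pROC on random ordinal instances", {
  skip_if_not_installed("pROC")
  set.seed(91)
  for (i in 1:5) {
    inst <- random_roc_instance()
    if (length(unique(c(inst$pos, inst$neg))) < 2) next
    truth <- rep(c(1, 0), c(length(inst$pos), length(inst$neg)))
    ours <- empirical_roc(c(inst$pos, inst$neg), truth)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(truth, c(inst$pos, inst$neg),
                                          quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE matches direct substitution and shrinks with n", {
  expect_equal(hanley_mcneil_se(0.5, 1, 1), 0.5)
  expect_equal(hanley_mcneil_se(1, 50, 80), 0)
  expect_equal(hanley_mcneil_se(0.84, 200, 312), direct_hm_se(0.84, 200, 312))
  expect_equal(hanley_mcneil_se(0.84, 200, 312), 0.01915914,
               tolerance = 1e-6)
  for (A in c(0.6, 0.75, 0.9)) {
    se_small <- hanley_mcneil_se(A, 20, 30)
    se_big <- hanley_mcneil_se(A, 200, 300)
    expect_lt(se_big, se_small)
    expect_equal(hanley_mcneil_se(A, 37, 53), direct_hm_se(A, 37, 53))
  }
  expect_error(hanley_mcneil_se(1.2, 10, 10), "\\[0, 1\\]")
})

test_that("paired AUC z-test behaves at its closed-form anchors", {
  eq <- compare_auc_paired(0.8, 0.8, 0.02, 0.03, r = 0.4)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  se1 <- hanley_mcneil_se(0.84, 200, 312)
  se2 <- hanley_mcneil_se(0.76, 200, 312)
  tst <- compare_auc_paired(0.84, 0.76, se1, se2, r = 0)
  expect_equal(tst$statistic, 0.08 / sqrt(se1^2 + se2^2))
  expect_equal(tst$p_value, 2 * pnorm(-abs(tst$statistic)))

  # |z| strictly increases with the pairing correlation
  zs <- sapply(seq(0, 0.9, by = 0.1), function(r) {
    abs(compare_auc_paired(0.84, 0.76, se1, se2, r = r)$statistic)
  })
  expect_true(all(diff(zs) > 0))

  deg <- suppressWarnings(compare_auc_paired(0.8, 0.7, 0, 0))
  expect_true(is.na(deg$statistic))
})

test_that("rating-correlation estimator hits its fixed points", {
  set.seed(14)
  truth <- rep(c("malignant", "benign"), each = 1000)
  s <- c(rnorm(1000, 1), rnorm(1000))
  expect_equal(estimate_paired_auc_correlation(s, s, truth), 1)
  # independent scores: near zero after clipping at 0
  s2 <- c(sample(s[1:1000]), sample(s[1001:2000]))
  r_indep <- estimate_paired_auc_correlation(s, s2, truth)
  expect_lte(r_indep, 3 / sqrt(999))
  expect_equal(estimate_paired_auc_correlation(s, -s, truth), 0)
  expect_warning(
    estimate_paired_auc_correlation(s, c(rep(1, 1000), s[1001:2000]), truth),
    "constant scores")
})

test_that("Youden cutoff sits at the midpoint and matches brute force", {
  truth4 <- rep(c("malignant", "benign"), each = 2)
  perfect <- empirical_roc(c(1, 1, 0, 0), truth4)
  expect_equal(youden_optimal(perfect), list(cutoff = 0.5, j = 1))
  chance <- empirical_roc(c(1, 0, 1, 0), truth4)
  expect_equal(youden_optimal(chance)$j, 0)

  ex <- empirical_roc(c(4, 3, 3, 2, 1, 1, 0, 2),
                      rep(c("malignant", "benign"), each = 4))
  expect_equal(youden_optimal(ex), list(cutoff = 1.5, j = 0.75))

  flat <- empirical_roc(rep(1, 4), truth4)
  expect_error(youden_optimal(flat), "interior")

  set.seed(52)
  for (i in 1:30) {
    inst <- random_roc_instance()
    scores <- c(inst$pos, inst$neg)
    if (length(unique(scores)) < 2) next
    truth <- rep(c("malignant", "benign"),
                 c(length(inst$pos), length(inst$neg)))
    got <- youden_optimal(empirical_roc(scores, truth))
    want <- brute_youden(scores, truth)
    expect_equal(got$j, want$j, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("proportion comparison selects chi-square or exact correctly", {
  expect_equal(compare_proportions(5, 10, 5, 10)$p_value, 1)
  ex <- compare_proportions(10, 10, 0, 10)
  expect_match(ex$method, "fisher")
  expect_equal(ex$p_value, 1.083e-5, tolerance = 1e-3)
  big <- compare_proportions(44, 115, 27, 70)
  expect_match(big$method, "chi_square")
  expect_equal(big$estimate, c(44 / 115, 27 / 70))
  expect_error(compare_proportions(5, 0, 1, 10), "positive")
  expect_error(compare_proportions(11, 10, 1, 10), "within")
})
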