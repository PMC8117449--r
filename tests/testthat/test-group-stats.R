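# Group statistics: Mann-Whitney, Bonferroni, ROC/DeLong, logistic, index.

test_that("Mann-Whitney U and exact p match enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1) # 2 of the 20 assignments are as extreme

  same <- mann_whitney(c(5, 7, 9, 11), c(5, 7, 9, 11))
  expect_equal(same$U, 16 / 2) # n^2 / 2 under exact symmetry
  expect_gt(same$p, 0.9)

  ties <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(ties$U, 2) # midranks: 2 pairs at 1/2 each + 1 win

  expect_error(mann_whitney(numeric(0), 1:3), "observations")

  # cross-check the large-sample branch against wilcox.test
  set.seed(3)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  mw2 <- mann_whitney(x, y)
  wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw2$U, unname(wt$statistic))
  expect_equal(mw2$p, wt$p.value)

  # exact branch agrees with wilcox.test's exact p when there are no ties
  mw3 <- mann_whitney(c(1.2, 3.4, 5.1), c(2.2, 0.1, 6.3, 4.4))
  wt3 <- wilcox.test(c(1.2, 3.4, 5.1), c(2.2, 0.1, 6.3, 4.4), exact = TRUE)
  expect_equal(mw3$p, wt3$p.value)
})

test_that("Bonferroni thresholds are alpha/m", {
  expect_equal(bonferroni(0.05, 18), 0.05 / 18)
  expect_equal(bonferroni(0.05, 4), 0.0125)
  expect_equal(bonferroni(0.07, 1), 0.07)
  expect_error(bonferroni(0.05, 0), "m must be")
})

test_that("empirical AUC matches brute force and the U statistic", {
  r <- roc_analysis(c(1, 2, 3, 0, 1, 2),
                    rep(c("TPR", "TRC"), each = 3))
  expect_equal(r$auc, 7 / 9)

  perfect <- roc_analysis(c(10, 11, 12, 1, 2, 3),
                          rep(c("TPR", "TRC"), each = 3))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)

  set.seed(41)
  for (i in 1:20) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    pos <- round(rnorm(n1, 1), 1); neg <- round(rnorm(n0), 1)
    vals <- c(pos, neg)
    labs <- c(rep("TPR", n1), rep("TRC", n0))
    r2 <- roc_analysis(vals, labs)
    bf <- brute_force_auc(pos, neg)
    expect_equal(r2$auc, max(bf, 1 - bf), tolerance = 1e-12)
    # AUC = U / (n1 n2) identity with the Mann-Whitney statistic
    expect_equal(mann_whitney(pos, neg)$U / (n1 * n0), bf,
                 tolerance = 1e-12)
  }

  expect_error(roc_analysis(1:5, rep("TPR", 5)), "both classes")
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(42)
  vals <- rnorm(400)
  labs <- sample(rep(c("TPR", "TRC"), each = 200))
  r <- roc_analysis(vals, labs)
  expect_lt(abs(r$auc - 0.5), 0.06)
  expect_gt(r$p_value, 0.01)
})

test_that("reported accuracy equals its prevalence-weighted identity", {
  set.seed(43)
  for (i in 1:10) {
    vals <- rnorm(60)
    labs <- sample(rep(c("TPR", "TRC"), c(35, 25)))
    vals[labs == "TPR"] <- vals[labs == "TPR"] + runif(1, 0, 2)
    r <- roc_analysis(vals, labs)
    expect_equal(r$accuracy,
                 (r$sensitivity * 35 + r$specificity * 25) / 60,
                 tolerance = 1e-9)
  }
})

test_that("optimal cutoff maximizes Youden J with ties toward specificity", {
  # two cutoffs share J; the reported one has the higher specificity
  pos <- c(2, 3, 4); neg <- c(0, 1, 2.5)
  r <- roc_analysis(c(pos, neg), rep(c("TPR", "TRC"), each = 3))
  curve <- r$curve
  J <- curve$sensitivity + curve$specificity - 1
  expect_equal(r$sensitivity / 100 + r$specificity / 100 - 1, max(J),
               tolerance = 1e-12)
  best <- which(J >= max(J) - 1e-12)
  expect_equal(r$specificity / 100, max(curve$specificity[best]))
})

test_that("our ROC and DeLong agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(44)
  labs <- rep(c("TPR", "TRC"), c(40, 30))
  v1 <- rnorm(70) + (labs == "TPR") * 1.2
  v2 <- v1 * 0.6 + rnorm(70, 0, 0.8)
  r1 <- roc_analysis(v1, labs)
  pr1 <- pROC::roc(labs, v1, levels = c("TRC", "TPR"), direction = "<",
                   quiet = TRUE)
  expect_equal(r1$auc, as.numeric(pROC::auc(pr1)), tolerance = 1e-12)

  dc <- delong_compare(v1, v2, labs)
  pr2 <- pROC::roc(labs, v2, levels = c("TRC", "TPR"), direction = "<",
                   quiet = TRUE)
  pt <- pROC::roc.test(pr1, pr2, method = "delong")
  expect_equal(dc$p, pt$p.value, tolerance = 1e-10)
  expect_equal(dc$auc1 - dc$auc2,
               as.numeric(pROC::auc(pr1)) - as.numeric(pROC::auc(pr2)),
               tolerance = 1e-12)
})

test_that("DeLong comparison handles identity and independence", {
  labs <- rep(c("TPR", "TRC"), c(12, 10))
  set.seed(45)
  v <- rnorm(22) + (labs == "TPR")
  self <- delong_compare(v, v, labs)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  expect_equal(self$auc1, roc_analysis(v, labs)$auc)

  expect_error(delong_compare(v, v[-1], labs[-1][-1]), "paired")

  # independent markers: the covariance term averages to ~0, so the
  # variance of the AUC difference matches the sum of the variances
  covs <- replicate(300, {
    a <- rnorm(22); b <- rnorm(22)
    pa <- a[labs == "TPR"]; na_ <- a[labs == "TRC"]
    pb <- b[labs == "TPR"]; nb <- b[labs == "TRC"]
    v10a <- vapply(pa, function(x) mean(x > na_) + 0.5 * mean(x == na_),
                   numeric(1))
    v10b <- vapply(pb, function(x) mean(x > nb) + 0.5 * mean(x == nb),
                   numeric(1))
    cov(v10a, v10b)
  })
  expect_lt(abs(mean(covs)), 0.01)
})

test_that("logistic fits recover closed-form and simulated coefficients", {
  # saturated 2x2 table: coefficient = log odds ratio = log(36)
  dat <- tibble::tibble(
    group = c(rep("TPR", 10), rep("TRC", 10)),
    x = c(rep(1, 9), 0, rep(1, 2), rep(0, 8))
  )
  lf <- logistic_fit(dat, "x")
  expect_equal(unname(lf$coefficients["x"]), log(36), tolerance = 1e-6)
  expect_false(lf$separation)

  # null predictor: coefficient near zero at large n
  set.seed(46)
  dat2 <- tibble::tibble(group = rep(c("TPR", "TRC"), each = 1000),
                         x = rnorm(2000))
  lf2 <- logistic_fit(dat2, "x")
  expect_lt(abs(unname(lf2$coefficients["x"])), 0.15)

  # recovery within 3 standard errors on data from a known model
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- -0.5 + 1.2 * x1 - 0.7 * x2
  y <- rbinom(n, 1, plogis(eta))
  dat3 <- tibble::tibble(group = ifelse(y == 1, "TPR", "TRC"),
                         a = x1, b = x2)
  lf3 <- logistic_fit(dat3, c("a", "b"))
  td <- tidy(lf3)
  expect_lt(abs(td$estimate[td$term == "a"] - 1.2) /
              td$std_error[td$term == "a"], 3)
  expect_lt(abs(td$estimate[td$term == "b"] + 0.7) /
              td$std_error[td$term == "b"], 3)

  # perfectly separating predictor raises the flag
  dat4 <- tibble::tibble(group = rep(c("TPR", "TRC"), each = 10),
                         x = c(rnorm(10, 10), rnorm(10, -10)))
  expect_true(logistic_fit(dat4, "x")$separation)

  # collinear design is rejected
  dat5 <- dat3; dat5$c <- dat5$a * 2
  expect_error(logistic_fit(dat5, c("a", "c")), "rank-deficient")
})

test_that("the FET-DKI index follows its closed form and decision rule", {
  idx <- fet_dki_index(c(3.30, 2.50, 0), c(0.78, 0.61, 0))
  expect_equal(idx$index, c(4.7 * 3.30 + 39.2 * 0.78,
                            4.7 * 2.50 + 39.2 * 0.61, 0))
  expect_equal(idx$class, c("TPR", "TRC", "TRC"))

  # strictly increasing in each argument
  set.seed(47)
  t0 <- runif(20, 1, 4); k0 <- runif(20, 0.4, 1)
  expect_true(all(fet_dki_index(t0 + 0.01, k0)$index >
                    fet_dki_index(t0, k0)$index))
  expect_true(all(fet_dki_index(t0, k0 + 0.01)$index >
                    fet_dki_index(t0, k0)$index))

  # exactly at the threshold the call is the treatment-related class
  expect_equal(fet_dki_index(41 / 4.7, 0)$class, "TRC")
  expect_true(is.na(fet_dki_index(NA_real_, 0.7)$class))
})

test_that("the full group analysis runs and controls family-wise error", {
  cohort <- simulate_feature_cohort(cohort_sim_config(seed = 21))
  ga <- run_group_analysis(cohort)
  expect_equal(nrow(ga$comparisons), 22L)
  expect_true(all(ga$comparisons$threshold[ga$comparisons$panel == "dtkt"] ==
                    0.05 / 18))
  expect_true(all(ga$comparisons$threshold[ga$comparisons$panel == "pet"] ==
                    0.0125))
  expect_equal(nrow(ga$index_calls), 32L)

  single <- dplyr::filter(cohort, group == "TPR")
  expect_error(run_group_analysis(single), "two groups")

  # permuted labels: the Bonferroni screen stays quiet in most replicates
  set.seed(22)
  fwer_hits <- replicate(50, {
    perm <- cohort
    perm$group <- sample(perm$group)
    gap <- run_group_analysis(perm)
    any(gap$comparisons$category == "significant")
  })
  expect_lte(mean(fwer_hits), 0.12) # 99% binomial envelope of alpha = 0.05
})
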