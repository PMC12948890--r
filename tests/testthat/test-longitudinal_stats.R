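# Repeated-measures ANOVA with sphericity handling, Friedman fallback and
# normality screening.

ref_anova <- function(x) {
  # independent reference: car::Anova on the multivariate linear model
  mlm <- stats::lm(x ~ 1)
  idata <- data.frame(tp = factor(seq_len(ncol(x))))
  s <- suppressWarnings(   # car warns when clipping HF eps > 1, as we do
    summary(car::Anova(mlm, idata = idata, idesign = ~tp, type = 3),
            multivariate = FALSE))
  list(F = s$univariate.tests["tp", "F value"],
       p = s$univariate.tests["tp", "Pr(>F)"],
       W = s$sphericity.tests["tp", "Test statistic"],
       mauchly_p = s$sphericity.tests["tp", "p-value"],
       gg = s$pval.adjustments["tp", "GG eps"],
       hf = min(1, s$pval.adjustments["tp", "HF eps"]),
       p_gg = s$pval.adjustments["tp", "Pr(>F[GG])"])
}

test_that("identical columns give F = 0 and pairwise p = 1", {
  x <- matrix(rep(c(40, 42, 41, 43, 39), 3), ncol = 3)
  f <- rm_anova(x)
  expect_equal(f$F, 0)
  expect_equal(f$p_uncorrected, 1)
  expect_true(all(f$pairwise$p_bonferroni == 1))
  fr <- friedman_rm(x)
  expect_equal(fr$chi2, 0)
  expect_equal(fr$p, 1)
})

test_that("RM-ANOVA agrees with the car reference within 1e-8", {
  set.seed(20250823)
  for (rep_i in 1:4) {
    x <- matrix(rnorm(30, mean = rep(c(43, 42, 43), each = 10),
                      sd = runif(1, 1, 3)), 10, 3)
    f <- rm_anova(x)
    r <- ref_anova(x)
    expect_equal(f$F, r$F, tolerance = 1e-8)
    expect_equal(f$p_uncorrected, r$p, tolerance = 1e-8)
    expect_equal(f$mauchly_W, r$W, tolerance = 1e-8)
    expect_equal(f$mauchly_p, r$mauchly_p, tolerance = 1e-8)
    expect_equal(f$epsilon_gg, r$gg, tolerance = 1e-8)
    expect_equal(f$epsilon_hf, r$hf, tolerance = 1e-8)
    # Mauchly also cross-checked against stats::mauchly.test
    mt <- stats::mauchly.test(stats::lm(x ~ 1), X = ~1)
    expect_equal(unname(f$mauchly_W), unname(mt$statistic), tolerance = 1e-8)
  }
})

test_that("two-condition RM-ANOVA equals the squared paired t statistic", {
  set.seed(7)
  x <- matrix(rnorm(24, mean = c(40, 41), sd = 2), 12, 2, byrow = TRUE)
  f <- rm_anova(x)
  tt <- t.test(x[, 1], x[, 2], paired = TRUE)
  expect_equal(f$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(f$p_uncorrected, tt$p.value, tolerance = 1e-10)
})

test_that("planned Bonferroni comparisons are rest-vs-21k and rest-vs-control", {
  set.seed(11)
  x <- matrix(rnorm(30, rep(c(43, 41, 43), each = 10), 1), 10, 3)
  colnames(x) <- c("rest", "21k", "control")
  f <- rm_anova(x)
  expect_equal(nrow(f$pairwise), 2)
  expect_equal(f$pairwise$contrast, c("rest vs 21k", "rest vs control"))
  expect_equal(f$pairwise$p_bonferroni,
               pmin(1, f$pairwise$p_raw * 2))
  f3 <- rm_anova(x, all_pairs = TRUE)
  expect_equal(nrow(f3$pairwise), 3)
  expect_equal(f3$pairwise$p_bonferroni, pmin(1, f3$pairwise$p_raw * 3))
  # adjusted p monotone in the raw p
  expect_equal(order(f3$pairwise$p_bonferroni), order(f3$pairwise$p_raw))
  expect_error(rm_anova(x[1:2, ]), "3 samples")
})

test_that("epsilon approaches 1 under compound symmetry", {
  set.seed(99)
  eps <- replicate(200, {
    subj <- rnorm(50, 0, 2)
    x <- matrix(subj, 50, 3) + matrix(rnorm(150), 50, 3)
    rm_anova(x)$epsilon_gg
  })
  expect_gt(median(eps), 0.9)
})

test_that("Friedman matches hand-computed ranks on a 4x3 table", {
  x <- matrix(c(7, 9, 8,
                6, 5, 4,
                9, 7, 6,
                8, 5, 6), 4, 3, byrow = TRUE)
  # hand ranks per row: (1,3,2),(3,2,1),(3,2,1),(3,1,2); R = (10,8,6)
  # chi2 = 12/(4*3*4) * (100+64+36) - 3*4*4 = 2
  fr <- friedman_rm(x)
  expect_equal(fr$chi2, 2)
  expect_equal(fr$df, 2)
  expect_equal(fr$p, pchisq(2, 2, lower.tail = FALSE))
  # tie-free case must equal the base implementation
  bt <- stats::friedman.test(x)
  expect_equal(fr$chi2, unname(bt$statistic))
  expect_equal(fr$p, bt$p.value)
})

test_that("Friedman handles constant rows via midranks", {
  x <- rbind(c(5, 5, 5), c(4, 6, 5), c(3, 5, 4), c(6, 6, 6))
  fr <- friedman_rm(x)
  expect_true(is.finite(fr$chi2))
  expect_gte(fr$chi2, 0)
})

test_that("Friedman detects a monotone shift", {
  set.seed(123)
  hits <- replicate(200, {
    x <- matrix(rnorm(120, 40, 1), 40, 3)
    x[, 2] <- x[, 2] + 1   # 1 SD shift
    friedman_rm(x)$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("normality screen passes normal data and fails exponential data", {
  set.seed(2024)
  pass_h0 <- replicate(100, {
    all(normality_screen(matrix(rnorm(200), 200, 1))$pass)
  })
  expect_gte(mean(pass_h0), 0.90)
  fail_h1 <- replicate(100, {
    !all(normality_screen(matrix(rexp(200), 200, 1))$pass)
  })
  expect_gte(mean(fail_h1), 0.90)
  scr <- normality_screen(matrix(rep(5, 10), 10, 1))
  expect_false(scr$pass)
  expect_equal(scr$reason, "zero variance")
})

test_that("the combined decision procedure holds its type-I error", {
  set.seed(31415)
  rejections <- replicate(1000, {
    x <- matrix(rnorm(57, 43, 2.5), 19, 3)
    timepoint_test(x)$p_omnibus < 0.05
  })
  expect_lte(mean(rejections), 0.07)
})
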