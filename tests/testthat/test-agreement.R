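test_that("ICC(2,1) equals the aov mean-squares formula on random tables", {
  set.seed(61)
  for (i in 1:60) {
    a <- rnorm(6); b <- rnorm(6)
    got <- icc_2_1(a, b)
    expect_lt(abs(got$icc - oracle_icc21(a, b)), 1e-10)
  }
})

test_that("ICC(2,1) reaches 1 for identical columns and ~0 for independent ones", {
  a <- c(0.5, 0.7, 0.9, 0.4, 0.8)
  expect_equal(icc_2_1(a, a)$icc, 1)
  expect_equal(icc_2_1(a, a)$label, "excellent")
  set.seed(62)
  x <- rnorm(500); y <- rnorm(500)
  r <- icc_2_1(x, y)
  expect_lt(abs(r$icc), 0.1)
  expect_true(r$ci[1] < 0 && r$ci[2] > r$icc)
  expect_equal(r$label, "poor")
  expect_error(icc_2_1(rep(1, 5), rep(1, 5)), "zero total variance")
  expect_error(icc_2_1(1:2, 1:2), "at least 3")
})

test_that("ICC(2,1) matches the closed-form variance-component ratio", {
  # y_ij = subject_i + rater_j + noise: ICC -> s_b^2 / (s_b^2 + s_r^2 + s_e^2)
  set.seed(63)
  n <- 4000
  sb <- 0.5; sr <- 0.05; se <- 0.1
  subj <- rnorm(n, 0, sb)
  a <- subj + rnorm(n, 0, se)
  b <- subj + sr + rnorm(n, 0, se)
  # column variance component for two raters shifted by 0 and sr: sr^2 / 2
  want <- sb^2 / (sb^2 + sr^2 / 2 + se^2)
  expect_lt(abs(icc_2_1(a, b)$icc - want), 0.02)
})

test_that("Cronbach's alpha follows the two-item formula", {
  a <- c(0.5, 0.7, 0.9, 0.4)
  expect_equal(cronbach_alpha(a, a), 1)
  expect_lt(cronbach_alpha(a, -2 * a + 3), 0)  # anti-correlated: negative allowed
  # hand-computed 4-row example: var(a) = 0.0466667, var(b) = 0.0672917,
  # var(a + b) = 0.2239583 -> alpha = 2 * (1 - 0.1139583 / 0.2239583)
  b <- c(0.6, 0.9, 1.0, 0.45)
  expect_equal(cronbach_alpha(a, b), 2 * (1 - (var(a) + var(b)) / var(a + b)))
  expect_equal(cronbach_alpha(a, b), 0.9824561, tolerance = 1e-6)
  expect_error(cronbach_alpha(c(1, 1), c(-1, -1)), "zero total")
})

test_that("Bland-Altman recovers an exact shift with zero-width limits", {
  a <- c(0.5, 0.7, 0.9, 0.4, 0.8)
  ba <- bland_altman(a + 0.5, a)
  expect_equal(ba$bias, 0.5)
  expect_equal(ba$loa_low, ba$loa_high)
  expect_equal(ba$sd_diff, 0)
  # proportional difference: r2 = 1 and the flag fires
  ba2 <- bland_altman(a * 1.1, a * 0.9)
  expect_equal(ba2$regression$r2, 1)
  expect_true(ba2$proportional_bias)
  # constant means: regression undefined, flagged NA
  ba3 <- bland_altman(c(1, 2, 3), c(3, 2, 1))
  expect_true(is.na(ba3$proportional_bias))
})

test_that("Bland-Altman consistency: bias -> b and LoA half-width -> 1.96 sigma", {
  set.seed(64)
  n <- 10000
  a <- rnorm(n, 0.6, 0.1)
  b <- a + 0.016 + rnorm(n, 0, 0.009)
  ba <- bland_altman(a, b)
  expect_lt(abs(ba$bias - (-0.016)) / 0.016, 0.02)
  half <- (ba$loa_high - ba$loa_low) / 2
  expect_lt(abs(half - 1.96 * 0.009) / (1.96 * 0.009), 0.02)
  expect_lt(ba$p_value, 0.01)
})

test_that("SWC and SEM give the printed usefulness ratios", {
  # ratio recomputation from reported SWC and SEM values
  expect_equal(usefulness_ratio(0.02, 0.010)$ratio, 2.00)
  expect_equal(usefulness_ratio(0.02, 0.010)$label, "good")
  expect_equal(usefulness_ratio(17.75, 13.17)$ratio, 1.3478, tolerance = 1e-4)
  expect_equal(usefulness_ratio(32.98, 23.89)$ratio, 1.3805, tolerance = 1e-4)
  expect_equal(usefulness_ratio(0.5, 1)$label, "marginal")
  expect_equal(usefulness_ratio(1, 1)$label, "satisfactory")
})

test_that("SWC is 20% of the between-subject SD and the ratio is scale-invariant", {
  set.seed(65)
  d <- generate_paired_measurements(12, 6, between_sd = 0.1, seed = 5)
  u <- swc_sem_usefulness(d$a, d$b, d$subject)
  subj_means <- tapply((d$a + d$b) / 2, d$subject, mean)
  expect_equal(u$swc, 0.2 * sd(subj_means))
  expect_equal(u$sem, sd(d$a - d$b) / sqrt(2))
  # scale invariance of the ratio
  k <- 7.3
  uk <- swc_sem_usefulness(k * d$a, k * d$b, d$subject)
  expect_equal(uk$ratio, u$ratio)
  # anova-based SEM alternative stays close for this design
  ua <- swc_sem_usefulness(d$a, d$b, d$subject, sem_method = "anova")
  expect_gt(ua$sem, 0)
  expect_error(swc_sem_usefulness(d$a, d$b, rep(1, nrow(d))), "single subject")
})

test_that("Pearson r with SEE matches hand computation", {
  a <- c(1, 2, 3, 4, 5)
  p <- pearson_with_see(2 * a + 1, a)
  expect_equal(p$r, 1)
  expect_equal(p$see, 0)
  expect_equal(p$r_label, "practically perfect")
  # textbook 5-point data, hand-computed r and SEE
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  p2 <- pearson_with_see(y, x)
  expect_equal(p2$r, 0.8, tolerance = 1e-12)
  # SEE = sqrt(SSE / (n - 2)); SSE = (1 - r^2) * Syy = 0.36 * 10 = 3.6
  expect_equal(p2$see, sqrt(3.6 / 3), tolerance = 1e-12)
  expect_true(p2$r_ci[1] < 0.8 && p2$r_ci[2] > 0.8)
  # standardized SEE of 0.08 labels trivial
  expect_equal(vbtrack:::see_label(0.08), "trivial")
  expect_equal(vbtrack:::see_label(0.45), "moderate")
  expect_error(pearson_with_see(rep(1, 5), 1:5), "zero variance")
})

test_that("the full agreement report assembles all statistics coherently", {
  d <- generate_paired_measurements(20, 8, seed = 9)
  rep <- agreement_report(d$a, d$b, d$subject, variable = "velocity (m/s)")
  expect_s3_class(rep, "agreement_report")
  expect_true(rep$icc$icc > 0.8)
  expect_lt(rep$bland_altman$loa_low, rep$bland_altman$bias)
  expect_gt(rep$bland_altman$loa_high, rep$bland_altman$bias)
  expect_equal(rep$usefulness$ratio, rep$usefulness$swc / rep$usefulness$sem)
  expect_output(print(rep), "ICC")
  path <- tempfile(fileext = ".json")
  write_agreement_report(rep, path)
  expect_true(jsonlite::validate(readChar(path, file.size(path))))
})
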