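make_average <- function(mat, times_ms, labels) {
  structure(list(mean = mat, sem = mat * 0, n_trials = 10,
                 times_ms = times_ms, labels = labels,
                 condition = "phasic", subject_id = 1),
            class = "hep_average")
}

test_that("windowed mean amplitude is the plain submatrix mean", {
  times <- seq(-200, 798, by = 2)
  mat <- matrix(3, 2, length(times), dimnames = list(c("Fz", "Cz"), NULL))
  av <- make_average(mat, times, c("Fz", "Cz"))
  expect_equal(window_mean_amplitude(av, c(400, 600)), 3)

  # linear ramp 0..10 over the window: midpoint 5
  sel <- times >= 400 & times <= 600
  mat2 <- mat
  mat2["Fz", sel] <- seq(0, 10, length.out = sum(sel))
  av2 <- make_average(mat2, times, c("Fz", "Cz"))
  expect_equal(window_mean_amplitude(av2, c(400, 600), "Fz"), 5)

  set.seed(61)
  mat3 <- matrix(rnorm(2 * length(times)), 2,
                 dimnames = list(c("Fz", "Cz"), NULL))
  av3 <- make_average(mat3, times, c("Fz", "Cz"))
  expect_equal(window_mean_amplitude(av3, c(350, 650)),
               mean(mat3[, times >= 350 & times <= 650]))

  expect_error(window_mean_amplitude(av3, c(400, 600), character(0)),
               "empty")
  expect_error(window_mean_amplitude(av3, c(400, 600), "Pz"), "unknown")
})

test_that("scalar condition contrast gates on normality and matches
           its oracles", {
  x <- c(5, 6, 7, 8, 9, 10, 11, 12)
  expect_equal(compare_conditions_scalar(x, x)$p, 1)
  expect_equal(compare_conditions_scalar(x, x)$statistic, 0)

  # normal differences: the paired-t branch, textbook statistic
  set.seed(62)
  y <- x + rnorm(8, 0.5, 0.3)
  res <- compare_conditions_scalar(y, x)
  expect_equal(res$test, "paired t")
  expect_equal(res$statistic, oracle_paired_t(y, x), tolerance = 1e-12)
  expect_equal(res$effect_size, mean(y - x) / sd(y - x), tolerance = 1e-12)

  # heavy-tailed differences trip the gate into the exact Wilcoxon
  d_heavy <- c(0.05, -0.02, 0.04, -0.03, 0.06, 0.01, 9, 12)
  res2 <- compare_conditions_scalar(x + d_heavy, x)
  expect_equal(res2$test, "wilcoxon signed-rank")
  expect_equal(res2$p, oracle_signrank_p(d_heavy), tolerance = 1e-12)

  expect_error(compare_conditions_scalar(1:2, 1:2), "3")
})

test_that("repeated-measures ANCOVA collapses to the paired t without
           covariate information", {
  set.seed(63)
  hp <- rnorm(12, 1, 1)
  ht <- rnorm(12, 0, 1)
  res <- rm_ancova_condition(hp, ht, rep(0, 12))
  t2 <- oracle_paired_t(hp, ht)^2
  expect_lt(abs(res$F - t2) / t2, 1e-9)
  expect_equal(res$df, c(1, 11))
  expect_true(res$covariate_constant)

  # identical conditions: no effect
  res0 <- rm_ancova_condition(hp, hp, rnorm(12))
  expect_lt(res0$F, 1e-20)
  expect_gt(res0$p, 0.99)

  # informative covariate changes the df and reports its own effect
  cov <- hp - ht + rnorm(12, 0, 0.1)
  res1 <- rm_ancova_condition(hp, ht, cov)
  expect_equal(res1$df, c(1, 10))
  expect_false(is.na(res1$covariate$F))
  expect_gt(res1$covariate$partial_eta_sq, 0.5)

  expect_error(rm_ancova_condition(hp[1:3], ht[1:3], cov[1:3]), "4")
})

test_that("ANCOVA recovers a known adjusted condition effect", {
  # difference scores = effect + b * covariate + noise; the intercept
  # test evaluated at the covariate mean recovers the effect
  set.seed(64)
  reps <- 200
  eff_est <- p_sig <- numeric(reps)
  for (i in seq_len(reps)) {
    n <- 16
    cov <- rnorm(n)
    d <- 0.8 + 0.5 * cov + rnorm(n, 0, 0.6)
    ht <- rnorm(n)
    res <- rm_ancova_condition(ht + d, ht, cov)
    p_sig[i] <- res$p < 0.05
    eff_est[i] <- res$partial_eta_sq
  }
  # strong true effect: high power and substantial partial eta squared
  expect_gt(mean(p_sig), 0.9)
  expect_gt(mean(eff_est), 0.4)
})

test_that("contrast correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_contrast_correlation(x, x)$r, 1)
  y <- c(1, -1, -1, 1)  # orthogonal to the centred ramp
  expect_equal(pearson_contrast_correlation(x, y)$r, 0)

  set.seed(65)
  a <- rnorm(15); b <- rnorm(15)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_contrast_correlation(a, b)$r, r_oracle,
               tolerance = 1e-12)

  expect_error(pearson_contrast_correlation(rep(1, 5), rnorm(5)),
               "zero variance")
})

test_that("the normality gate is a pure function of the differences", {
  set.seed(66)
  x <- rnorm(10); y <- rnorm(10)
  r1 <- compare_conditions_scalar(x, y)
  r2 <- compare_conditions_scalar(x + 5, y + 5)  # same differences
  expect_identical(r1$test, r2$test)
  expect_equal(r1$p, r2$p)
})
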