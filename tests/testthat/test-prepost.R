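test_that("normality gate routes Gaussian and skewed differences sensibly", {
  set.seed(21)
  gauss <- mean(replicate(100, normality_gate(rnorm(40)) == "parametric"))
  expect_gte(gauss, 0.9)
  skew <- mean(replicate(100, normality_gate(rexp(18)) == "nonparametric"))
  expect_gt(skew, 0.5)
  g <- normality_gate(rep(1, 10))
  expect_equal(as.character(g), "nonparametric")
  expect_true(attr(g, "zero_variance"))
  expect_error(normality_gate(c(1, 2)), "n >= 3")
})

test_that("identical paired samples give zero difference and p = 1", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  res <- paired_compare(x, x)
  expect_equal(res$difference, 0)
  expect_equal(res$p, 1)
  expect_equal(res$test, "wilcoxon")  # zero-variance branch
})

test_that("parametric branch reports t, Cohen's d and mean descriptives", {
  set.seed(31)
  m0 <- rnorm(18, 10, 2); m1 <- m0 - rnorm(18, 1, 0.5)
  res <- paired_compare(m0, m1)
  expect_equal(res$test, "paired_t")
  expect_equal(res$effect_d, res$statistic / sqrt(18))
  expect_equal(res$m0_center, mean(m0))
  expect_equal(res$difference, mean(m0 - m1))
  tt <- t.test(m0, m1, paired = TRUE)
  expect_equal(res$p, tt$p.value)
  expect_error(paired_compare(m0, m1[-1]), "paired")
})

test_that("nonparametric branch reports median descriptives without d", {
  set.seed(41)
  m0 <- rexp(20); m1 <- m0 * rexp(20)   # heavily skewed differences
  res <- paired_compare(m0, m1)
  if (res$test == "wilcoxon") {
    expect_true(is.na(res$effect_d))
    expect_equal(res$m0_center, median(m0))
    expect_equal(res$difference, median(m0 - m1))
  }
  # Pratt handling with zeros present: statistic and sane p
  d0 <- c(0, 0, 1.5, -0.5, 2.5, 3.5, 1, 2, 3, 4)
  res0 <- paired_compare(d0, numeric(10))
  expect_true(res0$p > 0 && res0$p <= 1)
})

test_that("gate + test pipeline holds its nominal type-I error (small sweep)", {
  set.seed(51)
  rej <- mean(replicate(400, paired_compare(rnorm(18), rnorm(18))$p < 0.05))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("empirical power at a 1 SD shift matches the noncentral-t prediction", {
  set.seed(61)
  n <- 17
  rej <- mean(replicate(400, {
    d <- rnorm(n, mean = 1, sd = 1)
    t.test(d, alternative = "greater")$p.value < 0.05
  }))
  pred <- paired_t_power(n, 1, 0.05, "one")
  expect_lt(abs(rej - pred), 3 * sqrt(pred * (1 - pred) / 400) + 0.01)
})

test_that("Cohen's d from t reproduces printed worked examples", {
  expect_equal(round(cohens_d_from_t(6.091, 18), 2), 1.44)
  expect_equal(round(cohens_d_from_t(2.732, 18), 2), 0.64)
  expect_equal(cohens_d_from_t(0, 10), 0)
  # antisymmetric in t
  expect_equal(cohens_d_from_t(-2.5, 12), -cohens_d_from_t(2.5, 12))
  expect_error(cohens_d_from_t(1, 1), "n >= 2")
})

test_that("design-stage effect size from MCID and SD", {
  expect_equal(round(effect_size_from_mcid(13.2, 20.71), 5), 0.63737)
  expect_equal(effect_size_from_mcid(2.7, 1.92), 1.40625)
  expect_equal(effect_size_from_mcid(0, 3), 0)
  expect_error(effect_size_from_mcid(1, 0), "sd")
})

test_that("required sample size matches the power oracle across effect sizes", {
  expect_equal(required_sample_size(0.63737, 0.05, 0.80, "one"), 17L)
  # independent oracle: exhaustive noncentral-t search via power.t.test
  for (d in c(0.3, 0.5, 0.8, 1.2, 2.0)) {
    want <- ceiling(stats::power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                        power = 0.80, type = "paired",
                                        alternative = "one.sided")$n - 1e-9)
    expect_equal(required_sample_size(d, 0.05, 0.80, "one"), want)
  }
  # monotone: required n non-increasing in d
  ns <- vapply(seq(0.3, 2, by = 0.1),
               function(d) required_sample_size(d, 0.05, 0.8, "one"), integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(required_sample_size(0), "d")
})

test_that("branch descriptives follow the mean/SD vs median/IQR convention", {
  expect_equal(summarize_outcome(c(1, 2, 3), "parametric"),
               c(center = 2, spread = 1))
  s <- summarize_outcome(c(1, 2, 3, 100), "nonparametric")
  expect_equal(s[["center"]], 2.5)
  expect_equal(s[["spread"]], stats::IQR(c(1, 2, 3, 100), type = 7))
  expect_error(summarize_outcome(numeric(0), "parametric"), "empty")
  expect_error(summarize_outcome(5, "parametric"), "single")
})

test_that("effect-size banding follows the stated cut-points", {
  expect_equal(effect_size_band(c(0.1, 0.5, 0.64, 1.44)),
               c("small", "moderate", "moderate", "large"))
})

test_that("prepost_table compares every outcome with optional Holm adjustment", {
  set.seed(71)
  m0 <- data.frame(a = rnorm(12), b = rnorm(12, 2))
  m1 <- data.frame(a = rnorm(12, 1), b = rnorm(12, 2))
  tab <- prepost_table(m0, m1)
  expect_equal(tab$outcome, c("a", "b"))
  tab_h <- prepost_table(m0, m1, adjust = "holm")
  expect_true(all(tab_h$p_adj >= tab_h$p))
})
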