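rand_2x2 <- function() matrix(rpois(4, 8) + 1L, 2)

test_that("CMH statistic matches direct formula and mantelhaen.test", {
  single <- cmh_test(list(matrix(c(10, 0, 0, 10), 2)))
  expect_equal(single$statistic, 19)
  expect_equal(single$df, 1L)
  # duplicated stratum doubles numerator root and variance: statistic doubles
  dup <- cmh_test(list(matrix(c(10, 0, 0, 10), 2), matrix(c(10, 0, 0, 10), 2)))
  expect_equal(dup$statistic, 38)
  # no-association strata give a near-zero statistic
  flat <- cmh_test(list(matrix(c(8, 8, 8, 8), 2), matrix(c(5, 5, 5, 5), 2)))
  expect_lt(flat$statistic, 1e-10)
  set.seed(14)
  for (i in 1:50) {
    K <- sample(1:5, 1)
    tabs <- replicate(K, rand_2x2(), simplify = FALSE)
    got <- cmh_test(tabs)
    expect_equal(got$statistic, brute_cmh(tabs))
    if (K >= 2) {  # mantelhaen.test needs at least two strata
      arr <- array(unlist(tabs), dim = c(2, 2, K))
      ref <- stats::mantelhaen.test(arr, correct = FALSE)
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p, ref$p.value)
    }
  }
  # zero-margin strata are skipped; all-degenerate input errors
  expect_warning(r <- cmh_test(list(matrix(c(5, 3, 2, 6), 2),
                                    matrix(c(0, 0, 4, 6), 2))), "skipped")
  expect_equal(r$k_used, 1L)
  expect_error(suppressWarnings(cmh_test(list(matrix(c(0, 0, 4, 6), 2)))),
               "degenerate")
})

test_that("general I x J x K association is supported through the same interface", {
  set.seed(3)
  tabs <- replicate(3, matrix(rpois(9, 6) + 1L, 3), simplify = FALSE)
  got <- cmh_test(tabs)
  ref <- stats::mantelhaen.test(array(unlist(tabs), c(3, 3, 3)),
                                correct = FALSE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni(c(0.9, 0.9)), c(1, 1))
  set.seed(1)
  p <- runif(7)
  expect_equal(bonferroni(p), p.adjust(p, "bonferroni"))
})

test_that("MH score chi-square matches the weighted-correlation oracle", {
  d <- diag(c(7, 7, 7))
  expect_equal(mh_chisq_frequencies(d)$statistic, sum(d) - 1)
  ind <- outer(c(10, 20), c(15, 15)) / 30  # exact independence
  expect_lt(mh_chisq_frequencies(ind)$statistic, 1e-10)
  set.seed(25)
  for (i in 1:50) {
    tab <- matrix(rpois(12, 5) + 1L, 3, 4)
    expect_equal(mh_chisq_frequencies(tab)$statistic, brute_mh_scores(tab))
  }
  expect_error(mh_chisq_frequencies(matrix(c(3, 3), 1)), "variance")
})

test_that("bout extraction is the ObjP filter of the spell decomposition", {
  b <- extract_bouts(c("ObjP", "ObjP", "NoP", "ObjP"))
  expect_equal(b$start, c(1L, 4L))
  expect_equal(b$duration, c(2L, 1L))
  expect_equal(nrow(extract_bouts(rep("NoP", 20))), 0L)
  expect_equal(extract_bouts(rep("ObjP", 360))$duration, 360L)
  set.seed(6)
  for (i in 1:20) {
    s <- rand_states(50)
    sp <- extract_spells(s)
    expect_equal(extract_bouts(s),
                 sp[sp$state == "ObjP", c("start", "duration")],
                 ignore_attr = TRUE)
  }
})

test_that("Poisson bout model recovers planted time decay and closed forms", {
  set.seed(10)
  # intercept-only closed form: coefficient is log of the mean (a constant
  # start time aliases the time covariate, which is flagged and dropped)
  b0 <- data.frame(duration = rpois(300, 6), start = 1)
  expect_warning(f0 <- poisson_bout_model(b0), "aliased")
  expect_equal(f0$coefficients["(Intercept)", "Estimate"],
               log(mean(b0$duration)))
  # planted decay of -3e-4 per second on bout start time
  start <- sample(1:360, 500, replace = TRUE)
  mu <- exp(2 - 3e-4 * (start - 1) * 5)
  bouts <- data.frame(duration = rpois(500, mu), start = start)
  fit <- poisson_bout_model(bouts)
  est <- fit$coefficients["time_s", ]
  expect_lt(abs(est["Estimate"] - (-3e-4)), 3 * est["Std. Error"])
  # flat durations: time coefficient CI covers zero
  flat <- data.frame(duration = rep(4, 200), start = rep(1:200))
  ff <- poisson_bout_model(flat)$coefficients
  expect_lt(abs(ff["time_s", "Estimate"]), 2 * ff["time_s", "Std. Error"])
})

test_that("trait GLM detects planted group effects and is calibrated under the null", {
  set.seed(33)
  g <- rep(sprintf("g%02d", 1:15), each = 4)
  base <- data.frame(group = g,
                     sex = rep(c("F", "M"), 30),
                     treatment = rep(c("h", "c"), each = 2, length.out = 60),
                     bw = rnorm(60, 1.6, 0.2))
  # planted between-group differences dominate residual noise
  base$trait <- rnorm(15, sd = 2)[as.integer(factor(g))] + rnorm(60, sd = 0.3)
  fit <- linear_model_traits(base, "trait", fixed = c("group", "sex", "treatment"),
                             covariates = "bw")
  expect_lt(fit$anova["group", "Pr(>F)"], 0.01)
  # identical data give identical statistics
  fit2 <- linear_model_traits(base, "trait", fixed = c("group", "sex", "treatment"),
                              covariates = "bw")
  expect_equal(fit$anova[, "F value"], fit2$anova[, "F value"])
  # pure-noise traits: the group F-test p-values are uniform
  pvals <- replicate(200, {
    base$trait <- rnorm(60)
    linear_model_traits(base, "trait",
                        fixed = c("group", "sex"))$anova["group", "Pr(>F)"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
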