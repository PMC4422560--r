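test_that("robust trendline recovers the identity on clean paired wells", {
  set.seed(51)
  ctrl <- runif(60, 8, 25)
  exper <- ctrl + rnorm(60, 0, 0.5)
  fit <- fit_trendline(exper, ctrl)
  expect_false(fit$fallback)
  expect_equal(fit$slope, 1, tolerance = 0.05)
  expect_equal(fit$intercept, 0, tolerance = 0.8)
})

test_that("robust trendline resists a block of strong-phenotype outliers", {
  set.seed(52)
  ctrl <- runif(96, 10, 30)
  exper <- 1.1 * ctrl + rnorm(96, 0, 0.3)
  exper[91:96] <- 0.5 * ctrl[91:96]  # six strong-knockdown wells
  fit <- fit_trendline(exper, ctrl)
  ols_clean <- coef(lm(exper[1:90] ~ ctrl[1:90]))
  expect_false(fit$fallback)
  expect_equal(fit$slope, unname(ols_clean[2]), tolerance = 0.02)
})

test_that("uncorrelated or degenerate controls trigger the median fallback", {
  set.seed(53)
  exper <- rnorm(50, 10, 1)
  ctrl <- rnorm(50, 10, 1)          # independent: Spearman near 0
  rho <- cor(exper, ctrl, method = "spearman")
  fit <- fit_trendline(exper, ctrl)
  expect_equal(fit$spearman, rho)
  if (rho < 0.1) expect_true(fit$fallback)

  # anticorrelated (negative slope)
  fit2 <- fit_trendline(20 - ctrl + rnorm(50, 0, 0.1), ctrl)
  expect_true(fit2$fallback)

  # all-constant control values
  fit3 <- fit_trendline(exper, rep(5, 50))
  expect_true(fit3$fallback)

  expect_error(fit_trendline(1:5, 1:5), "at least 8")
})

test_that("normalization turns trendline-relative values into scores", {
  set.seed(54)
  ctrl <- runif(40, 10, 30)
  exper <- 1.2 * ctrl + 1 + rnorm(40, 0, 1e-3)
  fit <- fit_trendline(exper, ctrl)
  ns <- normalize_scores(exper, ctrl, fit = fit)
  # wells exactly on the trendline: normalized 1, score 0
  expect_equal(ns$normalized, rep(1, 40), tolerance = 1e-3)
  expect_equal(ns$score, rep(0, 40), tolerance = 1e-3)

  # experimental at half the expected value: score -0.5
  ns2 <- normalize_scores(exper / 2, ctrl, fit = fit)
  expect_equal(ns2$score, rep(-0.5, 40), tolerance = 1e-3)

  # non-positive expected values are flagged and excluded
  fitneg <- structure(list(slope = 1, intercept = -100, spearman = 0.9,
                           fallback = FALSE), class = "trendline_fit")
  ns3 <- normalize_scores(c(5, 5), c(10, 200), fit = fitneg)
  expect_true(ns3$excluded[1])
  expect_true(is.na(ns3$score[1]))
  expect_false(ns3$excluded[2])
})

test_that("normalization is idempotent", {
  set.seed(55)
  ctrl <- runif(40, 10, 30)
  exper <- 1.3 * ctrl + rnorm(40, 0, 0.5)
  once <- normalize_scores(exper, ctrl)$normalized
  twice <- normalize_scores(once, ctrl)$normalized
  expect_equal(twice, rep(1, 40), tolerance = 0.1)
})

test_that("chemokinesis score is the robust residual of stimulated on basal", {
  set.seed(56)
  basal <- rnorm(60, 0, 0.2)
  stim <- basal  # population trend: slope 1 through the origin
  # a receptor-knockdown-like condition: normal basal, low stimulated
  basal <- c(basal, 0)
  stim <- c(stim, -0.4)
  ck <- chemokinesis_score(basal, stim)
  expect_equal(ck[1:60], rep(0, 60), tolerance = 1e-6)
  expect_equal(ck[61], -0.4, tolerance = 0.02)

  # adding a constant to all stimulated scores is absorbed by the intercept
  ck_shift <- chemokinesis_score(basal, stim + 0.7)
  expect_equal(ck_shift, ck, tolerance = 1e-6)

  # constant basal scores: residuals against a robust mean
  ck_const <- chemokinesis_score(rep(0.1, 20), c(rep(0, 19), 1))
  expect_equal(ck_const[1], 0, tolerance = 0.01)
})

test_that("error model recovers a single Gaussian and a true mixture", {
  set.seed(57)
  # single Gaussian, sigma = 0.1: fitted total SD within 5%
  d1 <- rnorm(2000, 0, sqrt(2) * 0.1)  # differences of two sigma = 0.1 draws
  m1 <- fit_error_model(diffs = d1)
  expect_equal(sqrt(error_model_var(m1)), 0.1, tolerance = 0.05)

  # two components, w = (0.8, 0.2), sigma = (0.05, 0.2): SDs within 15%
  rmix <- function(n) {
    k <- runif(n) < 0.2
    rnorm(n, 0, ifelse(k, 0.2, 0.05))
  }
  d2 <- rmix(5000) - rmix(5000)
  m2 <- fit_error_model(diffs = d2)
  expect_equal(m2$sigma[1], 0.05, tolerance = 0.15)
  expect_equal(m2$sigma[2], 0.2, tolerance = 0.15)
  expect_true(m2$converged)

  # moment identity: Var(differences) ~ 2 x fitted error variance
  ratio <- var(d2) / (2 * error_model_var(m2))
  expect_equal(ratio, 1, tolerance = 0.1)
})

test_that("replicate differences enumerate unordered within-condition pairs", {
  d <- replicate_differences(c(1, 2, 4, 10, 20), c("a", "a", "a", "b", "b"))
  expect_equal(sort(abs(d)), c(1, 2, 3, 10))  # 3 pairs from a, 1 from b
})

test_that("null interval matches the closed-form normal quantile when degenerate", {
  model <- structure(list(w = c(1, 0), sigma = c(0.1, 0.3)),
                     class = "error_model")
  ci <- null_interval(model, n = 3, coverage = 0.98)
  expect_equal(ci$upper, qnorm(0.99) * 0.1 / sqrt(3), tolerance = 1e-6)
  expect_equal(ci$lower, -ci$upper)

  # interval width shrinks to 0 as coverage does
  tiny <- null_interval(model, n = 3, coverage = 1e-6)
  expect_lt(tiny$upper, 1e-6)
})

test_that("p-values are symmetric, monotone, and consistent with the interval", {
  model <- structure(list(w = c(0.8, 0.2), sigma = c(0.05, 0.2)),
                     class = "error_model")
  expect_equal(null_p_value(0, 3, model), 1)
  ms <- seq(0.01, 0.5, by = 0.01)
  expect_equal(null_p_value(ms, 3, model), null_p_value(-ms, 3, model))
  expect_true(all(diff(null_p_value(ms, 3, model)) < 0))

  ci <- null_interval(model, n = 3, coverage = 0.98)
  expect_equal(null_p_value(ci$upper, 3, model), 0.02, tolerance = 1e-4)
})
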