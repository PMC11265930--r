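test_that("chi-squared uniform GOF reproduces the latch-preference statistics", {
  r1 <- chisq_uniform_gof(c(21, 11, 3, 0))
  expect_equal(r1$statistic, 30.257, tolerance = 1e-3)
  expect_equal(r1$df, 3)
  expect_lt(r1$p_value, 1e-4)
  r2 <- chisq_uniform_gof(c(217, 198, 193, 128))
  expect_equal(r2$statistic, 24.467, tolerance = 1e-3)
  expect_lt(r2$p_value, 1e-4)
  r3 <- chisq_uniform_gof(c(5, 5, 5, 5))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_error(chisq_uniform_gof(c(0, 0)), "zero")
  expect_error(chisq_uniform_gof(7), "two categories")
})

test_that("chi-squared matches the textbook formula on random count vectors", {
  set.seed(31)
  for (i in 1:40) {
    counts <- rpois(sample(2:8, 1), lambda = 20) + 1
    expect_equal(chisq_uniform_gof(counts)$statistic,
                 oracle_chisq(counts), tolerance = 1e-9)
  }
})

test_that("Mann-Whitney W convention and exact p match the worked example", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)
  # identical samples: W = n1*n2/2 by mid-ranks
  r2 <- mann_whitney(c(1, 1), c(1, 1))
  expect_equal(r2$statistic, 2)
  expect_true(r2$tie_correction_applied)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("swapping samples maps W to n1*n2 - W with the same p", {
  set.seed(32)
  for (i in 1:15) {
    x <- runif(sample(3:8, 1))
    y <- runif(sample(3:8, 1))
    a <- mann_whitney(x, y)
    b <- mann_whitney(y, x)
    expect_equal(a$statistic + b$statistic, length(x) * length(y))
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("exact Mann-Whitney p equals full permutation enumeration for tie-free samples", {
  set.seed(33)
  for (i in 1:20) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- sample(100, n1 + n2)  # distinct values, no ties
    r <- mann_whitney(x[seq_len(n1)], x[-seq_len(n1)])
    expect_true(r$exact)
    expect_equal(r$p_value, oracle_mw_p(x[seq_len(n1)], x[-seq_len(n1)]))
  }
})

test_that("intercept-only binomial fit has the closed-form deviance and AICc", {
  d <- data.frame(y = rep(c(0, 1), each = 5))
  f <- fit_binomial_glm(y ~ 1, d)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  expect_equal(f$deviance, -2 * 10 * log(0.5), tolerance = 1e-8)
  expect_equal(f$AIC, f$deviance + 2, tolerance = 1e-8)
  expect_equal(f$AICc, f$AIC + 2 * 1 * 2 / (10 - 1 - 1), tolerance = 1e-8)
  expect_equal(f$k, 1L)
})

test_that("perfect separation is flagged", {
  d <- data.frame(y = rep(c(0, 1), each = 10),
                  x = rep(c(0, 1), each = 10))
  expect_warning(fit_binomial_glm(y ~ x, d), "separation")
})

test_that("AICc is refused when n <= k + 1", {
  d <- data.frame(y = c(0, 1, 1), x = c(0.1, 0.7, 0.3))
  expect_error(suppressWarnings(fit_binomial_glm(y ~ x, d)),
               "AICc undefined")
})

test_that("logistic coefficients are recovered from simulated data", {
  set.seed(34)
  n <- 2000
  x <- rnorm(n)
  p <- plogis(-1 + 0.8 * x)
  d <- data.frame(y = rbinom(n, 1, p), x = x)
  f <- fit_binomial_glm(y ~ x, d)
  expect_lt(abs(f$coefficients[["(Intercept)"]] - (-1)), 0.15)
  expect_lt(abs(f$coefficients[["x"]] - 0.8), 0.15)
  # Wald CI covers the estimate and has the 1.96 SE half-width
  expect_equal(unname(f$ci[, "upper"] - f$ci[, "lower"]),
               unname(2 * 1.96 * f$se))
})

test_that("likelihood-ratio test matches the chi-squared tail and rejects non-nested input", {
  d <- data.frame(y = rep(c(0, 1), each = 20),
                  x = rnorm(40))
  f0 <- fit_binomial_glm(y ~ 1, d)
  r0 <- lrt(f0, f0)  # identical models
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  fx <- fit_binomial_glm(y ~ x, d)
  expect_error(lrt(fx, f0), "nested")  # reversed nesting
  # deviances 13.863 vs 7.313 on 1 df give the printed-magnitude LRT
  stat <- 13.863 - 7.313
  expect_equal(pchisq(stat, 1, lower.tail = FALSE), 0.0105,
               tolerance = 5e-3)
  set.seed(35)
  d$x2 <- rnorm(40)
  f1 <- fit_binomial_glm(y ~ x2, d)
  r <- lrt(f0, f1)
  expect_gte(r$statistic, 0)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value,
               pchisq(r$statistic, 1, lower.tail = FALSE))
})

test_that("Akaike weights normalise, order and shift-invariance hold", {
  expect_equal(akaike_weights(42), 1)
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))
  set.seed(36)
  a <- runif(6, 50, 90)
  expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(a), akaike_weights(a + 17.3),
               tolerance = 1e-12)
})

test_that("forward stepwise keeps a strong predictor and stops on noise", {
  set.seed(37)
  n <- 200
  x_good <- rnorm(n)
  d <- data.frame(y = rbinom(n, 1, plogis(-0.5 + 1.5 * x_good)),
                  x_good = x_good,
                  x_noise1 = rnorm(n),
                  x_noise2 = rnorm(n))
  st <- forward_stepwise(d, "y", c("x_noise1", "x_good", "x_noise2"))
  expect_true(grepl("x_good", deparse(st$best$formula)))
  expect_equal(st$models$dAICc[which.max(st$models$weight)], 0)
  expect_equal(sum(st$models$weight), 1, tolerance = 1e-12)
  expect_false(is.null(st$lrt_vs_null))
})

test_that("forward stepwise retains the null model when all candidates are noise at small n", {
  set.seed(38)
  n <- 35
  d <- data.frame(y = rbinom(n, 1, 0.25),
                  a = rnorm(n), b = rnorm(n), c = rnorm(n))
  st <- suppressWarnings(forward_stepwise(d, "y", c("a", "b", "c")))
  expect_equal(st$best$k, 1L)
  expect_null(st$lrt_vs_null)
})

test_that("duplicate candidates break ties by input order", {
  set.seed(39)
  n <- 150
  x <- rnorm(n)
  d <- data.frame(y = rbinom(n, 1, plogis(x)), first = x, second = x)
  st <- forward_stepwise(d, "y", c("first", "second"))
  expect_true(grepl("first", deparse(st$best$formula)))
  expect_false(grepl("second", deparse(st$best$formula)))
})
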