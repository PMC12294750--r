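test_that("noiseless data are interpolated exactly", {
  d <- data.frame(duration_log = 1.0 - 0.08 * seq(-5, 0, length.out = 20),
                  predictability = seq(-5, 0, length.out = 20))
  fit <- fit_duration_model(d, model_spec("predictability"))
  expect_equal(fit$coefficients$estimate[1], 1.0, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate[2], -0.08, tolerance = 1e-10)
  expect_equal(fit$r2$r2, 1)
  expect_equal(fit$r2$r2_adjusted, 1)
})

test_that("OLS matches the hand normal-equations solution", {
  d <- data.frame(duration_log = c(0, 1, 2, 3, 5),
                  predictability = c(0, 1, 2, 3, 4))
  fit <- fit_duration_model(d, model_spec("predictability"))
  expect_equal(fit$coefficients$estimate[fit$coefficients$term ==
                                           "predictability"], 1.2)
  expect_equal(fit$coefficients$estimate[1], -0.2)
  # SSE = 0.4, SST = 14.8 by hand
  expect_equal(fit$r2$r2, 1 - 0.4 / 14.8)
  expect_equal(fit$r2$r2_adjusted, 1 - (1 - (1 - 0.4 / 14.8)) * 4 / 3)
  expect_equal(compute_fit_stats(fit, d)$r2_adjusted, fit$r2$r2_adjusted)
})

test_that("OLS equals the closed-form solution on random full-rank designs", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- data.frame(predictability = rnorm(10), informativity = rnorm(10))
    d$duration_log <- 0.5 - 0.3 * d$predictability +
      0.2 * d$informativity + rnorm(10, 0, 0.1)
    fit <- fit_duration_model(d, model_spec(c("predictability",
                                              "informativity")))
    X <- cbind(1, d$predictability, d$informativity)
    beta <- solve(crossprod(X), crossprod(X, d$duration_log))
    expect_equal(fit$coefficients$estimate, as.vector(beta),
                 tolerance = 1e-10)
  }
})

test_that("rank-deficient designs error naming the aliased term", {
  d <- data.frame(predictability = rnorm(20))
  d$informativity <- -d$predictability   # exactly collinear
  d$duration_log <- rnorm(20)
  expect_error(
    fit_duration_model(d, model_spec(c("predictability", "informativity"))),
    "informativity")
})

test_that("model specs enforce their structural invariants", {
  expect_error(model_spec(c("predictability",
                            "predictability:context_freq")),
               "parent")
  expect_error(model_spec("volume"), "unknown fixed")
  expect_error(model_spec("predictability", random = "predictability"),
               "random intercept")
  sp <- model_spec(c("predictability", "informativity"), random = "intercept")
  expect_identical(sp$estimator, "mixed")
  expect_identical(model_spec("predictability")$estimator, "ols")
})

test_that("mixed fit with negligible word variance reproduces OLS", {
  set.seed(5)
  n <- 400
  d <- data.frame(word = rep(paste0("w", seq_len(n / 2)), each = 2),
                  predictability = rnorm(n, -2, 1))
  d$informativity <- -d$predictability + rnorm(n, 0, 0.5)
  # residuals centered within each word: zero between-word variance, so the
  # REML estimate of the word intercept variance sits at the 0 boundary
  e <- rnorm(n, 0, 0.3)
  e <- e - ave(e, d$word)
  d$duration_log <- -2 - 0.1 * d$predictability + e
  ols <- fit_duration_model(d, model_spec(c("predictability",
                                            "informativity")))
  mix <- fit_duration_model(d, model_spec(c("predictability",
                                            "informativity"),
                                          random = "intercept"))
  expect_equal(mix$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-6)
  expect_true(mix$var_word < 1e-6)
  expect_equal(mix$r2$r2_conditional, mix$r2$r2_marginal, tolerance = 1e-6)
})

test_that("mixed fits report Satterthwaite df and a sane R2 family", {
  set.seed(9)
  words <- paste0("w", 1:40)
  d <- data.frame(word = rep(words, each = 8))
  d$predictability <- rnorm(nrow(d), -2, 1)
  eff <- rnorm(40, 0, 0.4)
  d$duration_log <- -2 - 0.1 * d$predictability + eff[match(d$word, words)] +
    rnorm(nrow(d), 0, 0.3)
  fit <- fit_duration_model(d, model_spec("predictability",
                                          random = "intercept"))
  expect_identical(fit$df_method, "satterthwaite")
  expect_true(all(fit$coefficients$p >= 0 & fit$coefficients$p <= 1))
  expect_true(fit$var_word > 0)
  expect_gte(fit$r2$r2_conditional, fit$r2$r2_marginal)
  expect_true(fit$r2$r2_conditional <= 1)
  # Satterthwaite df should be near the residual df for the fixed slope
  expect_true(fit$coefficients$df[2] > 40)
})

test_that("parameter recovery on a mid-sized synthetic corpus", {
  corp <- generate_corpus(synth_config(n_tokens = 20000, sigma_word = 0,
                                       b_pred = -0.05, sigma_resid = 0.3,
                                       seed = 21))
  aug <- attach_predictors(corp$tokens, truth_stats(corp))
  gen <- calibrate_generating_model(aug)
  fit <- attr(gen, "fit")
  se <- fit$coefficients$se[fit$coefficients$term == "predictability"]
  expect_lt(abs(gen$b_pred - (-0.05)), 3 * se)
  expect_equal(gen$sigma_resid, 0.3, tolerance = 0.02)
})

test_that("nested comparison returns the adjusted-R2 drop", {
  set.seed(13)
  n <- 2000
  # collinear pair where only predictability drives durations
  d <- data.frame(predictability = rnorm(n, -2, 1))
  d$informativity <- -d$predictability + rnorm(n, 0, 0.6)
  d$duration_log <- -2 - 0.4 * d$predictability + rnorm(n, 0, 0.4)
  full <- fit_duration_model(d, model_spec(c("predictability",
                                             "informativity")))
  red <- fit_duration_model(d, model_spec("informativity"))
  delta <- compare_nested(full, red)
  # double-fit oracle straight from lm()
  a_full <- summary(lm(duration_log ~ predictability + informativity,
                       d))$adj.r.squared
  a_red <- summary(lm(duration_log ~ informativity, d))$adj.r.squared
  expect_equal(delta, 100 * (a_full - a_red))
  expect_gt(delta, 0)

  # dropping an orthogonal zero-coefficient regressor changes nothing
  d$context_freq <- sample(1:50, n, replace = TRUE)
  full2 <- fit_duration_model(d, model_spec(c("predictability",
                                              "context_freq")))
  red2 <- fit_duration_model(d, model_spec("predictability"))
  expect_equal(compare_nested(full2, red2), 0, tolerance = 0.1)
  expect_error(compare_nested(red2, full2), "subset")
})
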