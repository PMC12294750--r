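test_that("calibration recovers a noiseless generating process exactly", {
  toks <- random_tokens(60, seed = 3)
  st <- compute_bigram_stats(toks)
  aug <- attach_predictors(toks, st)
  aug$duration_log <- -2.1 - 0.07 * aug$predictability
  gen <- calibrate_generating_model(aug)
  expect_equal(gen$b0, -2.1, tolerance = 1e-10)
  expect_equal(gen$b_pred, -0.07, tolerance = 1e-10)
  expect_equal(gen$b_info, 0)
  expect_equal(gen$sigma_resid, 0, tolerance = 1e-10)
})

test_that("sigma_resid is the SD of the calibration fit's residuals", {
  corp <- generate_corpus(synth_config(n_tokens = 500, seed = 4))
  aug <- attach_predictors(corp$tokens, compute_bigram_stats(corp$tokens))
  gen <- calibrate_generating_model(aug)
  fit <- attr(gen, "fit")
  expect_equal(gen$sigma_resid, sd(residuals(fit$model)))
  genm <- calibrate_generating_model(aug, use_random_intercept = TRUE)
  fitm <- attr(genm, "fit")
  expect_equal(genm$sigma_resid, sd(residuals(fitm$model)))
  expect_named(genm$word_effects)
  expect_true(all(names(genm$word_effects) %in% aug$word))
})

test_that("omitting informativity inflates the predictability slope on collinear data", {
  set.seed(8)
  n <- 3000
  pred <- rnorm(n, -2, 1)
  info <- -pred + rnorm(n, 0, 0.5)   # strong negative correlation
  d <- data.frame(predictability = pred, informativity = info,
                  duration_log = -2 - 0.05 * pred + 0.05 * info +
                    rnorm(n, 0, 0.3))
  gen <- calibrate_generating_model(d)
  both <- fit_duration_model(d, model_spec(c("predictability",
                                             "informativity")))
  b_both <- both$coefficients$estimate[both$coefficients$term ==
                                         "predictability"]
  expect_gt(abs(gen$b_pred), abs(b_both))
})

test_that("binomial resampling has the right support and moments", {
  # degenerate p = 1: every trial a success
  certain <- token_table(word = rep("b", 7), context = rep("a", 7))
  st1 <- compute_bigram_stats(certain)
  set.seed(1)
  for (i in 1:5) expect_identical(resample_tokens(st1)$k, 7L)

  # a context of frequency 1 yields a sample probability of 0 or 1
  # regardless of the underlying probability
  single <- structure(list(
    pairs = data.frame(context = "a", word = "b", n_pair = 0.3, p = 0.3,
                       predictability = log(0.3), stringsAsFactors = FALSE),
    words = data.frame(word = "b", n_w = 0.3, informativity = -log(0.3),
                       mean_predictability = log(0.3),
                       stringsAsFactors = FALSE),
    contexts = data.frame(context = "a", n_cx = 1L, stringsAsFactors = FALSE),
    log_base = exp(1), n_tokens = 1L), class = "bigram_stats")
  set.seed(2)
  ks <- replicate(50, resample_tokens(single)$k)
  expect_true(all(ks %in% c(0L, 1L)))
  expect_true(any(ks == 0L) && any(ks == 1L))

  # moment oracle: p = 0.5, n_cx = 10
  half <- token_table(word = rep(c("x", "y"), each = 5),
                      context = rep("a", 10))
  st2 <- compute_bigram_stats(half)
  set.seed(3)
  ks <- replicate(10000, resample_tokens(st2)$k[1])
  se <- sqrt(10 * 0.25 / 10000)
  expect_lt(abs(mean(ks) - 5), 3 * se)

  # multinomial alternative: counts sum to n_cx within each context
  set.seed(4)
  km <- resample_tokens(st2, multinomial = TRUE)
  expect_identical(sum(km$k), 10L)
})

test_that("sample predictors match a brute-force recomputation", {
  toks <- random_tokens(120, n_words = 10, n_contexts = 6, seed = 11)
  st <- compute_bigram_stats(toks)

  # resample frozen at the original counts reproduces the original stats
  rs <- st$pairs
  rs$k <- rs$n_pair
  rs$n_cx <- st$contexts$n_cx[match(rs$context, st$contexts$context)]
  rep_tab <- infosim:::build_replicate(rs, st)
  rep_tab <- estimate_sample_predictors(rep_tab)
  expect_equal(rep_tab$predictability_sample, rep_tab$predictability_true)
  info_orig <- st$words$informativity[match(rep_tab$word, st$words$word)]
  expect_equal(rep_tab$informativity_sample, info_orig)

  # randomized counts against an independent per-token loop
  set.seed(12)
  rs <- resample_tokens(st)
  rep_tab <- estimate_sample_predictors(infosim:::build_replicate(rs, st))
  expect_true(all(rep_tab$pair_k >= 1))
  for (w in unique(rep_tab$word)[1:5]) {
    rows <- which(rep_tab$word == w)
    surp <- vapply(rows, function(i)
      -log(rep_tab$pair_k[i] / rep_tab$context_freq[i]), numeric(1))
    expect_equal(rep_tab$informativity_sample[rows[1]], mean(surp))
  }
})

test_that("duration simulation honors the generating model", {
  toks <- random_tokens(500, seed = 13)
  st <- compute_bigram_stats(toks)
  aug <- attach_predictors(toks, st)
  d <- data.frame(word = aug$word,
                  predictability_true = aug$predictability,
                  informativity_true = aug$informativity,
                  stringsAsFactors = FALSE)

  # zero noise, zero word effects: exact linear durations
  gen0 <- generating_model(b0 = -2, b_pred = -0.1, sigma_resid = 0)
  out <- simulate_durations(d, gen0)
  expect_equal(out$duration_log, -2 - 0.1 * d$predictability_true)

  # Monte-Carlo moment oracle on a large replicate
  gen1 <- generating_model(b0 = -2, b_pred = 0, sigma_resid = 0.4)
  set.seed(14)
  big <- d[rep(seq_len(nrow(d)), 20), ]
  out <- simulate_durations(big, gen1)
  n <- nrow(big)
  expect_lt(abs(mean(out$duration_log) + 2), 3 * 0.4 / sqrt(n))
  expect_lt(abs(sd(out$duration_log) - 0.4), 3 * 0.4 / sqrt(2 * n))
  # with b_pred = 0 durations are independent of predictability
  expect_lt(abs(cor(out$duration_log, out$predictability_true)),
            3 / sqrt(n))

  # word-effects map: missing word errors unless told otherwise
  genw <- generating_model(b0 = -2, b_pred = 0,
                           word_effects = c(w1 = 0.5), sigma_resid = 0.1)
  unknown <- data.frame(word = "w999", predictability_true = 0,
                        informativity_true = 0)
  expect_error(simulate_durations(unknown, genw), "w999")
  ok <- simulate_durations(unknown, genw, unseen = "zero")
  expect_true(is.finite(ok$duration_log))
})

test_that("a null experiment is reproducible bit-for-bit from its seed", {
  corp <- generate_corpus(synth_config(n_tokens = 400, n_context_types = 80,
                                       n_word_types = 60, seed = 15))
  stT <- truth_stats(corp)
  gen <- generating_model(b0 = -2.2, b_pred = -0.06, sigma_resid = 0.4)
  spec <- model_spec(c("predictability", "informativity"))
  s1 <- run_null_experiment(stT, gen, spec, n_reps = 20, master_seed = 99)
  s2 <- run_null_experiment(stT, gen, spec, n_reps = 20, master_seed = 99)
  expect_identical(s1$estimates, s2$estimates)
  s3 <- run_null_experiment(stT, gen, spec, n_reps = 20, master_seed = 100)
  expect_false(identical(s1$estimates$estimate, s3$estimates$estimate))
})

test_that("with true predictors the informativity test is calibrated", {
  corp <- generate_corpus(synth_config(seed = 16))
  stT <- truth_stats(corp)
  gen <- calibrate_generating_model(attach_predictors(corp$tokens, stT))
  sim <- run_null_experiment(stT, gen,
                             model_spec(c("predictability", "informativity")),
                             n_reps = 300, master_seed = 17,
                             predictor_source = "true")
  fa <- false_alarm_rate(sim, "informativity")
  # 99.9% binomial band around 0.05 at 300 replicates
  expect_gt(fa$rate_sig, 0.05 - 3.29 * sqrt(0.05 * 0.95 / 300))
  expect_lt(fa$rate_sig, 0.05 + 3.29 * sqrt(0.05 * 0.95 / 300))
  # positive and negative spurious coefficients about equally often
  expect_gt(fa$sign_rate, 0.35)
  expect_lt(fa$sign_rate, 0.65)
})

test_that("true and sample predictability correlate highly but imperfectly", {
  corp <- generate_corpus(synth_config(seed = 18))
  stT <- truth_stats(corp)
  cors <- function(stats) {
    set.seed(19)
    mean(replicate(5, {
      rs <- resample_tokens(stats)
      rt <- estimate_sample_predictors(infosim:::build_replicate(rs, stats))
      cor(rt$predictability_true, rt$predictability_sample)
    }))
  }
  r1 <- cors(stT)
  expect_gt(r1, 0.25)
  expect_lt(r1, 1)
  # scaling every context frequency up tightens the estimates
  st10 <- stT
  st10$contexts$n_cx <- st10$contexts$n_cx * 10L
  st10$pairs$n_pair <- st10$pairs$n_pair * 10
  expect_gt(cors(st10), r1)
})
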