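#' Construct a generating model
#'
#' The generating model is the ground truth behind every simulated dataset: a
#' linear model of log duration with an intercept, a per-nat predictability
#' coefficient, an (optionally zero) per-nat informativity coefficient,
#' per-word random intercepts, and Gaussian residual noise. Setting
#' `b_info = 0` defines the null regime the diagnostic studies: durations
#' driven by true predictability only. Generation never includes interaction
#' terms — any interaction the analysis model detects in such data is
#' spurious by construction.
#'
#' Word effects can be given either as a named map (`word_effects`), in which
#' case simulation looks each word up and errors on a miss, or implicitly via
#' `sigma_word`, in which case [simulate_durations()] draws a fresh effect
#' per word type.
#'
#' @param b0 intercept, log seconds.
#' @param b_pred predictability coefficient (log-seconds per nat).
#' @param b_info informativity coefficient; 0 under the null.
#' @param word_effects optional named numeric vector of per-word intercepts
#'   (log seconds).
#' @param sigma_word SD for sampling word effects when no map is given
#'   (>= 0).
#' @param sigma_resid residual SD, log seconds (>= 0; zero gives
#'   deterministic durations, useful for exactness checks).
#' @return An object of class `generating_model`.
#' @export
generating_model <- function(b0, b_pred, b_info = 0, word_effects = NULL,
                             sigma_word = 0, sigma_resid) {
  stopifnot(is.numeric(b0), is.numeric(b_pred), is.numeric(b_info),
            is.numeric(sigma_resid), sigma_resid >= 0, sigma_word >= 0)
  if (!is.null(word_effects) && is.null(names(word_effects)))
    stop("`word_effects` must be a named numeric vector")
  structure(list(b0 = b0, b_pred = b_pred, b_info = b_info,
                 word_effects = word_effects, sigma_word = sigma_word,
                 sigma_resid = sigma_resid),
            class = "generating_model")
}

#' @export
print.generating_model <- function(x, ...) {
  cat(sprintf(
    "Generating model: b0 = %.4f, b_pred = %.4f, b_info = %.4f, sigma_resid = %.4f\n",
    x$b0, x$b_pred, x$b_info, x$sigma_resid))
  if (!is.null(x$word_effects))
    cat("  word effects: map over", length(x$word_effects), "words\n")
  else if (x$sigma_word > 0)
    cat("  word effects: sampled with sigma_word =", x$sigma_word, "\n")
  invisible(x)
}

#' Calibrate a generating model from observed data
#'
#' Fits log duration on predictability alone — deliberately omitting
#' informativity, so that the predictability coefficient absorbs the full
#' bivariate relationship — and packages the result as the ground truth for
#' null simulation: the fitted intercept and slope, a zero informativity
#' coefficient, the model's predicted per-word random intercepts (when a
#' mixed calibration is requested), and the standard deviation of the
#' calibration fit's residuals as the residual SD.
#'
#' @param tokens an augmented token table (see [attach_predictors()]) with
#'   `duration_log` and `predictability` columns.
#' @param use_random_intercept logical; calibrate with a by-word random
#'   intercept (mixed model) rather than OLS.
#' @return A `generating_model` with `b_info = 0`; the calibration
#'   `fit_result` is attached as attribute `"fit"`.
#' @export
calibrate_generating_model <- function(tokens, use_random_intercept = FALSE) {
  spec <- model_spec("predictability",
                     random = if (use_random_intercept) "intercept"
                              else character())
  fit <- fit_duration_model(tokens, spec)
  cf <- fit$coefficients
  b0 <- cf$estimate[cf$term == "(Intercept)"]
  b_pred <- cf$estimate[cf$term == "predictability"]
  if (use_random_intercept) {
    re <- lme4::ranef(fit$model)$word
    word_effects <- stats::setNames(re[["(Intercept)"]], rownames(re))
    sigma_resid <- stats::sd(stats::residuals(fit$model))
    gen <- generating_model(b0 = b0, b_pred = b_pred, b_info = 0,
                            word_effects = word_effects,
                            sigma_word = sqrt(fit$var_word),
                            sigma_resid = sigma_resid)
  } else {
    sigma_resid <- stats::sd(stats::residuals(fit$model))
    gen <- generating_model(b0 = b0, b_pred = b_pred, b_info = 0,
                            sigma_resid = sigma_resid)
  }
  attr(gen, "fit") <- fit
  gen
}

#' Resample bigram counts by per-pair binomial draws
#'
#' Draws a new count for every observed (context, word) pair from
#' `Binomial(n_cx, p(w | cx))`: each token of the context is a "trial" on
#' which the word either occurs or not, independently across pairs. Context
#' frequencies are held at their observed values, so within a context the
#' resampled counts need not sum to `n_cx`; the alternative of a single
#' multinomial draw per context (which enforces the sum) is available via
#' `multinomial = TRUE`.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param stats a `bigram_stats`.
#' @param multinomial logical; draw one multinomial per context instead of
#'   independent binomials per pair.
#' @return `stats$pairs` with a column `k` of resampled counts; pairs with
#'   `k = 0` contribute no tokens to the replicate.
#' @export
resample_tokens <- function(stats, multinomial = FALSE) {
  stopifnot(inherits(stats, "bigram_stats"))
  pairs <- stats$pairs
  cx_idx <- match(pairs$context, stats$contexts$context)
  n_cx <- stats$contexts$n_cx[cx_idx]
  if (multinomial) {
    k <- integer(nrow(pairs))
    for (ci in seq_len(nrow(stats$contexts))) {
      rows <- which(cx_idx == ci)
      k[rows] <- as.vector(stats::rmultinom(1, stats$contexts$n_cx[ci],
                                            pairs$p[rows]))
    }
    pairs$k <- k
  } else {
    pairs$k <- stats::rbinom(nrow(pairs), size = n_cx, prob = pairs$p)
  }
  pairs$n_cx <- n_cx
  pairs
}

# Expand resampled pair counts into a replicate token table carrying the
# source corpus's true statistics per token.
build_replicate <- function(resampled, stats) {
  keep <- resampled$k > 0L
  rp <- resampled[keep, , drop = FALSE]
  idx <- rep.int(seq_len(nrow(rp)), rp$k)
  wi <- match(rp$word, stats$words$word)
  rep_tab <- data.frame(
    word = rp$word[idx],
    context = rp$context[idx],
    context_freq = rp$n_cx[idx],
    pair_k = rp$k[idx],
    p_true = rp$p[idx],
    predictability_true = rp$predictability[idx],
    informativity_true = stats$words$informativity[wi][idx],
    stringsAsFactors = FALSE)
  rep_tab$token_id <- seq_len(nrow(rep_tab))
  attr(rep_tab, "log_base") <- stats$log_base
  rep_tab
}

#' Re-estimate predictability and informativity from a resampled replicate
#'
#' Computes the sample statistics a researcher would estimate from the
#' replicate: `p_hat(w | cx) = k(w, cx) / n_cx` (the denominator is the
#' original context frequency, the number of binomial "trials"), sample
#' predictability `log p_hat`, and sample informativity as the
#' token-weighted mean sample surprisal over the replicate's tokens of each
#' word. Words with zero tokens in the replicate are simply absent (their
#' informativity is undefined there).
#'
#' @param replicate a replicate token table as produced inside
#'   [run_null_experiment()] (columns `word`, `context_freq`, `pair_k`).
#' @return The replicate with `predictability_sample` and
#'   `informativity_sample` columns filled.
#' @export
estimate_sample_predictors <- function(replicate) {
  stopifnot(all(c("word", "pair_k", "context_freq") %in% names(replicate)))
  log_base <- attr(replicate, "log_base")
  if (is.null(log_base)) log_base <- exp(1)
  p_hat <- replicate$pair_k / replicate$context_freq
  replicate$predictability_sample <- log(p_hat, base = log_base)
  uw <- unique(replicate$word)
  wi <- match(replicate$word, uw)
  surp <- -replicate$predictability_sample
  info <- as.vector(rowsum(surp, wi, reorder = TRUE)) /
    tabulate(wi, nbins = length(uw))
  replicate$informativity_sample <- info[wi]
  replicate
}

#' Simulate log durations from a generating model
#'
#' Draws each token's log duration from
#' `Normal(b0 + b_pred * pred_true + b_info * info_true + word_effect,
#' sigma_resid)`, independently per token. The mean always uses the TRUE
#' (source-corpus) predictability and informativity, never the sample
#' estimates — the divergence between the two is exactly what the diagnostic
#' measures downstream.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param replicate a replicate token table with `predictability_true` and
#'   `informativity_true` columns (any table with those columns and `word`
#'   works, e.g. an augmented original corpus renamed accordingly).
#' @param gen a [generating_model()]. If it carries a `word_effects` map,
#'   every word must be present in it (see `unseen`); otherwise, with
#'   `sigma_word > 0`, effects are drawn fresh per word type.
#' @param unseen what to do when a word is missing from the `word_effects`
#'   map: `"error"` (default) or `"zero"` (use the population mean, the
#'   predicted random intercept for a word never observed at calibration —
#'   needed when resampling can introduce words absent from the calibration
#'   data).
#' @return The replicate with a `duration_log` column filled.
#' @export
simulate_durations <- function(replicate, gen, unseen = c("error", "zero")) {
  unseen <- match.arg(unseen)
  stopifnot(inherits(gen, "generating_model"),
            all(c("word", "predictability_true", "informativity_true") %in%
                  names(replicate)))
  mu <- gen$b0 + gen$b_pred * replicate$predictability_true +
    gen$b_info * replicate$informativity_true
  if (!is.null(gen$word_effects)) {
    eff <- gen$word_effects[replicate$word]
    if (anyNA(eff)) {
      if (unseen == "error") {
        bad <- replicate$word[which(is.na(eff))[1]]
        stop("no stored word effect for word: ", bad)
      }
      eff[is.na(eff)] <- 0
    }
    mu <- mu + as.vector(eff)
  } else if (gen$sigma_word > 0) {
    uw <- unique(replicate$word)
    eff <- stats::setNames(stats::rnorm(length(uw), 0, gen$sigma_word), uw)
    mu <- mu + as.vector(eff[replicate$word])
  }
  replicate$duration_log <- stats::rnorm(nrow(replicate), mean = mu,
                                         sd = gen$sigma_resid)
  replicate
}

#' Run a null simulation experiment
#'
#' The core of the diagnostic. For each of `n_reps` replicates:
#' resample bigram counts from the source corpus's conditional probabilities
#' ([resample_tokens()]); re-estimate predictability and informativity from
#' the resampled counts ([estimate_sample_predictors()]) when
#' `predictor_source = "sample"`, or reuse the true source-corpus values when
#' `"true"`; simulate log durations from the generating model — true
#' predictability only when `gen$b_info = 0` ([simulate_durations()]); fit
#' the analysis model; and record every coefficient with its p-value.
#' Replicates whose analysis fit fails or does not converge are excluded and
#' counted. The whole experiment is reproducible bit-for-bit from
#' `master_seed` (per-replicate seeds come from [derive_seed()]).
#'
#' @param tokens the source token table (durations not needed; statistics are
#'   computed internally), or a precomputed `bigram_stats`.
#' @param gen a [generating_model()], e.g. from
#'   [calibrate_generating_model()].
#' @param analysis_spec a [model_spec()] fit to every replicate.
#' @param n_reps number of replicates (>= 1).
#' @param master_seed integer master seed.
#' @param predictor_source `"sample"` (predictors re-estimated from each
#'   replicate — the realistic analysis) or `"true"` (the unobtainable
#'   ground-truth predictors — the calibration benchmark).
#' @param multinomial passed to [resample_tokens()].
#' @param freeze_informativity logical; with `predictor_source = "sample"`,
#'   keep informativity frozen at its source-corpus value while
#'   predictability is still re-estimated per replicate.
#' @param unseen passed to [simulate_durations()]: handling of words missing
#'   from a calibrated `word_effects` map (resampling can introduce words
#'   the calibration data never saw).
#' @param log_base base for sample surprisal, matching the source statistics.
#'
#' @return An object of class `null_sim`: a list with `estimates` (data.frame
#'   over replicate x term: `rep`, `term`, `estimate`, `se`, `t`, `df`, `p`,
#'   `converged`), `n_reps`, `n_failed`, `master_seed`, `predictor_source`,
#'   `analysis_spec`, `gen`, `dropped_words` (mean words absent per
#'   replicate).
#' @export
run_null_experiment <- function(tokens, gen, analysis_spec,
                                n_reps, master_seed,
                                predictor_source = c("sample", "true"),
                                multinomial = FALSE,
                                freeze_informativity = FALSE,
                                unseen = c("error", "zero"),
                                log_base = exp(1)) {
  unseen <- match.arg(unseen)
  predictor_source <- match.arg(predictor_source)
  stopifnot(n_reps >= 1, inherits(gen, "generating_model"),
            inherits(analysis_spec, "model_spec"))
  stats <- if (inherits(tokens, "bigram_stats")) tokens
           else compute_bigram_stats(tokens, log_base = log_base)
  n_words_src <- nrow(stats$words)

  res <- vector("list", n_reps)
  n_failed <- 0L
  dropped <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(derive_seed(master_seed, i))
    resampled <- resample_tokens(stats, multinomial = multinomial)
    rep_tab <- build_replicate(resampled, stats)
    dropped[i] <- n_words_src - length(unique(rep_tab$word))
    if (predictor_source == "sample") {
      rep_tab <- estimate_sample_predictors(rep_tab)
      rep_tab$predictability <- rep_tab$predictability_sample
      rep_tab$informativity <- if (freeze_informativity)
        rep_tab$informativity_true else rep_tab$informativity_sample
    } else {
      rep_tab$predictability <- rep_tab$predictability_true
      rep_tab$informativity <- rep_tab$informativity_true
    }
    rep_tab <- simulate_durations(rep_tab, gen, unseen = unseen)
    fit <- tryCatch(fit_duration_model(rep_tab, analysis_spec),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      res[[i]] <- data.frame(rep = i, term = NA_character_,
                             estimate = NA_real_, se = NA_real_,
                             t = NA_real_, df = NA_real_, p = NA_real_,
                             converged = FALSE, stringsAsFactors = FALSE)
    } else {
      cf <- fit$coefficients
      res[[i]] <- data.frame(rep = i, term = cf$term, estimate = cf$estimate,
                             se = cf$se, t = cf$t, df = cf$df, p = cf$p,
                             converged = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (n_failed == n_reps)
    stop("no replicate's analysis model converged")

  structure(list(estimates = do.call(rbind, res),
                 n_reps = n_reps, n_failed = n_failed,
                 master_seed = master_seed,
                 predictor_source = predictor_source,
                 analysis_spec = analysis_spec, gen = gen,
                 dropped_words = mean(dropped)),
            class = "null_sim")
}

#' @export
print.null_sim <- function(x, ...) {
  cat("Null simulation:", x$n_reps, "replicates (",
      x$n_failed, "failed ), predictors:", x$predictor_source, "\n")
  cat("  generating b_pred =", format(x$gen$b_pred),
      ", b_info =", format(x$gen$b_info),
      ", master seed =", x$master_seed, "\n")
  cat("  mean words absent per replicate:", format(x$dropped_words), "\n")
  invisible(x)
}
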