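# Diagnostics over null-simulation coefficient arrays: false-alarm rates,
# spurious-effect means, Monte-Carlo p-values, direction conditionals,
# and the sweep table over generating settings x analysis specs.

# converged rows of one term, as a data.frame (errors if none)
term_estimates <- function(sim, term) {
  stopifnot(inherits(sim, "null_sim"))
  est <- sim$estimates
  rows <- est[est$converged & !is.na(est$term) & est$term == term, ,
              drop = FALSE]
  if (nrow(rows) == 0L) {
    if (sum(est$converged) == 0L) stop("no converged replicates")
    stop("term not found in any converged replicate: ", term)
  }
  rows
}

#' Directional false-alarm rate of a term across null replicates
#'
#' The proportion of converged replicates in which the term is significant
#' (`p < alpha`, two-sided) AND its coefficient has the expected sign — the
#' way a researcher would count a "detection" of an effect whose direction
#' theory predicts. With a two-sided test at `alpha`, the nominal directional
#' rate under a calibrated null is `alpha / 2`.
#'
#' @param sim a `null_sim`.
#' @param term coefficient name, e.g. `"informativity"`.
#' @param expected_sign `+1` or `-1`.
#' @param alpha significance level (default 0.05).
#' @return List: `rate` (directional false-alarm proportion), `rate_sig`
#'   (significance regardless of sign), `sign_rate` (proportion with the
#'   expected sign regardless of significance), `n` (converged replicates).
#' @export
false_alarm_rate <- function(sim, term, expected_sign = 1, alpha = 0.05) {
  stopifnot(expected_sign %in% c(-1, 1), alpha > 0, alpha < 1)
  rows <- term_estimates(sim, term)
  sig <- rows$p < alpha
  dir <- sign(rows$estimate) == expected_sign
  list(rate = mean(sig & dir), rate_sig = mean(sig),
       sign_rate = mean(dir), n = nrow(rows))
}

#' Mean spurious coefficient across null replicates
#'
#' The arithmetic mean of a term's estimates over converged replicates —
#' the expected size of the artifactual effect. Both the mean over all
#' converged replicates (the default) and the mean over significant
#' replicates only are available; they coincide when (nearly) every
#' replicate is significant.
#'
#' @param sim a `null_sim`.
#' @param term coefficient name.
#' @param significant_only average only replicates with
#'   `p < alpha` and the expected sign.
#' @param alpha,expected_sign used when `significant_only = TRUE`.
#' @return The mean estimate (`NA` if `significant_only` selects nothing).
#' @export
spurious_effect_mean <- function(sim, term, significant_only = FALSE,
                                 alpha = 0.05, expected_sign = 1) {
  rows <- term_estimates(sim, term)
  if (significant_only) {
    keep <- rows$p < alpha & sign(rows$estimate) == expected_sign
    if (!any(keep)) return(NA_real_)
    rows <- rows[keep, , drop = FALSE]
  }
  mean(rows$estimate)
}

#' Monte-Carlo p-value of an observed coefficient against the null
#'
#' The fraction of converged null estimates at least as extreme as the
#' observed coefficient in the stated direction. When no null estimate is as
#' extreme, the resolution of the simulation is the bound, reported as
#' `"< 1/n"` (e.g. `"< 0.001"` at 1000 replicates). The add-one estimator
#' `(k + 1) / (n + 1)`, which never returns zero, is available via
#' `plus_one = TRUE`.
#'
#' @param sim a `null_sim`.
#' @param term coefficient name.
#' @param observed the observed (real-data) coefficient.
#' @param direction `"ge"` (null >= observed counts as extreme), `"le"`, or
#'   `"two"` (absolute value).
#' @param plus_one use the `(k + 1)/(n + 1)` estimator.
#' @return List: `p` (numeric proportion, or the add-one estimate), `label`
#'   (printable string, `"< 1/n"` when the count is zero and
#'   `plus_one = FALSE`), `n_exceed`, `n`.
#' @export
mc_pvalue <- function(sim, term, observed, direction = c("ge", "le", "two"),
                      plus_one = FALSE) {
  direction <- match.arg(direction)
  stopifnot(is.finite(observed))
  rows <- term_estimates(sim, term)
  k <- switch(direction,
              ge = sum(rows$estimate >= observed),
              le = sum(rows$estimate <= observed),
              two = sum(abs(rows$estimate) >= abs(observed)))
  n <- nrow(rows)
  if (plus_one) {
    p <- (k + 1) / (n + 1)
    return(list(p = p, label = format(p, digits = 4), n_exceed = k, n = n))
  }
  p <- k / n
  label <- if (k == 0L) paste0("< ", format(1 / n, digits = 4))
           else format(p, digits = 4)
  list(p = p, label = label, n_exceed = k, n = n)
}

#' Co-occurrence of spurious main effects and interactions
#'
#' Three conditional proportions over converged replicates: the directional
#' false-alarm rate on the main term; the probability that the interaction
#' coefficient is in its expected direction given a false alarm on the main
#' term; and the probability that the main coefficient is in its expected
#' direction given a significant directional false alarm on the interaction.
#' Conditioning events with zero members return `NA` (undefined), never 0.
#'
#' @param sim a `null_sim` whose analysis model contains both terms.
#' @param main_term,interaction_term coefficient names.
#' @param alpha significance level.
#' @param expected_sign_main,expected_sign_int expected directions (for a
#'   positive spurious informativity effect the interaction with context
#'   frequency is expected negative: the effect shrinks in frequent
#'   contexts).
#' @return List: `p_fa_main`, `p_int_dir_given_fa_main`,
#'   `p_main_dir_given_fa_int`, `n`.
#' @export
direction_conditionals <- function(sim, main_term = "informativity",
                                   interaction_term = "informativity:context_freq",
                                   alpha = 0.05,
                                   expected_sign_main = 1,
                                   expected_sign_int = -1) {
  main <- term_estimates(sim, main_term)
  intr <- term_estimates(sim, interaction_term)
  common <- intersect(main$rep, intr$rep)
  main <- main[match(common, main$rep), , drop = FALSE]
  intr <- intr[match(common, intr$rep), , drop = FALSE]

  fa_main <- main$p < alpha & sign(main$estimate) == expected_sign_main
  fa_int <- intr$p < alpha & sign(intr$estimate) == expected_sign_int
  int_dir <- sign(intr$estimate) == expected_sign_int
  main_dir <- sign(main$estimate) == expected_sign_main

  cond <- function(event, given) {
    if (!any(given)) return(NA_real_)
    mean(event[given])
  }
  list(p_fa_main = mean(fa_main),
       p_int_dir_given_fa_main = cond(int_dir, fa_main),
       p_main_dir_given_fa_int = cond(main_dir, fa_int),
       n = length(common))
}

#' Sweep generating settings and analysis specs
#'
#' Runs one null experiment per combination of generating coefficients and
#' analysis model, and tabulates the diagnostics: the mean spurious
#' informativity coefficient (over all converged replicates and over
#' significant ones) and the directional false-alarm rate. This reproduces
#' the structure of an effect-size-by-model false-alarm table for any source
#' corpus.
#'
#' @param tokens source token table or `bigram_stats`.
#' @param gen_base a calibrated [generating_model()] supplying the intercept,
#'   residual SD and word effects; its `b_pred`/`b_info` are overridden by
#'   the grid.
#' @param b_pred_values numeric vector of generating predictability
#'   coefficients.
#' @param specs named list of [model_spec()] analysis models.
#' @param n_reps replicates per cell.
#' @param master_seed integer; each cell derives its own stream.
#' @param b_info_values generating informativity coefficients (default 0,
#'   the null).
#' @param term,expected_sign,alpha diagnostic settings for the monitored
#'   coefficient.
#' @param ... passed to [run_null_experiment()] (e.g. `predictor_source`).
#' @return A data.frame with one row per (b_pred, b_info, spec) cell:
#'   `b_pred`, `b_info`, `model`, `mean_spurious`, `mean_spurious_sig`,
#'   `fa_rate`, `fa_rate_sig`, `n_converged`, `n_failed`.
#' @export
sweep_table <- function(tokens, gen_base, b_pred_values, specs,
                        n_reps, master_seed, b_info_values = 0,
                        term = "informativity", expected_sign = 1,
                        alpha = 0.05, ...) {
  stopifnot(length(b_pred_values) >= 1, length(specs) >= 1,
            inherits(gen_base, "generating_model"))
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s)
      paste(s$fixed, collapse = "+"), character(1))
  stats <- if (inherits(tokens, "bigram_stats")) tokens
           else compute_bigram_stats(tokens)
  grid <- expand.grid(b_pred = b_pred_values, b_info = b_info_values,
                      model = names(specs), stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    gen <- gen_base
    gen$b_pred <- grid$b_pred[g]
    gen$b_info <- grid$b_info[g]
    sim <- run_null_experiment(stats, gen, specs[[grid$model[g]]],
                               n_reps = n_reps,
                               master_seed = derive_seed(master_seed, g),
                               ...)
    fa <- false_alarm_rate(sim, term, expected_sign, alpha)
    out[[g]] <- data.frame(
      b_pred = grid$b_pred[g], b_info = grid$b_info[g],
      model = grid$model[g],
      mean_spurious = spurious_effect_mean(sim, term),
      mean_spurious_sig = spurious_effect_mean(sim, term,
                                               significant_only = TRUE,
                                               alpha = alpha,
                                               expected_sign = expected_sign),
      fa_rate = fa$rate, fa_rate_sig = fa$rate_sig,
      n_converged = fa$n, n_failed = sim$n_failed,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
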