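#' Configuration for a synthetic Zipfian bigram corpus
#'
#' Describes a fully synthetic corpus with known ground truth, shaped like
#' the conversational-speech data the diagnostic targets: context (preceding
#' word) and word frequencies follow Zipfian rank-frequency laws with
#' exponent near 1 — so a large share of contexts occur exactly once — and
#' each context carries its own conditional word distribution, drawn from a
#' Dirichlet centered on the global word distribution. That gives genuinely
#' context-dependent predictability while preserving stable between-word
#' differences in average predictability, so that informativity varies
#' across words and anti-correlates strongly with predictability, as in real
#' corpora. Log durations are generated from a [generating_model()] using
#' the TRUE conditional probabilities.
#'
#' The defaults give a 2,000-token corpus over 500 context types and 400
#' word types with `b_info = 0` (the null regime), an intercept and
#' predictability slope in the range reported for conversational English
#' content words, and noise magnitudes (`sigma_word`, `sigma_resid`) chosen
#' so the predictors explain a realistic minority share of duration variance.
#'
#' @param n_context_types,n_word_types inventory sizes.
#' @param zipf_exponent exponent of the context and word rank-frequency laws
#'   (> 0, ~1 for natural language).
#' @param conditional_sharpness how context-specific the conditional word
#'   distributions are (> 0). Under the default `"lognormal"` family it is
#'   the standard deviation, in nats, of each word's context-specific
#'   deviation from its global log probability: a word's log conditional
#'   probability is stable to within about this many nats across contexts.
#'   Larger values mean stronger context-dependence of predictability.
#' @param n_tokens number of tokens to sample.
#' @param b0,b_pred,b_info,sigma_word,sigma_resid the generating duration
#'   model (see [generating_model()]).
#' @param conditional_family conditional-distribution family:
#'   \describe{
#'     \item{`"lognormal"`}{(default) `q(w | c)` proportional to
#'       `p_global(w) * exp(conditional_sharpness * z)`, `z` i.i.d. standard
#'       normal. Zipfian marginals, heavy-tailed context-specific
#'       conditionals, and stable between-word differences in average
#'       predictability — hence the strong predictability/informativity
#'       anti-correlation characteristic of real corpora.}
#'     \item{`"dirichlet"`}{Dirichlet centered on the global word
#'       distribution with concentration
#'       `n_word_types * p_global / conditional_sharpness`. Rare words get
#'       concentration well below 1, so their conditionals are much less
#'       stable across contexts than under `"lognormal"`.}
#'     \item{`"permutation"`}{each context's conditional is the same Zipf
#'       shape over an independent random permutation of the word inventory.
#'       Every word then has the same expected conditional probability, so
#'       true informativity is nearly constant across words — a no-signal
#'       control, not a realistic corpus.}
#'   }
#' @param seed integer seed for the whole generation.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_context_types = 500, n_word_types = 400,
                         zipf_exponent = 1, conditional_sharpness = 1,
                         n_tokens = 2000,
                         b0 = -2.27, b_pred = -0.05, b_info = 0,
                         sigma_word = 0.25, sigma_resid = 0.35,
                         conditional_family = c("lognormal", "dirichlet",
                                                "permutation"),
                         seed = 1L) {
  conditional_family <- match.arg(conditional_family)
  stopifnot(n_context_types >= 1, n_word_types >= 1, n_tokens >= 1,
            zipf_exponent > 0, conditional_sharpness > 0,
            sigma_resid > 0, sigma_word >= 0)
  if (n_tokens < n_context_types)
    warning("n_tokens < n_context_types: most contexts will be unobserved")
  structure(list(n_context_types = as.integer(n_context_types),
                 n_word_types = as.integer(n_word_types),
                 zipf_exponent = zipf_exponent,
                 conditional_sharpness = conditional_sharpness,
                 n_tokens = as.integer(n_tokens),
                 b0 = b0, b_pred = b_pred, b_info = b_info,
                 sigma_word = sigma_word, sigma_resid = sigma_resid,
                 conditional_family = conditional_family,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic Zipfian bigram corpus with known ground truth
#'
#' Samples a corpus from the structure described by [synth_config()]:
#' context types are drawn i.i.d. from a Zipf marginal
#' (`P(c) proportional to rank^-zipf_exponent`), the word following each
#' context token is drawn from that context's conditional distribution, and
#' each token's log duration is drawn from the generating model using its
#' TRUE predictability (`log p(w | c)`) and TRUE informativity
#' (`-E[log p(w | c) | w]` under the latent joint distribution), exactly as
#' [simulate_durations()] does.
#'
#' The observable token table and the latent truth are returned side by
#' side, so the estimation error of every downstream statistic can be
#' measured.
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_corpus`: a list with
#'   \describe{
#'     \item{tokens}{a `token_table` with `duration_log` — the observable
#'       corpus.}
#'     \item{truth}{a list: `p_true` (word x context conditional probability
#'       matrix), `context_probs`, `informativity_true` (named per-word,
#'       nats), `word_effects` (named per-word), `config`.}
#'   }
#' @export
#' @examples
#' corp <- generate_corpus(synth_config(n_context_types = 20,
#'                                      n_word_types = 15, n_tokens = 200))
#' head(corp$tokens)
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  C <- config$n_context_types
  W <- config$n_word_types
  if (C == 1L && W == 1L && config$sigma_resid == 0)
    warning("degenerate configuration: single context and word")
  set.seed(config$seed)

  # Zipf marginal over context types
  pc <- (seq_len(C))^(-config$zipf_exponent)
  pc <- pc / sum(pc)

  # global Zipfian word distribution
  pw_global <- (seq_len(W))^(-config$zipf_exponent)
  pw_global <- pw_global / sum(pw_global)

  # conditional word distribution per context: W x C matrix
  Q <- matrix(0, nrow = W, ncol = C)
  if (config$conditional_family == "lognormal") {
    Z <- matrix(stats::rnorm(W * C), nrow = W, ncol = C)
    Q <- pw_global * exp(config$conditional_sharpness * Z)
    Q <- sweep(Q, 2, colSums(Q), `/`)
  } else if (config$conditional_family == "dirichlet") {
    # Dirichlet centered on the global word distribution; smaller total
    # concentration = sharper, more context-specific conditionals
    alpha <- W * pw_global / config$conditional_sharpness
    for (ci in seq_len(C)) {
      g <- stats::rgamma(W, shape = alpha)
      s <- sum(g)
      if (s == 0) { g <- pw_global; s <- 1 } # guard extreme sharpness
      Q[, ci] <- g / s
    }
    # rgamma(shape < ~1e-3) can return exact zeros; keep support positive
    # so every (word, context) pair has p > 0 and log p is finite
    if (any(Q == 0)) {
      Q <- Q + 1e-12
      Q <- sweep(Q, 2, colSums(Q), `/`)
    }
  } else {
    base <- sort(pw_global, decreasing = TRUE)
    for (ci in seq_len(C)) {
      perm <- sample.int(W)        # context-specific word ranking
      Q[perm, ci] <- base
    }
  }
  context_names <- sprintf("c%04d", seq_len(C))
  word_names <- sprintf("w%04d", seq_len(W))
  dimnames(Q) <- list(word_names, context_names)

  # latent informativity: I(w) = -sum_c P(c | w) log p(w | c)
  joint <- sweep(Q, 2, pc, `*`)              # P(w, c)
  pw <- rowSums(joint)
  info_true <- -rowSums(joint * log(Q)) / pw
  names(info_true) <- word_names

  word_effects <- stats::setNames(
    stats::rnorm(W, 0, config$sigma_word), word_names)

  cx_tok <- sample.int(C, config$n_tokens, replace = TRUE, prob = pc)
  w_tok <- integer(config$n_tokens)
  for (ci in unique(cx_tok)) {
    rows <- which(cx_tok == ci)
    w_tok[rows] <- sample.int(W, length(rows), replace = TRUE, prob = Q[, ci])
  }

  pred_true <- log(Q[cbind(w_tok, cx_tok)])
  gen <- generating_model(b0 = config$b0, b_pred = config$b_pred,
                          b_info = config$b_info,
                          word_effects = word_effects,
                          sigma_word = config$sigma_word,
                          sigma_resid = config$sigma_resid)
  tok_df <- data.frame(word = word_names[w_tok],
                       context = context_names[cx_tok],
                       predictability_true = pred_true,
                       informativity_true = info_true[w_tok],
                       stringsAsFactors = FALSE)
  tok_df <- simulate_durations(tok_df, gen)

  tokens <- token_table(word = tok_df$word, context = tok_df$context,
                        duration_log = tok_df$duration_log)

  structure(list(tokens = tokens,
                 truth = list(p_true = Q, context_probs = pc,
                              informativity_true = info_true,
                              word_effects = word_effects,
                              predictability_true = pred_true,
                              gen = gen, config = config)),
            class = "synth_corpus")
}

#' Ground-truth bigram statistics for a synthetic corpus
#'
#' Builds a `bigram_stats` object whose probabilities are the LATENT
#' generating probabilities rather than the sample relative frequencies:
#' conditional probabilities come from the generator's `p_true` matrix,
#' informativity from the latent joint distribution, while context
#' frequencies are the observed token counts (the number of binomial
#' "trials" each context provides). This mirrors the situation the
#' diagnostic targets in real data, where probability estimates attached to
#' an analyzed sample come from a much larger corpus and are treated as the
#' truth: in particular a context observed once can still carry a
#' conditional probability far from 0 or 1. The pair table covers the full
#' word inventory for every observed context (`n_pair` holds expected, not
#' integer, counts), so resampling can produce words the original sample
#' missed.
#'
#' @param corpus a `synth_corpus` from [generate_corpus()].
#' @return A `bigram_stats` with latent probabilities and observed context
#'   frequencies.
#' @seealso [compute_bigram_stats()] for sample relative-frequency
#'   statistics of the same tokens.
#' @export
truth_stats <- function(corpus) {
  stopifnot(inherits(corpus, "synth_corpus"))
  Q <- corpus$truth$p_true
  toks <- corpus$tokens
  ucx <- unique(toks$context)
  n_cx <- tabulate(match(toks$context, ucx), nbins = length(ucx))
  W <- nrow(Q)
  pairs <- data.frame(context = rep(ucx, each = W),
                      word = rep(rownames(Q), times = length(ucx)),
                      stringsAsFactors = FALSE)
  pairs$p <- as.vector(Q[, ucx, drop = FALSE])
  pairs$predictability <- log(pairs$p)
  pairs$n_pair <- pairs$p * rep(n_cx, each = W)
  words <- data.frame(word = rownames(Q),
                      n_w = as.vector(rowsum(pairs$n_pair,
                                             match(pairs$word, rownames(Q)),
                                             reorder = TRUE)),
                      informativity = as.vector(corpus$truth$informativity_true),
                      stringsAsFactors = FALSE)
  words$mean_predictability <- -words$informativity
  structure(list(pairs = pairs, words = words,
                 contexts = data.frame(context = ucx, n_cx = n_cx,
                                       stringsAsFactors = FALSE),
                 log_base = exp(1), n_tokens = nrow(toks)),
            class = "bigram_stats")
}

#' @export
print.synth_corpus <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic Zipfian corpus:", cfg$n_tokens, "tokens,",
      cfg$n_context_types, "context types,", cfg$n_word_types,
      "word types (seed", cfg$seed, ")\n")
  cat(sprintf("  generating: b0 = %.3f, b_pred = %.3f, b_info = %.3f, sigma_word = %.3f, sigma_resid = %.3f\n",
              cfg$b0, cfg$b_pred, cfg$b_info, cfg$sigma_word,
              cfg$sigma_resid))
  invisible(x)
}
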