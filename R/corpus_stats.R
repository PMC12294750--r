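#' Bigram statistics: conditional probabilities, predictability, informativity
#'
#' Computes maximum-likelihood (unsmoothed relative-frequency) bigram
#' statistics from a token table. For every observed (context, word) pair the
#' conditional probability is `p(w | cx) = n(w, cx) / n_cx`, predictability is
#' its logarithm (forward bigram surprisal with a flipped sign, so always
#' less than or equal to 0), and a word's informativity is its token-weighted
#' mean surprisal across the contexts in which it occurs:
#' `I(w) = -(1/n_w) * sum over tokens of w of log p(w | cx of token)`.
#'
#' No smoothing (add-k, back-off) is applied: the whole point of the
#' downstream diagnostic is to study the raw, noisy in-context estimates, so
#' smoothing would contaminate it.
#'
#' @param tokens a `token_table` (durations not required).
#' @param log_base base for all logarithms. The default `exp(1)` puts
#'   predictability and informativity in nats; `2` gives bits. The choice
#'   rescales regression coefficients linearly and changes nothing else.
#'
#' @return An object of class `bigram_stats`: a list with
#'   \describe{
#'     \item{pairs}{data.frame: `context`, `word`, `n_pair`, `p`
#'       (conditional probability), `predictability` (log p, <= 0).}
#'     \item{words}{data.frame: `word`, `n_w`, `informativity` (>= 0),
#'       `mean_predictability` (= -informativity).}
#'     \item{contexts}{data.frame: `context`, `n_cx`.}
#'     \item{log_base, n_tokens}{bookkeeping.}
#'   }
#' @export
#' @examples
#' toks <- token_table(word    = c("w1", "w1", "w2", "w1"),
#'                     context = c("A", "A", "A", "B"))
#' st <- compute_bigram_stats(toks)
#' st$pairs
#' st$words   # I(w1) ~ 0.2703 nats, I(w2) = log(3)
compute_bigram_stats <- function(tokens, log_base = exp(1)) {
  tokens <- validate_token_table(tokens)
  if (nrow(tokens) == 0L) stop("cannot compute bigram statistics from an empty token table")
  stopifnot(is.numeric(log_base), length(log_base) == 1, log_base > 1)

  key <- paste(tokens$context, tokens$word, sep = "\x1f")
  ukey <- unique(key)
  pair_idx <- match(key, ukey)
  n_pair <- tabulate(pair_idx, nbins = length(ukey))
  first <- match(ukey, key)
  pairs <- data.frame(context = tokens$context[first],
                      word = tokens$word[first],
                      n_pair = n_pair, stringsAsFactors = FALSE)

  ucx <- unique(pairs$context)
  cx_idx <- match(pairs$context, ucx)
  n_cx <- as.vector(rowsum(pairs$n_pair, cx_idx, reorder = TRUE))
  contexts <- data.frame(context = ucx, n_cx = n_cx, stringsAsFactors = FALSE)

  pairs$p <- pairs$n_pair / contexts$n_cx[cx_idx]
  pairs$predictability <- log(pairs$p, base = log_base)

  uw <- unique(pairs$word)
  w_idx <- match(pairs$word, uw)
  n_w <- as.vector(rowsum(pairs$n_pair, w_idx, reorder = TRUE))
  # token-weighted mean surprisal: each pair contributes n_pair tokens
  surp_sum <- as.vector(rowsum(pairs$n_pair * (-pairs$predictability),
                               w_idx, reorder = TRUE))
  words <- data.frame(word = uw, n_w = n_w,
                      informativity = surp_sum / n_w,
                      stringsAsFactors = FALSE)
  words$mean_predictability <- -words$informativity

  structure(list(pairs = pairs, words = words, contexts = contexts,
                 log_base = log_base, n_tokens = nrow(tokens)),
            class = "bigram_stats")
}

#' @export
print.bigram_stats <- function(x, ...) {
  cat("Bigram statistics:", x$n_tokens, "tokens,",
      nrow(x$pairs), "pairs,", nrow(x$words), "word types,",
      nrow(x$contexts), "context types\n")
  cat("log base:", format(x$log_base), "\n")
  invisible(x)
}

#' Attach predictability, informativity and context frequency to tokens
#'
#' Adds the regressors used by the duration models to each token row:
#' `predictability` (log conditional probability of the token's word given
#' its context), `informativity` (the word's average surprisal) and
#' `context_freq` (the context's token frequency, raw counts).
#'
#' @param tokens a `token_table`.
#' @param stats a `bigram_stats`, normally computed from the same tokens.
#' @return The token table with the three predictor columns added.
#' @export
attach_predictors <- function(tokens, stats) {
  tokens <- validate_token_table(tokens)
  stopifnot(inherits(stats, "bigram_stats"))
  key <- paste(tokens$context, tokens$word, sep = "\x1f")
  pkey <- paste(stats$pairs$context, stats$pairs$word, sep = "\x1f")
  i <- match(key, pkey)
  if (anyNA(i)) {
    bad <- which(is.na(i))[1]
    stop(sprintf("(context, word) pair not present in stats: (%s, %s)",
                 tokens$context[bad], tokens$word[bad]))
  }
  tokens$predictability <- stats$pairs$predictability[i]
  j <- match(tokens$word, stats$words$word)
  tokens$informativity <- stats$words$informativity[j]
  k <- match(tokens$context, stats$contexts$context)
  tokens$context_freq <- stats$contexts$n_cx[k]
  tokens
}
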