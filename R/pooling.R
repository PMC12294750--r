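#' Adaptive partial pooling of an in-context and an across-context estimate
#'
#' Closed-form precision-weighted combination of a local (in-context) estimate
#' of some word characteristic with the word's across-context average:
#' \deqn{\hat\alpha_{w|cx} = w_{loc}\,\alpha_{w|cx} + (1 - w_{loc})\,\alpha_w,
#'   \quad w_{loc} = \frac{n_{cx}/\sigma^2_{cx}}
#'     {n_{cx}/\sigma^2_{cx} + 1/\sigma^2_w}}
#' where `n_cx` is the context's frequency, `var_within` (\eqn{\sigma^2_{cx}})
#' the variance of the characteristic across words within the context, and
#' `var_between` (\eqn{\sigma^2_w}) the variance of word averages across
#' words. The local estimate dominates when the context is frequent and words
#' vary little within it; the across-context average dominates otherwise.
#'
#' All arguments are vectorized and recycled. Edge cases: `n_cx = 0` returns
#' the global estimate (zero local weight); `var_within = 0` with `n_cx > 0`
#' means infinite local precision and returns the local estimate (a message
#' notes how often this happened).
#'
#' @param alpha_local in-context estimate(s).
#' @param alpha_global across-context average(s).
#' @param n_cx context frequency (non-negative).
#' @param var_within variance of the characteristic across words within the
#'   context (>= 0).
#' @param var_between variance of word averages across words (> 0).
#'
#' @return Numeric vector of pooled estimates; each lies in the closed
#'   interval between its `alpha_local` and `alpha_global`.
#' @export
#' @examples
#' partial_pool(0.5, -0.5, n_cx = 4, var_within = 2, var_between = 1) # 1/6
partial_pool <- function(alpha_local, alpha_global, n_cx,
                         var_within, var_between) {
  n <- max(length(alpha_local), length(alpha_global), length(n_cx),
           length(var_within), length(var_between))
  alpha_local <- rep_len(alpha_local, n)
  alpha_global <- rep_len(alpha_global, n)
  n_cx <- rep_len(n_cx, n)
  var_within <- rep_len(var_within, n)
  var_between <- rep_len(var_between, n)
  if (any(!is.finite(var_between)) || any(var_between <= 0))
    stop("`var_between` must be strictly positive")
  if (any(var_within < 0)) stop("`var_within` must be non-negative")
  if (any(n_cx < 0)) stop("`n_cx` must be non-negative")

  w <- numeric(n)
  zero_var <- var_within == 0
  exact <- zero_var & n_cx > 0
  if (any(exact)) {
    message(sprintf(
      "partial_pool: %d case(s) with var_within = 0 and n_cx > 0; returning the local estimate",
      sum(exact)))
    w[exact] <- 1
  }
  ok <- !zero_var
  prec_loc <- n_cx[ok] / var_within[ok]
  w[ok] <- prec_loc / (prec_loc + 1 / var_between[ok])
  # n_cx = 0 (with any var_within) gives zero local weight
  w[n_cx == 0] <- 0
  w * alpha_local + (1 - w) * alpha_global
}

#' Shrunken predictability for every bigram pair
#'
#' Applies [partial_pool()] across all (context, word) pairs of a
#' `bigram_stats` object, pooling each pair's in-context predictability with
#' the word's across-context mean predictability (minus its informativity).
#' The within-context variance is the variance of predictability across the
#' word types observed in that context; contexts with a single observed word
#' type, where that sample variance is undefined, fall back to the average
#' within-context variance (documented per run via the returned columns). The
#' between-word variance is the variance of word mean predictability across
#' word types.
#'
#' Pooling is performed on the scale the statistics are stored on
#' (log-probability); the scale is recorded in the result attributes.
#'
#' @param stats a `bigram_stats`.
#' @return The `stats$pairs` data.frame with columns `alpha_global`,
#'   `var_within`, `pooled_predictability` added; attributes `var_between`
#'   and `scale` record the run's pooling inputs.
#' @export
pool_predictability <- function(stats) {
  stopifnot(inherits(stats, "bigram_stats"))
  pairs <- stats$pairs
  cx_idx <- match(pairs$context, stats$contexts$context)
  w_idx <- match(pairs$word, stats$words$word)

  alpha_global <- stats$words$mean_predictability[w_idx]

  # type-level variance of predictability within each context
  n_types <- tabulate(cx_idx, nbins = nrow(stats$contexts))
  s1 <- as.vector(rowsum(pairs$predictability, cx_idx, reorder = TRUE))
  s2 <- as.vector(rowsum(pairs$predictability^2, cx_idx, reorder = TRUE))
  vw <- rep(NA_real_, nrow(stats$contexts))
  multi <- n_types > 1
  vw[multi] <- (s2[multi] - s1[multi]^2 / n_types[multi]) / (n_types[multi] - 1)
  vw[multi] <- pmax(vw[multi], 0) # guard tiny negative from rounding
  fallback <- if (any(multi)) mean(vw[multi]) else 1
  vw[!multi] <- fallback

  var_between <- stats::var(stats$words$mean_predictability)
  if (!is.finite(var_between) || var_between <= 0) {
    # degenerate corpus (single word type): no across-word information
    var_between <- 1
    warning("between-word variance is degenerate; using var_between = 1")
  }

  pairs$alpha_global <- alpha_global
  pairs$var_within <- vw[cx_idx]
  pairs$pooled_predictability <- suppressMessages(partial_pool(
    alpha_local = pairs$predictability,
    alpha_global = alpha_global,
    n_cx = stats$contexts$n_cx[cx_idx],
    var_within = pairs$var_within,
    var_between = var_between))
  attr(pairs, "var_between") <- var_between
  attr(pairs, "scale") <- "log-probability"
  pairs
}
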