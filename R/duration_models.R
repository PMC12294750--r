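#' Specify a duration regression model
#'
#' Describes the fixed- and random-effects structure of a duration model.
#' Fixed terms are drawn from the predictor columns produced by
#' [attach_predictors()] plus their interactions with raw context frequency;
#' random terms are a by-word intercept and optionally a by-word
#' predictability slope. Interactions are only allowed when both parent main
#' effects are present, and random terms only with a mixed estimator.
#'
#' @param fixed character vector of fixed-effect terms, a subset of
#'   `"predictability"`, `"informativity"`, `"context_freq"`,
#'   `"predictability:context_freq"`, `"informativity:context_freq"`.
#'   The intercept is always included.
#' @param random character vector of random terms: `"intercept"` for
#'   `(1 | word)` and/or `"predictability"` for a correlated by-word
#'   predictability slope. Empty (the default) selects ordinary least squares.
#' @param reml logical; fit mixed models by REML (default) or ML.
#' @param response name of the response column, default `"duration_log"`.
#'
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec(c("predictability", "informativity"))
#' model_spec(c("predictability", "informativity"), random = "intercept")
model_spec <- function(fixed = c("predictability", "informativity"),
                       random = character(), reml = TRUE,
                       response = "duration_log") {
  allowed_fixed <- c("predictability", "informativity", "context_freq",
                     "predictability:context_freq",
                     "informativity:context_freq")
  bad <- setdiff(fixed, allowed_fixed)
  if (length(bad)) stop("unknown fixed term(s): ", paste(bad, collapse = ", "))
  for (term in grep(":", fixed, value = TRUE)) {
    parents <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(parents %in% fixed))
      stop("interaction `", term, "` requires both parent main effects")
  }
  bad_r <- setdiff(random, c("intercept", "predictability"))
  if (length(bad_r)) stop("unknown random term(s): ", paste(bad_r, collapse = ", "))
  if ("predictability" %in% random && !"intercept" %in% random)
    stop("a random predictability slope requires the random intercept")
  structure(list(fixed = fixed, random = random,
                 estimator = if (length(random)) "mixed" else "ols",
                 reml = isTRUE(reml), response = response),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec (", x$estimator, "): ",
      deparse(spec_formula(x)), "\n", sep = "")
  invisible(x)
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  if (length(spec$random)) {
    re <- if ("predictability" %in% spec$random) "(1 + predictability | word)"
          else "(1 | word)"
    rhs <- paste(rhs, re, sep = " + ")
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Fit a duration regression
#'
#' Fits log word duration on the predictors named in a [model_spec()], by
#' ordinary least squares (`lm`) or as a Gaussian mixed model with a by-word
#' random intercept (and optional predictability slope) via
#' [lmerTest::lmer()]. Mixed-model p-values use Satterthwaite degrees of
#' freedom; if the Satterthwaite computation fails the fit falls back to a
#' normal approximation and records it in `df_method`. A fit that triggers an
#' lme4 convergence warning is flagged `converged = FALSE` and should be
#' excluded downstream (simulation loops do this automatically).
#'
#' @param data a token table augmented with the predictor columns the spec
#'   names (see [attach_predictors()]), plus the response column.
#' @param spec a [model_spec()].
#'
#' @return An object of class `fit_result`: a list with `coefficients` (one
#'   row per term: `term`, `estimate`, `se`, `t`, `df`, `p`), `var_word`,
#'   `var_resid`, `r2` (list with `r2_adjusted` for OLS, `r2_marginal` and
#'   `r2_conditional` for mixed fits), `converged`, `df_method`, `n`,
#'   `estimator` and the fitted model object in `$model`.
#' @export
#' @examples
#' d <- data.frame(duration_log = c(0, 1, 2, 3, 5),
#'                 predictability = c(0, -1, -2, -3, -4),
#'                 informativity = 0, word = "w", context = "c")
#' fit <- fit_duration_model(d, model_spec("predictability"))
#' fit$coefficients
fit_duration_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  need <- c(spec$response, vars, if (length(spec$random)) "word")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  for (v in c(spec$response, vars))
    if (any(!is.finite(data[[v]])))
      stop("non-finite values in `", v, "`")
  p_fixed <- length(spec$fixed) + 1L
  if (nrow(data) < p_fixed + 1L)
    stop("too few rows (", nrow(data), ") for ", p_fixed, " fixed terms")

  f <- spec_formula(spec)
  if (spec$estimator == "ols") {
    fit <- stats::lm(f, data = data)
    cf <- stats::coef(fit)
    if (anyNA(cf))
      stop("rank-deficient design; aliased term(s): ",
           paste(names(cf)[is.na(cf)], collapse = ", "))
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        # noiseless oracle fixtures interpolate exactly; that is not a defect
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    ct <- sm$coefficients
    coefs <- data.frame(term = rownames(ct), estimate = ct[, 1],
                        se = ct[, 2], t = ct[, 3],
                        df = fit$df.residual, p = ct[, 4],
                        row.names = NULL, stringsAsFactors = FALSE)
    res <- structure(list(
      coefficients = coefs,
      var_word = 0,
      var_resid = sm$sigma^2,
      r2 = list(r2_adjusted = sm$adj.r.squared, r2 = sm$r.squared,
                r2_marginal = NA_real_, r2_conditional = NA_real_),
      converged = TRUE, df_method = "residual",
      n = nrow(data), estimator = "ols", spec = spec, model = fit),
      class = "fit_result")
    return(res)
  }

  if ("predictability" %in% spec$random) {
    n_rep <- max(tabulate(match(data$word, unique(data$word))))
    if (n_rep < 2L)
      stop("random predictability slope requires repeated words in the data")
  }

  converged <- TRUE
  fit <- withCallingHandlers(
    lmerTest::lmer(f, data = data, REML = spec$reml),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })

  df_method <- "satterthwaite"
  ct <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(ct) || ncol(ct) < 5) {
    # Satterthwaite failed: normal approximation on the t statistic
    df_method <- "normal"
    ct0 <- summary(fit, ddf = "lme4")$coefficients
    ct <- cbind(ct0[, 1:2, drop = FALSE], df = Inf,
                t = ct0[, 3], p = 2 * stats::pnorm(-abs(ct0[, 3])))
    ct <- ct[, c(1, 2, 4, 3, 5), drop = FALSE]
    colnames(ct) <- c("Estimate", "Std. Error", "t value", "df", "Pr(>|t|)")
    coefs <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                        t = ct[, 3], df = ct[, 4], p = ct[, 5],
                        row.names = NULL, stringsAsFactors = FALSE)
  } else {
    coefs <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                        se = ct[, "Std. Error"], t = ct[, "t value"],
                        df = ct[, "df"], p = ct[, "Pr(>|t|)"],
                        row.names = NULL, stringsAsFactors = FALSE)
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_word <- sum(vc$vcov[which(vc$grp == "word" &
                                  vc$var1 == "(Intercept)" &
                                  is.na(vc$var2))])
  var_resid <- vc$vcov[which(vc$grp == "Residual")]
  r2 <- nakagawa_r2(fit,
                    var_word_total = sum(vc$vcov[which(vc$grp != "Residual" &
                                                         is.na(vc$var2))]),
                    var_resid = var_resid)

  structure(list(coefficients = coefs, var_word = var_word,
                 var_resid = var_resid, r2 = r2,
                 converged = converged, df_method = df_method,
                 n = nrow(data), estimator = "mixed", spec = spec,
                 model = fit),
            class = "fit_result")
}

# Marginal and conditional R^2 for a Gaussian mixed model:
# var_fixed / (var_fixed + var_random + var_resid) and
# (var_fixed + var_random) / (same denominator), with var_fixed the variance
# of the fixed-effects linear predictor over the data.
nakagawa_r2 <- function(fit, var_word_total, var_resid) {
  X <- lme4::getME(fit, "X")
  var_fixed <- stats::var(as.vector(X %*% lme4::fixef(fit)))
  denom <- var_fixed + var_word_total + var_resid
  list(r2_adjusted = NA_real_, r2 = NA_real_,
       r2_marginal = var_fixed / denom,
       r2_conditional = (var_fixed + var_word_total) / denom)
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat("Duration model (", x$estimator, ", n = ", x$n, ", df method: ",
      x$df_method, ")\n", sep = "")
  cf <- x$coefficients
  cf[c("estimate", "se", "t", "df")] <-
    lapply(cf[c("estimate", "se", "t", "df")], signif, digits)
  cf$p <- format.pval(cf$p, digits = 3)
  print(cf, row.names = FALSE)
  if (x$estimator == "ols") {
    cat(sprintf("Adjusted R^2 = %.4f; residual variance = %.5f\n",
                x$r2$r2_adjusted, x$var_resid))
  } else {
    cat(sprintf(
      "Marginal R^2 = %.4f; conditional R^2 = %.4f; var(word) = %.5f; var(resid) = %.5f\n",
      x$r2$r2_marginal, x$r2$r2_conditional, x$var_word, x$var_resid))
    if (!x$converged) cat("NOTE: fit did not converge\n")
  }
  invisible(x)
}

#' Fit statistics of a duration model
#'
#' Returns the R-squared family of a fitted model: adjusted R-squared
#' (`1 - (1 - R^2)(n - 1)/(n - p - 1)`) for OLS fits, and marginal
#' (`var_fixed / (var_fixed + var_word + var_resid)`) and conditional
#' (`(var_fixed + var_word) / (...)`) R-squared for mixed fits. When `data`
#' is supplied the statistics are recomputed from scratch; otherwise the
#' values stored at fit time are returned.
#'
#' @param fit a `fit_result` (must have converged).
#' @param data optional data to recompute on (the fitting data).
#' @return List with `r2_adjusted`, `r2_marginal`, `r2_conditional`.
#' @export
compute_fit_stats <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("fit did not converge; statistics unavailable")
  if (is.null(data)) {
    return(fit$r2[c("r2_adjusted", "r2_marginal", "r2_conditional")])
  }
  if (fit$estimator == "ols") {
    n <- nrow(data)
    p <- length(stats::coef(fit$model)) - 1L
    if (n <= p + 1L) stop("adjusted R^2 undefined: n <= p + 1")
    y <- data[[fit$spec$response]]
    e <- y - stats::predict(fit$model, newdata = data)
    r2 <- 1 - sum(e^2) / sum((y - mean(y))^2)
    list(r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - p - 1),
         r2_marginal = NA_real_, r2_conditional = NA_real_)
  } else {
    fit$r2[c("r2_adjusted", "r2_marginal", "r2_conditional")]
  }
}

#' Change in adjusted R-squared between nested models
#'
#' Compares a full and a reduced fit of the same data and returns the drop in
#' adjusted R-squared in percentage points (e.g. `3` means the reduced model
#' explains 3 points less adjusted variance). Used to quantify how much a
#' predictor adds over its collinear partner.
#'
#' @param full,reduced converged OLS `fit_result`s on the same rows;
#'   `reduced`'s fixed terms must be a subset of `full`'s.
#' @return Numeric: `100 * (adjR2_full - adjR2_reduced)`.
#' @export
compare_nested <- function(full, reduced) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  if (!all(reduced$spec$fixed %in% full$spec$fixed))
    stop("`reduced` terms are not a subset of `full` terms")
  if (full$n != reduced$n)
    stop("models were fit to different numbers of rows")
  if (full$estimator != "ols" || reduced$estimator != "ols")
    stop("adjusted R^2 comparison is defined for OLS fits")
  100 * (full$r2$r2_adjusted - reduced$r2$r2_adjusted)
}
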