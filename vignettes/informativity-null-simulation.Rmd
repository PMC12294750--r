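---
title: "Is an informativity effect a predictability effect in disguise? Methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Is an informativity effect a predictability effect in disguise? Methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infosim)
```

## The model and its assumptions

`infosim` asks a narrow, sharp question about duration regressions of the
form

$$\log d_i = \beta_0 + \beta_P \,\mathrm{pred}_i + \beta_I \,\mathrm{inf}_i
  + u_{w(i)} + \varepsilon_i,$$

where `pred` is bigram predictability ($\log p(w \mid cx)$, in nats),
`inf` is informativity (the word's token-weighted mean surprisal),
$u_w$ an optional by-word random intercept, and $\varepsilon$ Gaussian
noise: *if durations were driven by true predictability alone
($\beta_I = 0$), how often and how strongly would this regression
nonetheless report an informativity effect?*

The mechanism under study is estimation noise, not speaker behavior.
$p(w \mid cx)$ is estimated from $n_{cx}$ observations of the context;
when $n_{cx}$ is small the estimate is coarse (with one observation it is
0 or 1 regardless of the underlying probability). Informativity, an
average over all the word's occurrences, is exactly the across-context
quantity that adaptive partial pooling

$$\hat\alpha_{w|cx} =
  \frac{n_{cx}/\sigma^2_{cx}}{n_{cx}/\sigma^2_{cx} + 1/\sigma^2_w}\,
  \alpha_{w|cx} +
  \frac{1/\sigma^2_w}{n_{cx}/\sigma^2_{cx} + 1/\sigma^2_w}\,\alpha_w$$

would blend with the in-context estimate, with weight governed by context
frequency. So whenever the measured predictability diverges from the
predictability that actually drove durations, the informativity regressor
can recover part of the lost signal — producing a positive coefficient
(opposing a negative $\beta_P$) with no true informativity effect, and an
apparent informativity-by-context-frequency interaction (the "effect"
concentrates in rare contexts, where the noise is).

Key assumptions, inherited by every conclusion the diagnostic supports:

- the source probabilities used as simulation truth are an unbiased
  estimate of the probabilities driving behavior;
- durations are conditionally Gaussian on the log scale, with no true
  interaction terms in the generating process;
- context frequencies are fixed at their observed values across replicates
  (resampling them multinomially is available via `multinomial = TRUE` but
  changes little, since the binomial trial counts dominate).

## The simulation procedure

`run_null_experiment()` executes, per replicate:

1. **Resample counts.** For every (context, word) pair,
   $k \sim \mathrm{Binomial}(n_{cx},\, p(w \mid cx))$, independently
   across pairs (`resample_tokens()`). Counts within a context are *not*
   constrained to sum to $n_{cx}$; each context token is a "trial" on
   which the word occurs or not. Pairs with $k = 0$ contribute no tokens.
2. **Re-estimate predictors** (`estimate_sample_predictors()`, used when
   `predictor_source = "sample"`): $\hat p = k / n_{cx}$, sample
   predictability $\log \hat p$, sample informativity the token-weighted
   mean sample surprisal over the word's replicate tokens. Words absent
   from a replicate drop out of that replicate's fit (their count is
   reported). With `predictor_source = "true"` the source values are used
   instead — the unobtainable-in-practice benchmark under which the
   informativity test must be calibrated at the nominal level.
3. **Simulate durations** (`simulate_durations()`):
   $\log d \sim N(\beta_0 + \beta_P\,\mathrm{pred}_{true} + u_w,\ \sigma)$.
   The mean always uses *true* predictability; the residual SD is the
   standard deviation of the calibration fit's residuals
   (`calibrate_generating_model()`, which regresses duration on
   predictability *alone* so that $\beta_P$ absorbs the full bivariate
   relationship, and, when requested, takes the fitted by-word random
   intercepts as the word effects — deterministic per word, not fresh
   draws).
4. **Fit and record.** The analysis model (a `model_spec()`) is fit by
   `lm()` or `lmerTest::lmer()`; every coefficient, SE and p-value is
   stored. Fits that error or trigger a convergence warning are excluded
   and counted; they never silently return estimates.

Diagnostics then reduce the replicate array: `false_alarm_rate()` (the
directional rate: two-sided $p < \alpha$ *and* the expected sign, nominal
$\alpha/2$), `spurious_effect_mean()` (over all converged replicates by
default; the significant-only variant is also reported since the two
coincide only when nearly every replicate is significant),
`mc_pvalue()` (exceedance fraction, reported as "< 1/n" at zero
exceedances; the $(k+1)/(n+1)$ estimator is available by flag), and
`direction_conditionals()` (co-occurrence of the spurious main effect with
the negative context-frequency interaction). `sweep_table()` crosses
generating slopes with analysis models.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `b_pred` | log-seconds per nat | calibrated from data (synthetic default −0.05) | the engine of the artifact: the spurious informativity effect is roughly proportional to it |
| `sigma_resid` | log-seconds | SD of calibration residuals (synthetic default 0.35) | sets the significance threshold the spurious effect must clear |
| `sigma_word` | log-seconds | 0.25 | word-level heterogeneity; about the share of duration variance a random intercept absorbs in conversational-speech fits |
| `alpha` | — | 0.05 | two-sided; directional false alarms are therefore benchmarked against 0.025 |
| `n_reps` | — | 1000 | Monte-Carlo resolution of rates and p-values (bound 1/n) |
| `log_base` | — | e (nats) | coefficients rescale linearly with base; signs and p-values are invariant |

Informativity is token-weighted (the expectation over the word's observed
contexts) rather than type-weighted; token weighting makes the
single-context identity exact — a word seen in only one context type has
informativity equal to minus its predictability — which the sample/true
distinction relies on. Probabilities are raw maximum-likelihood relative
frequencies: no smoothing, because smoothed estimates already blend in
across-context information and would contaminate the very effect being
measured. Predictors enter the regressions uncentered, and context
frequency enters interactions on its raw count scale.

## The synthetic corpus generator

`generate_corpus()` provides study conditions with known ground truth. Its
defaults — 2,000 tokens over 500 context types and 400 word types — are
the package's desk-scale testbed; the corresponding real datasets are
2–3 times larger.

- **Context marginal**: Zipf with exponent 1 (`P(rank) ∝ rank^{-1}`). At
  the default sizes roughly 40–55% of observed context types occur exactly
  once, matching the rank-frequency structure of conversational corpora.
- **Conditionals** (`conditional_family = "lognormal"`, the default):
  $q(w \mid c) \propto p_{global}(w)\, e^{\tau z_{w,c}}$ with $z$ i.i.d.
  standard normal and $\tau$ = `conditional_sharpness` (default 1 nat).
  This was a genuinely open design choice, and the deciding constraint is
  that the diagnostic's subject matter *requires* words to have stable
  average predictability: informativity can only soak up predictability
  signal if knowing the word tells you something about its probability in
  unseen contexts. The lognormal family keeps a word's log conditional
  probability within about $\tau$ of its global log probability in every
  context, which yields the strong predictability–informativity
  anti-correlation seen in real token samples (≈ −0.9 at the defaults)
  while still making predictability genuinely context-dependent. Two
  alternative families are kept for contrast: `"dirichlet"` (conditionals
  Dirichlet-centered on the global distribution; rare words get
  concentration parameters far below 1 and hence unrealistically unstable
  conditionals) and `"permutation"` (the same Zipf shape permuted
  independently per context; every word then has the *same* expected
  conditional probability, so true informativity is nearly constant across
  words — a useful no-signal control, and a demonstration that Zipfian
  marginals alone do not produce informativity artifacts).
- **Durations** are generated exactly as in the null simulator, from the
  latent probabilities, with `b_info = 0` by default.
- **Truth sidecar**: the latent conditional matrix, per-word true
  informativity and word effects are returned separately from the
  observable token table, and `truth_stats()` packages them as the
  simulation's ground truth with the *observed* context frequencies as
  trial counts. This mirrors the intended real-data situation, where the
  probability estimates attached to an analyzed sample come from a much
  larger corpus: in particular, a context observed once can still carry a
  conditional probability far from 0 or 1. Computing statistics from the
  analyzed table itself (`compute_bigram_stats()`) remains the right thing
  for real token tables, but understates noise in exactly the rarest
  contexts, since a singleton context's relative frequency is always 1.

What the generator does *not* emulate: lexical content, segmental or
prosodic structure, speaker variation, autocorrelation within
conversations, and any mismatch between corpus probabilities and speaker
experience. Passing tests on synthetic corpora therefore establish that
the machinery measures what it claims to measure under the stated
generative assumptions — not that any particular real effect is or is not
spurious.

## Numerical and procedural choices

- **Seeding.** Every replicate's RNG stream derives from
  `derive_seed(master_seed, index)`, an affine bijection modulo the prime
  $2^{31}-1$: deterministic, collision-free within an experiment, and
  bit-for-bit reproducible end to end.
- **Mixed models.** REML by default (ML by flag); p-values by
  Satterthwaite approximation via `lmerTest`, with a normal-approximation
  fallback recorded in `df_method` if the Satterthwaite computation fails.
  Marginal and conditional $R^2$ follow the variance-partition definition
  for Gaussian mixed models:
  $R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_w + \sigma^2_\varepsilon)$,
  $R^2_c = (\sigma^2_f + \sigma^2_w) / (\cdot)$, with $\sigma^2_f$ the
  variance of the fixed-effects predictor over the data.
- **Degenerate inputs.** Rank-deficient designs error naming the aliased
  term (informativity is *exactly* minus predictability when every word
  occurs in one context type, so this is reachable with real data);
  `partial_pool()` returns the local estimate at infinite local precision
  (`var_within = 0, n_cx > 0`, logged) and the global estimate at
  `n_cx = 0`; a random predictability slope is attempted only when some
  word has at least two observations; contexts with a single observed word
  type, where the within-context variance is undefined, fall back to the
  average within-context variance in `pool_predictability()`.
- **Convergence.** Replicates whose analysis fit fails are excluded from
  every rate, and the exclusion count is carried in the summary; an
  experiment errors only if *no* replicate converges. Conditional
  proportions with empty conditioning events return `NA`, never 0.
- **Problem sizes.** The shipped tests run the calibration experiment at
  1,000 replicates (binomial 99% band 3.3–6.9% around the nominal 5%) and
  the inflation/co-occurrence experiments at 250 replicates per generating
  slope, on the default 2,000-token corpus; parameter recovery uses a
  50,000-token corpus. These sizes put Monte-Carlo error comfortably below
  the effect sizes being asserted while keeping a full run in tens of
  seconds.

## Known limitations

- The diagnostic conditions on the observed context frequencies and on the
  bigram operationalization of context; it says nothing about wider
  context windows or contexts that should be pooled because they are
  similar.
- The spurious-effect magnitude scales with the measurement-noise level of
  the probability estimates. When statistics are computed from the
  analyzed table itself, singleton-context noise is invisible (see above),
  so rates obtained that way are conservative.
- `compare_nested()` and adjusted $R^2$ are defined for the OLS path;
  mixed fits are compared on marginal/conditional $R^2$ instead.
- The CLI is a thin wrapper for shell pipelines; programmatic use of the
  package functions is the primary interface.
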