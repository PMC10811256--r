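---
title: "Methods: predicting psychotherapy outcome and alliance in nested dyadic data"
author: "dyadpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting psychotherapy outcome and alliance in nested dyadic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadpred)
```

## The problem and the modelling strategy

`dyadpred` implements a data-driven framework for predicting psychotherapy
process and outcome from baseline characteristics in the classic nested
design of dyadic studies: clients nested in therapists, with short
longitudinal measurement series per client. The design it emulates has 23
therapists, two clients each, seven weekly sessions; symptom burden
(OQ-45 total) is measured pre-treatment, at sessions 1, 3, 5, 7 and
post-termination, and the working alliance (WAI) is rated by both client
and therapist at sessions 1, 3, 5 and 7.

Five client-level dependent variables are derived and then predicted from
baseline covariates only:

1. the client-specific slope of symptom change (treatment outcome),
2. and 3. the between-client alliance level (mean WAI across sessions), per
   rater,
4. and 5. the within-client alliance slope (conditional time slope), per
   rater.

Prediction models are two-level linear mixed models with a therapist
random intercept,

$$y_i = \mathbf{x}_i^\top\beta + u_{t(i)} + \varepsilon_i,
\qquad u_t \sim N(0, \tau_{00}),\ \varepsilon_i \sim N(0, \sigma^2),$$

whose fixed-effect terms are chosen by best-subset search over all linear
terms, quadratics of continuous predictors, and pairwise interactions, up
to nine terms per model. Candidates are ranked by AIC under maximum
likelihood, and a leave-one-client-out cross-validation (LOOCV) guard
discards candidates whose out-of-sample $R^2$ falls more than 0.10 below
the training marginal $R^2$ — the operational definition of overfitting
used here. Effect size is the Nakagawa–Schielzeth marginal $R^2$,
$\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \hat\tau_{00} +
\hat\sigma^2)$, with the population variance (denominator $n$) of the
fitted fixed-effect predictor.

## Two-stage target derivation

Stage 1 turns session series into client-level targets. Growth models
`y ~ time` with client-specific random intercepts and slopes are fitted by
maximum likelihood (backed by `lme4::lmer`), and each client's
*conditional* (shrunken) slope — fixed slope plus the client's conditional
mode — is the derived target, not the raw per-client OLS slope. Between
alliance targets are available-case means over the four alliance
sessions.

Three choices deserve comment:

* **Time coding.** The measurement index is the default metric (pre = 0
  … post = 5 for the outcome; sessions 1/3/5/7 coded 0..3 for alliance),
  since the sessions are equally spaced in measurement order; a week-based
  coding is available (`week_coding()`). Slopes transform exactly as a
  linear reparameterization (halving, for alliance index vs. weeks).
* **Uncorrelated random intercept/slope, centered time.** Stage-1 models
  use independent intercept/slope deviations with time centered at the
  fixed mean of the coding. Centering makes the independence assumption
  invariant to relabeling the time origin, so index- and week-coded fits
  are exactly rescaled versions of one another; and for balanced series it
  makes the conditional slope a coordinate-wise shrinkage of the client's
  OLS slope toward the fixed-effect slope — an interval property the test
  suite checks against a per-client OLS oracle.
* **Client-level stage 1.** The therapist level enters at stage 2 (the
  prediction models carry the therapist random intercept); stage-1 growth
  models are client-level only. This mirrors where the printed variance
  components ($\tau_{00}$ per therapist) live in the prediction models.
  Exactly noise-free series are handled by an explicit degenerate branch
  that returns the per-client OLS slopes, which are the analytic limit of
  the conditional slopes as residual noise vanishes.

Derived targets are Z-scored before stage 2 (the magnitudes of published
coefficients in this literature are consistent with standardized targets);
this is toggleable via `standardize_targets()`.

## The mixed-model engine

Stage-2 models are fitted by an in-package profile-likelihood engine
(C++): for a single grouping factor the covariance
$\sigma^2(I + \lambda ZZ^\top)$ with $\lambda = \tau_{00}/\sigma^2$ is
block diagonal, so GLS quantities reduce to per-group sums and one
likelihood evaluation costs $O(gp^2 + p^3)$ regardless of $n$. The profile
over $\log\lambda$ is maximized by golden-section search with an explicit
boundary check at $\tau_{00} = 0$; $\hat\beta$ and
$\hat\sigma^2 = \mathrm{RSS}_V/n$ (ML, not REML) follow in closed form.
ML is used throughout because AIC comparison across different fixed-effect
sets requires it; `AIC = -2\ell + 2k` with $k$ = number of fixed effects
(intercept included) + 2 variance components.

This is what makes the search feasible: a candidate fit costs tens of
microseconds, and a full LOOCV re-optimizes $\lambda$ from scratch in
every fold by downdating the precomputed cross-products (the "streaming"
path). A naive refit-per-client implementation is retained and tested
equal to the streaming path.

Inference is Wald-$t$ with residual degrees of freedom
$n - p_{\text{fixed}} - 1$. The degrees of freedom behind the published
tables this layout mirrors follow an unstated rule, so exact df
replication is out of scope; CIs are $\hat\beta \pm t_{0.975}\,SE$.
Residual diagnostics are a Shapiro–Wilk test on conditional residuals and
a studentized Breusch–Pagan-type score test (n·R² of squared residuals on
fitted values against $\chi^2_1$), with pass flags at $\alpha = 0.05$.

`lme4` — the reference tool for this model class — is used in the test
suite as an independent oracle for the engine (coefficients, likelihood,
variance components agree to ~1e-5), never as the engine itself.

## The search

The term universe over $L$ declared predictors ($Q$ continuous) has
$L + Q + \binom{L}{2}$ members; the full 16-predictor study universe has
146 terms. Exhaustive enumeration of all subsets of up to nine terms is
astronomically infeasible there ($\sim 10^{13}$ models), so the search is
exhaustive only when the implied count fits a budget (default $2 \times
10^6$) and otherwise uses a deterministic forward beam search (default
width 100), growing term sets one term at a time under AIC and applying
the LOOCV guard to the final candidate pool. The mode used is always
recorded in the result. LOOCV is computed for the `cv_pool_size` (default
50) best-AIC candidates; cross-validating every enumerated candidate is
configurable but rarely affordable.

Two readings of the "did not decrease by more than 10%" guard exist; the
implemented default is an **absolute** drop of 0.10 in $R^2$ units, because
the published model pairs this package mirrors (training/CV 0.613/0.528,
0.582/0.528, 0.506/0.438, 0.374/0.322, 0.301/0.241) all satisfy the
absolute rule (max drop 0.085) while several violate a 10%-relative rule.
Relative mode is available (`drop_mode = "relative"`).

Heredity defaults: interactions require both linear parents (every
published interaction row in the mirrored tables has both mains present);
quadratics do **not** require their linear parent (the tables contain a
squared term with no matching linear term). Both flags are configurable.
AIC ties break by fewer terms, then canonical term order, for
reproducibility. When no candidate passes the guard, the best-CV-$R^2$
candidate is selected and an explicit fallback note recorded — at $n = 46$
clients this is common, because nine-term models genuinely overfit there.

## Preprocessing

Continuous predictors are Z-scored (sample sd); binary predictors are
coded $-0.5/+0.5$; missing client income is imputed by k-nearest
neighbours (default $k = 5$, a common default that is robust at $n
\approx 46$; the study this emulates imputed four missing income values).
Distances are Euclidean over the variables observed in both rows,
rescaled by the fraction observed — the standard KNN-imputation
convention. Single imputation understates standard errors; multiple
imputation is a stated non-goal. In cross-validation, fold-wise
re-standardization is available (`refit_scaling = TRUE`) to avoid
information leakage through whole-sample scaling statistics.

## The synthetic world

`synthetic_config()` states the world once: 23 therapists × 2 clients,
covariates generated on an already-standardized scale (continuous
N(0, 1); binary levels with the study's reported compositions — 15/23
female therapists, 11/23 trained, 45.3% male clients), client latent
outcome slopes built as intercept + true-term effects + therapist effect
+ client deviation, and session series from client intercept/slope plus
noise. Defaults: mean outcome slope −0.2 per measurement index (modest
symptom reduction), therapist sd 0.15 and client sd 0.3 around it, session
noise sd 0.4, modest true effects of baseline symptom burden and
orientation; alliance trajectories with mean slope 0.15, client slope sd
0.25, and therapist-level variance larger for therapist-rated than
client-rated alliance (0.6 vs 0.4), consistent with the much larger
therapist share of variance in therapist-rated alliance reported in this
literature. Income missingness is MCAR at rate 0.087 (≈ 4 cells among 46).
These are stated-world choices, not tuning knobs.

What the generator does *not* emulate: dropout and informative
missingness, item-level instrument behaviour, rater drift, and
non-Gaussian covariate distributions. A green test therefore establishes
algorithmic correctness and calibration under the stated world, not
empirical validity on any real sample.

## Known limitations and one documented red criterion

The acceptance suite includes a model-recovery criterion requiring the
search to recover *exactly* the true three-term set in ≥ 80% of 50
replicates (effects 0.5, $\sigma^2 = 0.5$, 200 clients). This assertion is
left failing, deliberately: AIC admits a spurious term whenever it
improves deviance by more than 2, which happens with probability
$P(\chi^2_1 > 2) \approx 0.157$ per noise term. With five noise terms in
the minimal universe containing the truth, the exact-recovery probability
is structurally $\approx 0.84^5 \approx 0.44$ (measured: 0.52), for *any*
correct implementation of the stated selection rule; the LOOCV guard does
not change this at $n = 200$ because mild overfits generalize almost as
well as the truth. What the search does achieve, and the suite verifies,
is that all three true terms are recovered in 100% of replicates and that
on pure-noise outcomes the selected model's CV $R^2$ stays ≤ 0.05 in over
90% of replicates. A selection rule targeting exact support recovery
would need a BIC-type penalty, which the mirrored methodology does not
use.

Other limitations: inference df are approximate (no Satterthwaite /
Kenward–Roger); the LOOCV estimate itself is optimistic as a
generalization estimate (no nested CV); crossed random effects and
non-Gaussian outcomes are out of scope.
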