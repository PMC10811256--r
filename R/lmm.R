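#' Fit a two-level linear mixed model by maximum likelihood
#'
#' Fits `y = X beta + Z u + e` with a single random intercept on the
#' grouping factor (`u ~ N(0, tau00 I)`, `e ~ N(0, sigma2 I)`) by profiling
#' the Gaussian likelihood over `lambda = tau00 / sigma2` (golden-section
#' search on the log scale with an explicit boundary check at
#' `tau00 = 0`). Estimation is always ML, not REML, so that AIC comparisons
#' across models with different fixed effects are valid.
#'
#' Inference is Wald-t with residual degrees of freedom
#' `df = n_obs - n_fixed - 1`; 95% CIs are `estimate +/- t(df, 0.975) * SE`.
#'
#' @param design a design as returned by [build_design()].
#' @return An object of class `lmm_fit` with the coefficient table
#'   (`coefficients`), variance components `sigma2` and `tau00`, `icc`,
#'   `loglik`, `aic` (with `k = n_fixed + 2` parameters), Nakagawa-Schielzeth
#'   marginal R-squared `r2_marginal`, conditional group intercepts `blup`,
#'   fitted values and conditional residuals.
#' @export
fit_lmm <- function(design) {
  X <- design$X; y <- design$y; grp <- design$group
  n <- length(y); p <- ncol(X)
  if (n <= p + 2)
    stop(sprintf("too few observations (%d) for %d fixed effects", n, p),
         call. = FALSE)
  if (nlevels(droplevels(grp)) < 2)
    stop("need at least 2 groups", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  grp <- droplevels(grp)
  fit <- lmm_profile_fit_cpp(X, y, as.integer(grp) - 1L, nlevels(grp))
  if (!isTRUE(fit$converged))
    stop("mixed-model fit did not converge (non-finite profile likelihood)",
         call. = FALSE)
  beta <- drop(fit$beta)
  se <- sqrt(pmax(diag(fit$cov), 0))
  df <- n - p - 1
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  crit <- qt(0.975, df)
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      ci_lower = beta - crit * se, ci_upper = beta + crit * se,
                      df = df, statistic = tstat, p_value = pval,
                      row.names = NULL, stringsAsFactors = FALSE)
  eta <- drop(X %*% beta)                     # fixed-effect linear predictor
  var_f <- mean((eta - mean(eta))^2)          # population variance, denom n
  sigma2 <- fit$sigma2; tau00 <- fit$tau00
  blup <- setNames(drop(fit$blup), levels(grp))
  fitted_cond <- eta + blup[as.character(grp)]
  structure(list(coefficients = coefs,
                 sigma2 = sigma2, tau00 = tau00,
                 icc = tau00 / (tau00 + sigma2),
                 lambda = fit$lambda,
                 loglik = fit$loglik,
                 aic = -2 * fit$loglik + 2 * (p + 2),
                 r2_marginal = var_f / (var_f + tau00 + sigma2),
                 var_fixed = var_f,
                 beta = setNames(beta, colnames(X)),
                 cov_beta = fit$cov,
                 blup = blup,
                 converged = TRUE,
                 n_obs = n, n_groups = nlevels(grp),
                 estimation = "ML",
                 spec = design$spec,
                 group_labels = as.character(grp),
                 fitted_fixed = eta,
                 fitted = unname(fitted_cond),
                 residuals = unname(y - fitted_cond),
                 y = y, X = X),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-level LMM (ML): %s, n = %d clients, %d therapists\n",
              x$spec$outcome, x$n_obs, x$n_groups))
  print(cbind(round(x$coefficients[, c("estimate", "se", "ci_lower",
                                       "ci_upper", "statistic")], digits),
              p = round(x$coefficients$p_value, 3)))
  cat(sprintf("sigma2 = %.*f  tau00 = %.*f  ICC = %.*f\n",
              digits, x$sigma2, digits, x$tau00, digits, x$icc))
  cat(sprintf("logLik = %.*f  AIC = %.*f  marginal R2 = %.*f\n",
              digits, x$loglik, digits, x$aic, digits, x$r2_marginal))
  invisible(x)
}

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2,
            nobs = object$n_obs, class = "logLik")
}

#' Akaike Information Criterion of an ML mixed-model fit
#'
#' `AIC = -2 logLik + 2 k` with `k` = number of fixed effects (including
#' the intercept) + 2 variance components (`tau00`, `sigma2`). Fits are
#' ML by construction; a REML fit would be rejected.
#'
#' @param fit an `lmm_fit`.
#' @return numeric AIC value.
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!identical(fit$estimation, "ML"))
    stop("AIC comparison requires ML estimation, not REML", call. = FALSE)
  fit$aic
}

#' Nakagawa-Schielzeth marginal R-squared
#'
#' `R2m = var_f / (var_f + tau00 + sigma2)` where `var_f` is the population
#' variance (denominator n) of the fitted fixed-effect linear predictor over
#' the estimation sample: the share of total variance attributable to the
#' fixed effects alone.
#'
#' @param fit an `lmm_fit`.
#' @return numeric in \[0, 1\].
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$var_fixed / (fit$var_fixed + fit$tau00 + fit$sigma2)
}

#' Intraclass correlation
#'
#' Share of residual-level variance attributable to the therapist level:
#' `ICC = tau00 / (tau00 + sigma2)`.
#'
#' @param fit an `lmm_fit`.
#' @return numeric in \[0, 1).
#' @export
icc <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  icc_from_components(fit$tau00, fit$sigma2)
}

#' @rdname icc
#' @param tau00 therapist-intercept variance.
#' @param sigma2 residual variance.
#' @export
icc_from_components <- function(tau00, sigma2) {
  stopifnot(tau00 >= 0, sigma2 > 0)
  tau00 / (tau00 + sigma2)
}

#' Predict from a fitted two-level model
#'
#' @param object an `lmm_fit`.
#' @param newdata data.frame carrying all term variables (and the grouping
#'   column for `type = "conditional"`).
#' @param type `"fixed"` returns `X beta`; `"conditional"` adds the
#'   estimated conditional therapist intercept for therapists present in
#'   the fit and falls back to the fixed-only prediction (with a note) for
#'   unknown therapists.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lmm_fit <- function(object, newdata, type = c("fixed", "conditional"),
                            ...) {
  type <- match.arg(type)
  spec <- object$spec
  cols <- lapply(spec$terms, function(t) term_column(newdata, t))
  X <- cbind(rep(1, nrow(newdata)), if (length(cols)) do.call(cbind, cols))
  pred <- drop(X %*% object$beta)
  if (type == "conditional") {
    if (!spec$group %in% names(newdata))
      stop(sprintf("conditional prediction needs column '%s'", spec$group),
           call. = FALSE)
    g <- as.character(newdata[[spec$group]])
    u <- object$blup[g]
    if (anyNA(u)) {
      message(sprintf("%d row(s) with unknown therapist: using fixed-only prediction",
                      sum(is.na(u))))
      u[is.na(u)] <- 0
    }
    pred <- pred + unname(u)
  }
  pred
}

#' Residual diagnostics for a fitted model
#'
#' Shapiro-Wilk normality test on the conditional residuals and a
#' studentized Breusch-Pagan-type score test for heteroscedasticity
#' (`LM = n * R^2` from regressing squared residuals on fitted values,
#' compared to chi-squared with 1 df).
#'
#' @param fit an `lmm_fit`.
#' @param alpha significance level for the pass flags (default 0.05).
#' @return A `diagnostics_report` with statistics, p-values and pass flags.
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lmm_fit"))
  r <- fit$residuals
  if (sd(r) < 1e-12)
    stop("degenerate input: residuals are constant", call. = FALSE)
  if (length(r) < 8)
    stop("normality test refused: fewer than 8 residuals", call. = FALSE)
  sw <- shapiro.test(r)
  aux <- lm(I(r^2) ~ fit$fitted)
  lm_stat <- length(r) * summary(aux)$r.squared
  lm_p <- pchisq(lm_stat, df = 1, lower.tail = FALSE)
  structure(list(normality_statistic = unname(sw$statistic),
                 normality_p = sw$p.value,
                 heteroscedasticity_statistic = lm_stat,
                 heteroscedasticity_p = lm_p,
                 normality_pass = sw$p.value >= alpha,
                 heteroscedasticity_pass = lm_p >= alpha,
                 alpha = alpha),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("Residual diagnostics (alpha = %.2f)\n", x$alpha))
  cat(sprintf("  Normality (Shapiro-Wilk): W = %.4f, p = %.3f  [%s]\n",
              x$normality_statistic, x$normality_p,
              if (x$normality_pass) "met" else "violated"))
  cat(sprintf("  Heteroscedasticity (score): LM = %.4f, p = %.3f  [%s]\n",
              x$heteroscedasticity_statistic, x$heteroscedasticity_p,
              if (x$heteroscedasticity_pass) "met" else "violated"))
  invisible(x)
}
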