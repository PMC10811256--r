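#' Assemble a model report bundle
#'
#' Collects everything the study-style coefficient tables print —
#' predictor rows (estimate, CI, df, t statistic, p), the random-effects
#' block (sigma2, tau00, ICC), the training/CV R-squared pair — plus the
#' residual diagnostics and search metadata. All values are stored
#' unrounded; rounding happens only at render time (estimates 2 dp,
#' p-values 3 dp, R-squared 3 dp).
#'
#' @param fit an [fit_lmm()] result.
#' @param cv optional [loocv_r2()] result for the same model.
#' @param diagnostics optional [residual_diagnostics()] report.
#' @param meta optional list of search metadata (mode, seed, thresholds).
#' @return An object of class `report_bundle`.
#' @export
render_model_report <- function(fit, cv = NULL, diagnostics = NULL,
                                meta = list()) {
  stopifnot(inherits(fit, "lmm_fit"))
  tab <- fit$coefficients
  tab$label <- gsub(":", " × ", tab$term)
  structure(list(outcome = fit$spec$outcome,
                 table = tab,
                 random_effects = list(sigma2 = fit$sigma2,
                                       tau00 = fit$tau00, icc = fit$icc),
                 r2 = list(train = fit$r2_marginal,
                           cv = if (!is.null(cv)) cv$r2_cv else NA_real_),
                 aic = fit$aic, loglik = fit$loglik,
                 n_obs = fit$n_obs, n_groups = fit$n_groups,
                 diagnostics = if (!is.null(diagnostics))
                   unclass(diagnostics) else NULL,
                 meta = meta),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render a report bundle as text in the study-table layout
#'
#' @param x a `report_bundle`.
#' @return character vector of lines.
#' @export
format_report <- function(x) {
  stopifnot(inherits(x, "report_bundle"))
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  rows <- sprintf("%-55s %6.2f  %6.2f to %5.2f  %3d  %6.2f  %s",
                  x$table$label, x$table$estimate, x$table$ci_lower,
                  x$table$ci_upper, x$table$df, x$table$statistic,
                  fmt_p(x$table$p_value))
  out <- c(sprintf("Outcome: %s (n = %d clients, %d therapists)",
                   x$outcome, x$n_obs, x$n_groups),
           sprintf("%-55s %6s  %15s  %3s  %6s  %s",
                   "Predictors", "Estimates", "CI", "df", "Statistic", "p"),
           rows,
           "Random effects",
           sprintf("  sigma^2     %.2f", x$random_effects$sigma2),
           sprintf("  tau00 tid   %.2f", x$random_effects$tau00),
           sprintf("  ICC         %.2f", x$random_effects$icc),
           sprintf("Marginal training/CV R^2  %.3f/%.3f",
                   x$r2$train, x$r2$cv))
  if (!is.null(x$diagnostics))
    out <- c(out, sprintf(
      "Residuals: normality p = %.3f [%s], heteroscedasticity p = %.3f [%s]",
      x$diagnostics$normality_p,
      if (x$diagnostics$normality_pass) "met" else "violated",
      x$diagnostics$heteroscedasticity_p,
      if (x$diagnostics$heteroscedasticity_pass) "met" else "violated"))
  out
}

#' Serialize / restore a report bundle (full precision)
#'
#' @param x a `report_bundle`.
#' @param path JSON file path.
#' @return `report_from_json` returns the restored `report_bundle`.
#' @export
report_to_json <- function(x, path) {
  stopifnot(inherits(x, "report_bundle"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$table <- as.data.frame(x$table, stringsAsFactors = FALSE)
  structure(x, class = "report_bundle")
}

#' Numeric effect grid for a fitted term
#'
#' Evaluates the fixed-effect polynomial over a grid with all other
#' covariates held at 0 (the standardized mean): quadratic terms get 41
#' points over +/- 2 SD of the focal variable; interactions get a 21-point
#' focal grid crossed with two moderator levels (+/- 1 SD for continuous
#' moderators, the +/- 0.5 codes for binary ones); linear terms get a
#' 2-point line. This numeric grid is the canonical plotting artifact.
#'
#' @param fit an `lmm_fit` containing the term.
#' @param term a [model_term()] present in the fit.
#' @param moderator for interactions: which of the two variables acts as
#'   moderator (default: the second in canonical order).
#' @param moderator_values the two moderator levels (default `c(-1, 1)`;
#'   use `c(-0.5, 0.5)` for binary moderators).
#' @return An `effect_grid`: data.frame with the focal value, moderator
#'   value (interactions only) and the fixed-effect prediction.
#' @export
effect_grid <- function(fit, term, moderator = NULL,
                        moderator_values = c(-1, 1)) {
  stopifnot(inherits(fit, "lmm_fit"), inherits(term, "model_term"))
  labels <- vapply(fit$spec$terms, term_label, "")
  if (!term_label(term) %in% labels)
    stop(sprintf("term '%s' is not in the fitted model", term_label(term)),
         call. = FALSE)
  vars <- unique(unlist(lapply(fit$spec$terms, `[[`, "vars")))
  base_row <- as.data.frame(setNames(as.list(rep(0, length(vars))), vars))
  if (term$kind == "interaction") {
    if (is.null(moderator)) moderator <- term$vars[2]
    stopifnot(moderator %in% term$vars)
    focal <- setdiff(term$vars, moderator)
    grid <- expand.grid(focal = seq(-2, 2, length.out = 21),
                        moderator = moderator_values)
    newdata <- base_row[rep(1, nrow(grid)), , drop = FALSE]
    newdata[[focal]] <- grid$focal
    newdata[[moderator]] <- grid$moderator
    pred <- predict(fit, newdata, type = "fixed")
    out <- data.frame(grid, predicted = pred)
    names(out)[1:2] <- c(focal, moderator)
  } else {
    npts <- if (term$kind == "quadratic") 41 else 2
    xs <- seq(-2, 2, length.out = npts)
    newdata <- base_row[rep(1, npts), , drop = FALSE]
    newdata[[term$vars]] <- xs
    pred <- predict(fit, newdata, type = "fixed")
    out <- data.frame(x = xs, predicted = pred)
    names(out)[1] <- term$vars
  }
  structure(out, term = term, class = c("effect_grid", "data.frame"))
}
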