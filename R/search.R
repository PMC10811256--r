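#' Build the candidate term universe
#'
#' All admissible fixed-effect terms over a declared predictor set: every
#' linear term, a quadratic for every continuous predictor, and every
#' unordered pairwise interaction, minus explicit exclusions. With `L`
#' predictors of which `Q` are continuous and no exclusions the universe
#' has `L + Q + choose(L, 2)` terms, in canonical order (linears
#' alphabetically, then quadratics, then sorted interaction pairs).
#'
#' @param predictors data.frame with columns `name`, `type`
#'   (`"continuous"`/`"binary"`) and optionally `level`
#'   (`"client"`/`"therapist"`, informational).
#' @param exclusions optional character vector of term labels (as produced
#'   by [term_label()], e.g. `"x^2"`, `"a:b"`) to drop.
#' @return An object of class `term_universe`.
#' @export
build_universe <- function(predictors, exclusions = NULL) {
  stopifnot(is.data.frame(predictors),
            all(c("name", "type") %in% names(predictors)))
  if (anyDuplicated(predictors$name))
    stop("duplicate predictor names", call. = FALSE)
  terms <- lapply(sort(predictors$name), function(v) model_term("linear", v))
  cont <- sort(predictors$name[predictors$type == "continuous"])
  terms <- c(terms, lapply(cont, function(v) model_term("quadratic", v)))
  if (nrow(predictors) >= 2) {
    prs <- combn(sort(predictors$name), 2, simplify = FALSE)
    terms <- c(terms, lapply(prs, function(p) model_term("interaction", p)))
  }
  labels <- vapply(terms, term_label, "")
  if (length(exclusions)) {
    unknown <- setdiff(exclusions, labels)
    if (length(unknown))
      stop(sprintf("exclusion(s) not in universe: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    keep <- !(labels %in% exclusions)
    terms <- terms[keep]; labels <- labels[keep]
  }
  structure(list(terms = terms, labels = labels, predictors = predictors),
            class = "term_universe")
}

#' @export
print.term_universe <- function(x, ...) {
  kinds <- vapply(x$terms, `[[`, "", "kind")
  cat(sprintf("<term_universe> %d terms (%d linear, %d quadratic, %d interaction)\n",
              length(x$terms), sum(kinds == "linear"),
              sum(kinds == "quadratic"), sum(kinds == "interaction")))
  invisible(x)
}

# heredity check for a candidate term set (indices into universe)
satisfies_heredity <- function(universe, idx, interactions = TRUE,
                               quadratics = FALSE) {
  if (!length(idx)) return(TRUE)
  terms <- universe$terms[idx]
  linear_vars <- unlist(lapply(terms, function(t)
    if (t$kind == "linear") t$vars))
  for (t in terms) {
    if (interactions && t$kind == "interaction" &&
        !all(t$vars %in% linear_vars)) return(FALSE)
    if (quadratics && t$kind == "quadratic" &&
        !(t$vars %in% linear_vars)) return(FALSE)
  }
  TRUE
}

#' Enumerate candidate models up to the term cap
#'
#' Yields every subset of the universe with at most `max_terms` terms that
#' satisfies the heredity constraints (when enabled, an interaction
#' requires both linear parents; a quadratic may optionally require its
#' linear parent). The intercept-only model (empty set) is always
#' included. Refuses to start when the implied unconstrained count
#' `sum(choose(T, 0..max_terms))` exceeds `budget` — callers should switch
#' to the beam search in [select_model()].
#'
#' @param universe a [build_universe()] result.
#' @param max_terms subset size cap (default 9).
#' @param budget maximum number of candidates to enumerate (default 2e6).
#' @param heredity_interactions,heredity_quadratics heredity flags.
#' @return list of integer vectors (term indices into the universe), in
#'   deterministic order.
#' @export
enumerate_models <- function(universe, max_terms = 9, budget = 2e6,
                             heredity_interactions = TRUE,
                             heredity_quadratics = FALSE) {
  stopifnot(inherits(universe, "term_universe"), max_terms >= 0)
  tn <- length(universe$terms)
  sizes <- 0:min(max_terms, tn)
  implied <- sum(choose(tn, sizes))
  if (implied > budget)
    stop(sprintf("enumeration of %.0f candidate models exceeds the budget of %.0f; use the beam search",
                 implied, budget), call. = FALSE)
  out <- list(integer(0))
  for (k in sizes[sizes > 0]) {
    sets <- combn(tn, k, simplify = FALSE)
    keep <- vapply(sets, satisfies_heredity, TRUE, universe = universe,
                   interactions = heredity_interactions,
                   quadratics = heredity_quadratics)
    out <- c(out, sets[keep])
  }
  out
}

# internal: full-universe design used by the batch scorer; columns after the
# intercept are in universe order, so term-index sets map to column indices.
universe_design <- function(data, universe, outcome, group) {
  spec <- model_spec(outcome, universe$terms, group = group,
                     max_terms = length(universe$terms))
  d <- build_design(data, spec)
  grp <- droplevels(d$group)
  list(X = d$X, y = d$y, grp = as.integer(grp) - 1L, ngrp = nlevels(grp),
       group = grp)
}

# batch-score candidate term-index sets (AIC, training marginal R2)
score_sets <- function(ud, sets) {
  sc <- lmm_score_batch_cpp(ud$X, ud$y, ud$grp, ud$ngrp,
                            lapply(sets, function(i) as.integer(i) - 1L))
  data.frame(aic = ifelse(sc[, "converged"] > 0, sc[, "aic"], NA_real_),
             r2_train = ifelse(sc[, "converged"] > 0, sc[, "r2"], NA_real_),
             converged = sc[, "converged"] > 0)
}

#' Leave-one-client-out cross-validated R-squared
#'
#' For each client, refits the model on the remaining clients and
#' predicts the held-out client; returns
#' `r2_cv = 1 - sum((y - yhat_cv)^2) / sum((y - mean(y))^2)` with the
#' full-sample mean in the denominator (may be negative).
#'
#' @param data one-row-per-client analysis table.
#' @param spec a [model_spec()].
#' @param method `"streaming"` (cross-product downdating, the fast path)
#'   or `"naive"` (an independent refit-per-client implementation kept as
#'   an oracle; also required when `refit_scaling = TRUE`).
#' @param predict_mode `"fixed"` (default: fixed effects only) or
#'   `"conditional"` (adds the held-out client's therapist conditional
#'   intercept when that therapist keeps other clients in the fold).
#' @param refit_scaling when TRUE, re-standardizes the outcome and all
#'   continuous term variables within each training fold and applies the
#'   fold statistics to the held-out client (guards against information
#'   leakage through whole-sample scaling).
#' @return list with `r2_cv`, `press`, and the per-client predictions.
#' @export
loocv_r2 <- function(data, spec, method = c("streaming", "naive"),
                     predict_mode = c("fixed", "conditional"),
                     refit_scaling = FALSE) {
  method <- match.arg(method)
  predict_mode <- match.arg(predict_mode)
  if (refit_scaling) method <- "naive"
  n <- nrow(data)
  y <- as.numeric(data[[spec$outcome]])
  if (method == "streaming") {
    design <- build_design(data, spec)
    grp <- droplevels(design$group)
    yhat <- drop(lmm_loocv_cpp(design$X, design$y, as.integer(grp) - 1L,
                               nlevels(grp), predict_mode == "conditional"))
  } else {
    term_vars <- unique(unlist(lapply(spec$terms, `[[`, "vars")))
    cont_vars <- term_vars[vapply(term_vars, function(v)
      length(unique(data[[v]])) > 2, TRUE)]
    yhat <- numeric(n)
    for (i in seq_len(n)) {
      train <- data[-i, , drop = FALSE]
      test <- data[i, , drop = FALSE]
      if (refit_scaling) {
        for (v in c(spec$outcome, cont_vars)) {
          m <- mean(train[[v]]); s <- sd(train[[v]])
          if (s <= 0) stop(sprintf("degenerate variable '%s' in fold %d", v, i),
                           call. = FALSE)
          train[[v]] <- (train[[v]] - m) / s
          test[[v]] <- (test[[v]] - m) / s
        }
      }
      fit <- tryCatch(fit_lmm(build_design(train, spec)),
                      error = function(e) NULL)
      if (is.null(fit)) { yhat[i] <- NA_real_; next }
      pred <- predict(fit, test,
                      type = if (predict_mode == "conditional")
                        "conditional" else "fixed")
      if (refit_scaling) {
        m <- mean(data[-i, spec$outcome]); s <- sd(data[-i, spec$outcome])
        pred <- pred * s + m
      }
      yhat[i] <- pred
    }
  }
  if (anyNA(yhat))   # some fold failed: candidate marked not converged
    return(list(r2_cv = NA_real_, press = NA_real_, predictions = yhat,
                converged = FALSE))
  press <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  list(r2_cv = 1 - press / tss, press = press, predictions = yhat,
       converged = TRUE)
}

#' Best-subset model search with AIC and a LOOCV overfitting guard
#'
#' Scores candidate models by AIC (ML) on the full sample, computes the
#' leave-one-client-out CV R-squared for the `cv_pool_size` best-AIC
#' converged candidates, and selects the minimal-AIC candidate whose
#' training-vs-CV R-squared drop does not exceed `drop_threshold`
#' (absolute drop in R-squared units by default; a relative mode is
#' available). If no candidate passes the guard, the candidate with the
#' best CV R-squared is selected and an explicit fallback note recorded.
#'
#' Candidates are enumerated exhaustively when the implied count fits the
#' budget; otherwise a deterministic forward beam search (grown one term
#' at a time, scored by AIC) explores the space and the guard is applied
#' to the final pool. The mode used is always recorded.
#'
#' @param data one-row-per-client analysis table (targets derived and
#'   standardized, predictors preprocessed).
#' @param universe a [build_universe()] result.
#' @param outcome dependent-variable column in `data`.
#' @param group grouping column (default `"therapist_id"`).
#' @param max_terms term cap (default 9).
#' @param drop_threshold LOOCV guard threshold (default 0.10).
#' @param drop_mode `"absolute"` (default) or `"relative"`.
#' @param cv_pool_size number of best-AIC candidates to cross-validate
#'   (default 50); `Inf` cross-validates all.
#' @param budget exhaustive-enumeration cap (default 2e6).
#' @param heredity_interactions,heredity_quadratics heredity flags
#'   (defaults: interactions require both parents; quadratics free).
#' @param beam_width beam width for the stepwise fallback (default 100).
#' @param predict_mode CV prediction mode, see [loocv_r2()].
#' @param seed recorded in the result (the search itself is
#'   deterministic).
#' @return An object of class `search_result`: `ledger` (all scored
#'   candidates), `selected` ([model_spec()]), `fit` (the selected model
#'   refitted on the full sample), `cv` (its LOOCV score),
#'   `selection_note`, `search_mode`, `seed`.
#' @export
select_model <- function(data, universe, outcome, group = "therapist_id",
                         max_terms = 9, drop_threshold = 0.10,
                         drop_mode = c("absolute", "relative"),
                         cv_pool_size = 50, budget = 2e6,
                         heredity_interactions = TRUE,
                         heredity_quadratics = FALSE,
                         beam_width = 100,
                         predict_mode = c("fixed", "conditional"),
                         seed = NULL) {
  drop_mode <- match.arg(drop_mode)
  predict_mode <- match.arg(predict_mode)
  stopifnot(inherits(universe, "term_universe"))
  if (!length(universe$terms)) stop("empty term universe", call. = FALSE)
  tn <- length(universe$terms)
  implied <- sum(choose(tn, 0:min(max_terms, tn)))
  exhaustive <- implied <= budget

  ud <- universe_design(data, universe, outcome, group)
  if (exhaustive) {
    sets <- enumerate_models(universe, max_terms, budget,
                             heredity_interactions, heredity_quadratics)
    search_mode <- "exhaustive"
  } else {
    sets <- beam_enumerate(ud, universe, max_terms, beam_width,
                           heredity_interactions, heredity_quadratics)
    search_mode <- sprintf("beam(width=%d)", beam_width)
  }

  scores <- score_sets(ud, sets)
  labels <- vapply(sets, function(idx)
    if (length(idx)) paste(universe$labels[idx], collapse = " + ") else "1", "")
  ledger <- data.frame(model = labels,
                       n_terms = lengths(sets),
                       aic = scores$aic,
                       r2_train = scores$r2_train,
                       r2_cv = NA_real_,
                       converged = scores$converged,
                       admissible = NA,
                       stringsAsFactors = FALSE)
  if (!any(ledger$converged))
    stop("all candidate models failed to converge", call. = FALSE)

  # deterministic AIC ranking: ties broken by fewer terms, then label
  ord <- order(ledger$aic, ledger$n_terms, ledger$model, na.last = TRUE)
  pool <- ord[ledger$converged[ord]]
  pool <- pool[seq_len(min(length(pool), cv_pool_size))]
  for (j in pool) {
    spec_j <- model_spec(outcome, universe$terms[sets[[j]]], group = group,
                         max_terms = tn)
    ledger$r2_cv[j] <- loocv_r2(data, spec_j, method = "streaming",
                                predict_mode = predict_mode)$r2_cv
  }
  rule <- apply_selection_rule(ledger, pool, drop_threshold, drop_mode)
  ledger$admissible <- rule$admissible
  sel <- rule$selected
  note <- rule$note
  sel_spec <- model_spec(outcome, universe$terms[sets[[sel]]], group = group,
                         max_terms = tn)
  fit <- fit_lmm(build_design(data, sel_spec))
  cv <- loocv_r2(data, sel_spec, method = "streaming",
                 predict_mode = predict_mode)
  structure(list(ledger = ledger, sets = sets, selected = sel_spec,
                 selected_index = sel, fit = fit, cv = cv,
                 selection_note = note, search_mode = search_mode,
                 drop_threshold = drop_threshold, drop_mode = drop_mode,
                 seed = seed),
            class = "search_result")
}

# The selection rule applied to a scored ledger: a candidate is admissible
# when converged, cross-validated, and its training-vs-CV R2 drop is within
# the threshold (absolute drop in R2 units, or relative to the training R2).
# The selected model is the first admissible candidate in AIC order, else
# the best-CV-R2 candidate with an explicit fallback note.
apply_selection_rule <- function(ledger, pool, drop_threshold,
                                 drop_mode = c("absolute", "relative")) {
  drop_mode <- match.arg(drop_mode)
  drop <- if (drop_mode == "absolute") ledger$r2_train - ledger$r2_cv
          else (ledger$r2_train - ledger$r2_cv) / pmax(ledger$r2_train, 1e-12)
  admissible <- ledger$converged & !is.na(ledger$r2_cv) &
    drop <= drop_threshold
  if (any(admissible[pool], na.rm = TRUE)) {
    sel <- pool[which(admissible[pool])[1]]  # pool is AIC-ordered
    note <- sprintf("minimal-AIC candidate passing the %s LOOCV drop rule (threshold %.3g)",
                    drop_mode, drop_threshold)
  } else {
    sel <- pool[which.max(ledger$r2_cv[pool])]
    note <- sprintf("fallback: no candidate passed the %s drop rule (threshold %.3g); selected the best CV R2 candidate",
                    drop_mode, drop_threshold)
  }
  list(admissible = admissible, selected = sel, note = note)
}

# deterministic forward beam search over term sets, scored by AIC; each
# level's candidates are batch-scored in one C++ call
beam_enumerate <- function(ud, universe, max_terms, beam_width,
                           heredity_interactions, heredity_quadratics) {
  seen <- new.env(parent = emptyenv())
  key <- function(idx) paste0("k", paste(idx, collapse = ","))
  visited <- list(integer(0))
  assign(key(integer(0)), TRUE, envir = seen)
  frontier <- list(integer(0))
  tn <- length(universe$terms)
  for (step in seq_len(max_terms)) {
    cand <- list()
    for (s in frontier) {
      for (t in setdiff(seq_len(tn), s)) {
        idx <- sort(c(s, t))
        k <- key(idx)
        if (exists(k, envir = seen, inherits = FALSE)) next
        if (!satisfies_heredity(universe, idx, heredity_interactions,
                                heredity_quadratics)) next
        assign(k, TRUE, envir = seen)
        cand[[length(cand) + 1]] <- idx
      }
    }
    if (!length(cand)) break
    visited <- c(visited, cand)
    cand_aic <- score_sets(ud, cand)$aic
    ok <- is.finite(cand_aic)
    if (!any(ok)) break
    ordc <- order(cand_aic)[seq_len(min(beam_width, sum(ok)))]
    frontier <- cand[ordc]
  }
  visited
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %s over %d candidates (%s)\n",
              x$selected$outcome, nrow(x$ledger), x$search_mode))
  cat("selected:", format(x$selected$outcome), "~",
      if (length(x$selected$terms))
        paste(vapply(x$selected$terms, term_label, ""), collapse = " + ")
      else "1", "\n")
  cat(sprintf("AIC = %.2f  training R2 = %.3f  CV R2 = %.3f\n",
              x$fit$aic, x$fit$r2_marginal, x$cv$r2_cv))
  cat(x$selection_note, "\n")
  invisible(x)
}
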