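#' Fixed-effect model terms
#'
#' A `model_term` is a linear, quadratic or pairwise-interaction fixed
#' effect over named predictors. The intercept is implicit in every model
#' and is never represented as a term.
#'
#' @param kind one of `"linear"`, `"quadratic"`, `"interaction"`.
#' @param vars one variable name (linear/quadratic) or two distinct names
#'   (interaction; order is irrelevant and is canonicalized by sorting).
#' @return An object of class `model_term`.
#' @export
model_term <- function(kind = c("linear", "quadratic", "interaction"), vars) {
  kind <- match.arg(kind)
  vars <- as.character(vars)
  if (kind == "interaction") {
    if (length(vars) != 2 || vars[1] == vars[2])
      stop("interaction terms need two distinct variables", call. = FALSE)
    vars <- sort(vars)
  } else if (length(vars) != 1) {
    stop(sprintf("%s terms take exactly one variable", kind), call. = FALSE)
  }
  structure(list(kind = kind, vars = vars), class = "model_term")
}

#' @export
format.model_term <- function(x, ...) term_label(x)

#' @export
print.model_term <- function(x, ...) {
  cat("<model_term>", term_label(x), "\n"); invisible(x)
}

#' Display label of a term ("x", "x^2", "a:b")
#' @param term a `model_term`.
#' @return character scalar.
#' @export
term_label <- function(term) {
  switch(term$kind,
         linear = term$vars,
         quadratic = paste0(term$vars, "^2"),
         interaction = paste(term$vars, collapse = ":"))
}

# canonical order: linear (alphabetical), quadratics, interactions
term_sort_key <- function(term) {
  rank <- match(term$kind, c("linear", "quadratic", "interaction"))
  sprintf("%d|%s", rank, paste(term$vars, collapse = "|"))
}

sort_terms <- function(terms) terms[order(vapply(terms, term_sort_key, ""))]

term_column <- function(data, term) {
  for (v in term$vars)
    if (!v %in% names(data))
      stop(sprintf("unknown variable '%s' in term '%s'", v, term_label(term)),
           call. = FALSE)
  col <- switch(term$kind,
                linear = data[[term$vars]],
                quadratic = data[[term$vars]]^2,
                interaction = data[[term$vars[1]]] * data[[term$vars[2]]])
  as.numeric(col)
}

#' Candidate model specification
#'
#' @param outcome name of the client-level dependent variable.
#' @param terms list of [model_term()]s (duplicates are an error); the
#'   intercept and the therapist random intercept are always included.
#' @param group name of the grouping (therapist) column.
#' @param max_terms cap on the number of fixed-effect terms (default 9).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome, terms = list(), group = "therapist_id",
                       max_terms = 9) {
  if (inherits(terms, "model_term")) terms <- list(terms)
  labels <- vapply(terms, term_label, "")
  if (anyDuplicated(labels))
    stop("duplicate terms in model specification", call. = FALSE)
  if (length(terms) > max_terms)
    stop(sprintf("%d terms exceed the cap of %d", length(terms), max_terms),
         call. = FALSE)
  structure(list(outcome = outcome, terms = sort_terms(terms), group = group,
                 estimation = "ML"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  lab <- if (length(x$terms))
    paste(vapply(x$terms, term_label, ""), collapse = " + ") else "1"
  cat(sprintf("<model_spec> %s ~ %s + (1 | %s), ML\n", x$outcome, lab, x$group))
  invisible(x)
}

#' Build the numeric design for a mixed-model fit
#'
#' @param data one-row-per-client data.frame containing the outcome, all
#'   term variables (preprocessed: standardized / coded, no missing cells)
#'   and the grouping column.
#' @param spec a [model_spec()].
#' @return A list with the response `y`, fixed-effect matrix `X` (intercept
#'   first, then terms in canonical order), group factor `group`, and the
#'   spec itself.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$outcome %in% names(data))
    stop(sprintf("unknown outcome '%s'", spec$outcome), call. = FALSE)
  if (!spec$group %in% names(data))
    stop(sprintf("unknown grouping column '%s'", spec$group), call. = FALSE)
  y <- as.numeric(data[[spec$outcome]])
  cols <- lapply(spec$terms, function(t) term_column(data, t))
  X <- cbind(`(Intercept)` = rep(1, nrow(data)),
             if (length(cols)) do.call(cbind, cols))
  if (length(spec$terms))
    colnames(X) <- c("(Intercept)", vapply(spec$terms, term_label, ""))
  if (anyNA(y) || anyNA(X))
    stop("missing cells in outcome or predictors; impute before fitting",
         call. = FALSE)
  list(y = y, X = X, group = factor(data[[spec$group]]), spec = spec)
}
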