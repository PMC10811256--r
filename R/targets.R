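#' Trajectory specification for stage-1 growth models
#'
#' Describes how a longitudinal series is turned into a per-client slope:
#' which outcome column, which timepoints, and the numeric time coding.
#' The default coding is the measurement index (pre = 0 ... post = 5 for
#' the symptom outcome; s1 = 0 ... s7 = 3 for alliance); a week-based
#' coding (`weeks = TRUE`) maps the alliance sessions to 1, 3, 5, 7.
#'
#' @param outcome session column (`"oq_total"`, `"wai_client"`,
#'   `"wai_therapist"`).
#' @param timepoints character vector of timepoints to use.
#' @param time_coding named numeric vector mapping each timepoint to a
#'   time value; must be strictly increasing in timepoint order.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(outcome,
                            timepoints = if (outcome == "oq_total")
                              TIMEPOINTS else WAI_TIMEPOINTS,
                            time_coding = setNames(seq_along(timepoints) - 1,
                                                   timepoints)) {
  stopifnot(length(timepoints) >= 2,
            all(timepoints %in% TIMEPOINTS),
            all(timepoints %in% names(time_coding)))
  tc <- time_coding[timepoints]
  if (any(diff(tc) <= 0))
    stop("time coding must be strictly increasing in timepoint order",
         call. = FALSE)
  structure(list(outcome = outcome, timepoints = timepoints,
                 time_coding = tc),
            class = "trajectory_spec")
}

#' @rdname trajectory_spec
#' @param outcome session column name.
#' @export
week_coding <- function(outcome) {
  if (outcome == "oq_total")
    trajectory_spec(outcome, TIMEPOINTS,
                    c(pre = 0, s1 = 1, s3 = 3, s5 = 5, s7 = 7, post = 8))
  else trajectory_spec(outcome, WAI_TIMEPOINTS,
                       c(s1 = 1, s3 = 3, s5 = 5, s7 = 7))
}

# Shared stage-1 machinery: fit y ~ time with uncorrelated client random
# intercept and slope by ML and return conditional (shrunken) per-client
# slopes.  Time is centered at the fixed mean of the spec's coding so that
# (a) index-vs-week recoding is a pure rescaling and (b) for balanced
# series the conditional slope is a coordinate-wise shrinkage of the
# per-client OLS slope toward the fixed-effect slope.  When the series are
# exactly linear per client (max |OLS residual| ~ 0) the mixed model is
# degenerate and the OLS slopes ARE the noise-free limit of the
# conditional slopes, so they are returned directly.
growth_slopes <- function(x, spec) {
  stopifnot(inherits(x, "dyad_dataset"), inherits(spec, "trajectory_spec"))
  se <- x$sessions
  se <- se[se$timepoint %in% spec$timepoints & !is.na(se[[spec$outcome]]), ]
  long <- data.frame(client_id = se$client_id,
                     time = unname(spec$time_coding[se$timepoint]),
                     y = se[[spec$outcome]], stringsAsFactors = FALSE)
  counts <- table(long$client_id)
  all_ids <- x$clients$client_id
  ok_ids <- names(counts)[counts >= 2]
  dropped <- setdiff(all_ids, ok_ids)
  if (length(dropped))
    warning(sprintf("excluding client(s) with fewer than 2 observed '%s' values: %s",
                    spec$outcome, paste(dropped, collapse = ", ")),
            call. = FALSE)
  long <- long[long$client_id %in% ok_ids, ]
  long$tc <- long$time - mean(spec$time_coding)

  # per-client OLS oracle quantities (also the degenerate-noise branch)
  ols <- vapply(split(long, long$client_id), function(d) {
    f <- lm(y ~ tc, data = d)
    c(slope = unname(coef(f)[2]), maxres = max(abs(stats::residuals(f))))
  }, numeric(2))
  ols_slope <- ols["slope", ]

  if (max(ols["maxres", ]) < 1e-8) {
    cond <- ols_slope
    fixed_slope <- mean(ols_slope)
  } else {
    fit <- tryCatch(
      lme4::lmer(y ~ tc + (1 + tc || client_id), data = long, REML = FALSE),
      error = function(e) stop("stage-1 growth model failed to converge: ",
                               conditionMessage(e), call. = FALSE))
    fixed_slope <- unname(lme4::fixef(fit)["tc"])
    re <- lme4::ranef(fit)$client_id
    dev <- if ("tc" %in% colnames(re))
      setNames(re[, "tc"], rownames(re)) else setNames(rep(0, nrow(re)),
                                                       rownames(re))
    cond <- fixed_slope + dev[names(ols_slope)]
  }
  structure(data.frame(client_id = names(ols_slope),
                       slope = unname(cond),
                       ols_slope = unname(ols_slope),
                       n_obs = as.integer(counts[names(ols_slope)]),
                       row.names = NULL, stringsAsFactors = FALSE),
            fixed_slope = fixed_slope, excluded = dropped)
}

#' Client-specific outcome slope (Model 1 dependent variable)
#'
#' Fits one linear growth model to the symptom outcome series of all
#' clients jointly (ML, client random intercept and slope) and returns
#' each client's conditional (shrunken) slope. Negative values mean
#' symptom reduction.
#'
#' @param x a `dyad_dataset`.
#' @param spec a [trajectory_spec()]; defaults to all six timepoints with
#'   index coding 0..5.
#' @return data.frame `client_id`, `slope`, `ols_slope`, `n_obs`, with the
#'   fitted fixed-effect slope and any excluded clients as attributes.
#' @export
outcome_slope <- function(x, spec = trajectory_spec("oq_total")) {
  stopifnot(spec$outcome == "oq_total")
  growth_slopes(x, spec)
}

#' Between-client alliance aggregate (Models 2-3 dependent variables)
#'
#' Per-client arithmetic mean of the available session alliance ratings
#' (sessions 1/3/5/7), the trait-like alliance level.
#'
#' @param x a `dyad_dataset`.
#' @param rater `"client"` or `"therapist"`.
#' @return data.frame `client_id`, `mean_alliance`, `n_obs`.
#' @export
between_alliance <- function(x, rater = c("client", "therapist")) {
  rater <- match.arg(rater)
  col <- paste0("wai_", rater)
  se <- x$sessions[x$sessions$timepoint %in% WAI_TIMEPOINTS, ]
  m <- tapply(se[[col]], se$client_id, function(v) mean(v, na.rm = TRUE))
  n <- tapply(se[[col]], se$client_id, function(v) sum(!is.na(v)))
  all_ids <- x$clients$client_id
  m <- m[all_ids]; n <- n[all_ids]
  n[is.na(n)] <- 0L
  dropped <- all_ids[n == 0]
  if (length(dropped))
    warning(sprintf("excluding client(s) with no observed '%s' sessions: %s",
                    col, paste(dropped, collapse = ", ")), call. = FALSE)
  keep <- n > 0
  data.frame(client_id = all_ids[keep], mean_alliance = unname(m[keep]),
             n_obs = as.integer(n[keep]), stringsAsFactors = FALSE)
}

#' Within-client alliance slope (Models 4-5 dependent variables)
#'
#' Conditional client-specific time slope of the session alliance series
#' from a mixed growth model; positive values mean a strengthening
#' alliance over treatment.
#'
#' @param x a `dyad_dataset`.
#' @param rater `"client"` or `"therapist"`.
#' @param spec a [trajectory_spec()] for the alliance series; defaults to
#'   sessions 1/3/5/7 with index coding 0..3.
#' @return as [outcome_slope()].
#' @export
within_alliance_slope <- function(x, rater = c("client", "therapist"),
                                  spec = NULL) {
  rater <- match.arg(rater)
  col <- paste0("wai_", rater)
  if (is.null(spec)) spec <- trajectory_spec(col)
  stopifnot(spec$outcome == col)
  growth_slopes(x, spec)
}

#' Derive the five client-level dependent variables
#'
#' Runs the two between-client aggregates and the three stage-1 growth
#' models, returning one row per client (clients excluded from a given
#' derivation carry `NA` in that column).
#'
#' @param x a `dyad_dataset`.
#' @param oq_spec,wai_client_spec,wai_therapist_spec optional
#'   [trajectory_spec()] overrides.
#' @return data.frame with `client_id`, `therapist_id` and the five DVs
#'   `outcome_slope`, `alliance_between_client`, `alliance_between_therapist`,
#'   `alliance_within_client`, `alliance_within_therapist`.
#' @export
derive_targets <- function(x, oq_spec = trajectory_spec("oq_total"),
                           wai_client_spec = trajectory_spec("wai_client"),
                           wai_therapist_spec = trajectory_spec("wai_therapist")) {
  out <- data.frame(client_id = x$clients$client_id,
                    therapist_id = x$clients$therapist_id,
                    stringsAsFactors = FALSE)
  put <- function(out, df, value_col, name) {
    out[[name]] <- df[[value_col]][match(out$client_id, df$client_id)]
    out
  }
  out <- put(out, outcome_slope(x, oq_spec), "slope", "outcome_slope")
  out <- put(out, between_alliance(x, "client"), "mean_alliance",
             "alliance_between_client")
  out <- put(out, between_alliance(x, "therapist"), "mean_alliance",
             "alliance_between_therapist")
  out <- put(out, within_alliance_slope(x, "client", wai_client_spec),
             "slope", "alliance_within_client")
  out <- put(out, within_alliance_slope(x, "therapist", wai_therapist_spec),
             "slope", "alliance_within_therapist")
  out
}

#' Standardize derived dependent variables
#'
#' Z-scores each DV across the included (non-missing) clients; the
#' scaling statistics are attached for back-transformation.
#'
#' @param targets data.frame as returned by [derive_targets()].
#' @param columns DV columns to standardize (default: all five).
#' @return The standardized data.frame with a `scaling` attribute
#'   (data.frame `variable`, `mean`, `sd`).
#' @export
standardize_targets <- function(targets,
                                columns = intersect(
                                  c("outcome_slope", "alliance_between_client",
                                    "alliance_between_therapist",
                                    "alliance_within_client",
                                    "alliance_within_therapist"),
                                  names(targets))) {
  stats <- data.frame(variable = character(), mean = double(), sd = double(),
                      stringsAsFactors = FALSE)
  for (v in columns) {
    col <- targets[[v]]
    m <- mean(col, na.rm = TRUE); s <- sd(col, na.rm = TRUE)
    if (!is.finite(s) || s <= 0)
      stop(sprintf("degenerate dependent variable '%s': sd is zero", v),
           call. = FALSE)
    targets[[v]] <- (col - m) / s
    stats <- rbind(stats, data.frame(variable = v, mean = m, sd = s,
                                     stringsAsFactors = FALSE))
  }
  attr(targets, "scaling") <- stats
  targets
}

#' Assemble the client-level analysis table
#'
#' Joins the derived targets with the preprocessed client covariates and
#' the client's therapist covariates (therapist demographics prefixed
#' `therapist_` to avoid clashing with the client's own).
#'
#' @param x a preprocessed `dyad_dataset` (standardized, binaries coded,
#'   imputed).
#' @param targets data.frame from [derive_targets()] /
#'   [standardize_targets()].
#' @return One-row-per-client data.frame ready for [build_design()].
#' @export
build_analysis_table <- function(x, targets) {
  th <- x$therapists
  names(th)[names(th) %in% c("age", "gender", "income")] <-
    paste0("therapist_", c("age", "gender", "income"))
  out <- merge(targets, x$clients, by = c("client_id", "therapist_id"),
               sort = FALSE)
  out <- merge(out, th, by = "therapist_id", sort = FALSE)
  out[match(targets$client_id, out$client_id), , drop = FALSE]
}
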