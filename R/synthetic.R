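#' Configuration of the synthetic dyadic-study generator
#'
#' Describes a complete generating model for a nested
#' therapist -> client -> session study: baseline covariate distributions,
#' a ground-truth model for the client-level outcome slope, latent growth
#' trajectories for the symptom outcome (six timepoints: pre, sessions
#' 1/3/5/7, post) and for client- and therapist-rated alliance (sessions
#' 1/3/5/7), and MCAR missingness in income. Defaults mirror the study
#' design the package targets: 23 therapists, 2 clients each, 7 weekly
#' sessions, covariates on an already-standardized scale (continuous
#' N(0,1); binary levels coded -0.5/+0.5 when entering terms).
#'
#' @param n_therapists number of therapists (default 23).
#' @param clients_per_therapist clients per therapist (default 2).
#' @param covariates list of covariate specs, each a list with `name`,
#'   `level` (`"therapist"`/`"client"`), `type` (`"continuous"` with
#'   `mean`, `sd`, or `"binary"` with `levels = c(low, high)` and `p_high`).
#'   Therapist demographics use prefixed names (`therapist_age`, ...) so
#'   that model terms are unambiguous; the prefix is stripped when writing
#'   the therapist CSV table.
#' @param outcome_model ground truth for the client outcome slope:
#'   `list(intercept, terms = list(list(term, coef), ...), therapist_sd,
#'   client_sd)`.
#' @param oq_trajectory `list(noise_sd, time_coding)` for the outcome
#'   series; the client's trajectory intercept is their baseline OQ score.
#' @param alliance_client,alliance_therapist per-rater alliance trajectory:
#'   `list(intercept, slope, intercept_sd, slope_sd, therapist_sd,
#'   noise_sd, level_terms, slope_terms, time_coding)`.
#' @param missing_rate_income MCAR missingness fraction for client income
#'   (default 0.087, i.e. about 4 cells in a 46-client study).
#' @param seed integer seed making the generated dataset reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_therapists = 23,
                             clients_per_therapist = 2,
                             covariates = default_covariates(),
                             outcome_model = default_outcome_model(),
                             oq_trajectory = list(
                               noise_sd = 0.4,
                               time_coding = c(pre = 0, s1 = 1, s3 = 2,
                                               s5 = 3, s7 = 4, post = 5)),
                             alliance_client = default_alliance(
                               therapist_sd = 0.4, intercept_sd = 0.6),
                             alliance_therapist = default_alliance(
                               therapist_sd = 0.6, intercept_sd = 0.4),
                             missing_rate_income = 0.087,
                             seed = 1L) {
  cfg <- structure(list(n_therapists = as.integer(n_therapists),
                        clients_per_therapist = as.integer(clients_per_therapist),
                        covariates = covariates,
                        outcome_model = outcome_model,
                        oq_trajectory = oq_trajectory,
                        alliance_client = alliance_client,
                        alliance_therapist = alliance_therapist,
                        missing_rate_income = missing_rate_income,
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' Default covariate distributions of the emulated study
#'
#' Continuous covariates are generated already standardized (N(0,1));
#' binary level probabilities follow the study's reported composition
#' (15/23 female therapists, 11/23 trained, 45.3% male clients).
#'
#' @return list of covariate specs for [synthetic_config()].
#' @export
default_covariates <- function() {
  cont <- function(name, level) list(name = name, level = level,
                                     type = "continuous", mean = 0, sd = 1)
  bin <- function(name, level, levels, p_high)
    list(name = name, level = level, type = "binary", levels = levels,
         p_high = p_high)
  list(
    cont("therapist_age", "therapist"),
    bin("therapist_gender", "therapist", c("female", "male"), 8 / 23),
    cont("therapist_income", "therapist"),
    bin("fis_level", "therapist", c("low", "high"), 0.5),
    bin("training", "therapist", c("untrained", "trained"), 11 / 23),
    bin("orientation", "therapist", c("eclectic_undetected", "cog_dyn_hum"), 0.5),
    cont("age", "client"),
    bin("gender", "client", c("female", "male"), 0.453),
    cont("income", "client"),
    cont("ssi_total", "client"),
    cont("iip_total", "client"),
    cont("oq_total_baseline", "client"),
    cont("oq_sub_symptom", "client"),
    cont("oq_sub_interpersonal", "client"),
    cont("oq_sub_social_role", "client"),
    bin("prior_treatment", "client", c("no", "yes"), 0.3))
}

default_outcome_model <- function() {
  list(intercept = -0.2,
       terms = list(
         list(term = model_term("linear", "oq_total_baseline"), coef = -0.1),
         list(term = model_term("linear", "orientation"), coef = 0.15)),
       therapist_sd = 0.15,
       client_sd = 0.3)
}

default_alliance <- function(therapist_sd, intercept_sd) {
  list(intercept = 0, slope = 0.15,
       intercept_sd = intercept_sd, slope_sd = 0.25,
       therapist_sd = therapist_sd, noise_sd = 0.3,
       level_terms = list(
         list(term = model_term("linear", "iip_total"), coef = -0.2),
         list(term = model_term("linear", "fis_level"), coef = 0.3)),
       slope_terms = list(
         list(term = model_term("linear", "oq_total_baseline"), coef = -0.1)),
       time_coding = c(s1 = 0, s3 = 1, s5 = 2, s7 = 3))
}

validate_synthetic_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, what) if (!isTRUE(ok)) bad <<- c(bad, what)
  chk(cfg$n_therapists >= 2, "n_therapists >= 2")
  chk(cfg$clients_per_therapist >= 1, "clients_per_therapist >= 1")
  chk(cfg$missing_rate_income >= 0 && cfg$missing_rate_income < 1,
      "missing_rate_income in [0, 1)")
  cov_names <- vapply(cfg$covariates, `[[`, "", "name")
  chk(!anyDuplicated(cov_names), "unique covariate names")
  for (cv in cfg$covariates) {
    if (cv$type == "continuous") chk(cv$sd >= 0, paste0(cv$name, ": sd >= 0"))
    if (cv$type == "binary")
      chk(cv$p_high >= 0 && cv$p_high <= 1, paste0(cv$name, ": p_high in [0,1]"))
  }
  for (nm in c("outcome_model")) {
    m <- cfg[[nm]]
    chk(m$therapist_sd >= 0, paste0(nm, ": therapist_sd >= 0"))
    chk(m$client_sd >= 0, paste0(nm, ": client_sd >= 0"))
    for (tc in m$terms)
      chk(all(tc$term$vars %in% cov_names),
          sprintf("%s term '%s' references declared covariates", nm,
                  term_label(tc$term)))
  }
  for (nm in c("alliance_client", "alliance_therapist")) {
    m <- cfg[[nm]]
    for (fld in c("intercept_sd", "slope_sd", "therapist_sd", "noise_sd"))
      chk(m[[fld]] >= 0, paste0(nm, ": ", fld, " >= 0"))
    for (tc in c(m$level_terms, m$slope_terms))
      chk(all(tc$term$vars %in% cov_names),
          sprintf("%s term '%s' references declared covariates", nm,
                  term_label(tc$term)))
  }
  if (length(bad))
    stop("invalid synthetic_config: ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(cfg)
}

# sum of coefficient * term(covariates) over a list of (term, coef) pairs
eval_true_terms <- function(df, term_list) {
  out <- rep(0, nrow(df))
  for (tc in term_list) out <- out + tc$coef * term_column(df, tc$term)
  out
}

#' Generate a synthetic dyadic study with known ground truth
#'
#' Draws baseline covariates, client-level latent targets (outcome slope
#' and per-rater alliance level/slope as
#' `intercept + sum(coef * term) + therapist effect + client deviation`),
#' and longitudinal session series from client-specific intercept/slope
#' plus session noise. Fully reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` (useful for replicate studies from
#'   one configuration).
#' @return A list with `dataset` (a [dyad_dataset()]) and `truth` (the
#'   realized generating quantities: coefficients, therapist effects,
#'   client-level intercepts/slopes, and the numeric covariate frame used
#'   to evaluate the true terms).
#' @export
generate_study <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  set.seed(seed)
  nt <- config$n_therapists
  nc <- nt * config$clients_per_therapist
  tid <- sprintf("T%03d", seq_len(nt))
  cid <- sprintf("C%03d", seq_len(nc))
  ther_of <- rep(tid, each = config$clients_per_therapist)

  draw <- function(cv, n) {
    if (cv$type == "continuous") rnorm(n, cv$mean, cv$sd)
    else cv$levels[1 + rbinom(n, 1, cv$p_high)]
  }
  ther_cov <- list(); cli_cov <- list()
  for (cv in config$covariates) {
    if (cv$level == "therapist") ther_cov[[cv$name]] <- draw(cv, nt)
    else cli_cov[[cv$name]] <- draw(cv, nc)
  }

  # numeric frame (binary -> -0.5/+0.5) used to evaluate the true terms
  num <- data.frame(row.names = seq_len(nc))
  for (cv in config$covariates) {
    raw <- if (cv$level == "therapist")
      ther_cov[[cv$name]][match(ther_of, tid)] else cli_cov[[cv$name]]
    num[[cv$name]] <- if (cv$type == "binary")
      ifelse(raw == cv$levels[2], 0.5, -0.5) else raw
  }

  om <- config$outcome_model
  u_out <- rnorm(nt, 0, om$therapist_sd)
  slope_oq <- om$intercept + eval_true_terms(num, om$terms) +
    u_out[match(ther_of, tid)] + rnorm(nc, 0, om$client_sd)
  icpt_oq <- num$oq_total_baseline

  alliance_draw <- function(m) {
    u <- rnorm(nt, 0, m$therapist_sd)
    level <- m$intercept + eval_true_terms(num, m$level_terms) +
      u[match(ther_of, tid)] + rnorm(nc, 0, m$intercept_sd)
    slope <- m$slope + eval_true_terms(num, m$slope_terms) +
      rnorm(nc, 0, m$slope_sd)
    list(therapist_effects = setNames(u, tid), levels = level, slopes = slope)
  }
  ac <- alliance_draw(config$alliance_client)
  at <- alliance_draw(config$alliance_therapist)

  # session rows, client-major, timepoints in design order
  oq_t <- config$oq_trajectory$time_coding
  wai_t_c <- config$alliance_client$time_coding
  wai_t_t <- config$alliance_therapist$time_coding
  n_tp <- length(TIMEPOINTS); n_wai <- length(WAI_TIMEPOINTS)
  ci6 <- rep(seq_len(nc), each = n_tp)
  tp6 <- rep(TIMEPOINTS, nc)
  oq <- icpt_oq[ci6] + slope_oq[ci6] * unname(oq_t[tp6]) +
    rnorm(nc * n_tp, 0, config$oq_trajectory$noise_sd)
  ci4 <- rep(seq_len(nc), each = n_wai)
  tp4 <- rep(WAI_TIMEPOINTS, nc)
  wc <- ac$levels[ci4] + ac$slopes[ci4] * unname(wai_t_c[tp4]) +
    rnorm(nc * n_wai, 0, config$alliance_client$noise_sd)
  wt <- at$levels[ci4] + at$slopes[ci4] * unname(wai_t_t[tp4]) +
    rnorm(nc * n_wai, 0, config$alliance_therapist$noise_sd)
  pos <- match(paste(ci6, tp6), paste(ci4, tp4))  # NA at pre/post
  sessions <- data.frame(client_id = cid[ci6], timepoint = tp6,
                         wai_client = wc[pos], wai_therapist = wt[pos],
                         oq_total = oq, stringsAsFactors = FALSE)

  strip <- function(nm) sub("^therapist_", "", nm)
  therapists <- data.frame(therapist_id = tid, stringsAsFactors = FALSE)
  for (nm in names(ther_cov)) therapists[[strip(nm)]] <- ther_cov[[nm]]
  therapists <- therapists[, required_columns$therapists]
  clients <- data.frame(client_id = cid, therapist_id = ther_of,
                        stringsAsFactors = FALSE)
  for (nm in names(cli_cov)) clients[[nm]] <- cli_cov[[nm]]
  clients <- clients[, required_columns$clients]

  ds <- dyad_dataset(therapists, clients, sessions,
                     provenance = list(generator = list(seed = seed)))
  truth <- list(outcome = list(intercept = om$intercept,
                               terms = om$terms,
                               therapist_effects = setNames(u_out, tid),
                               client_slopes = setNames(slope_oq, cid),
                               client_intercepts = setNames(icpt_oq, cid)),
                alliance_client = ac, alliance_therapist = at,
                covariate_frame = cbind(client_id = cid,
                                        therapist_id = ther_of, num))
  if (config$missing_rate_income > 0)
    ds <- inject_missingness(ds, "clients.income",
                             config$missing_rate_income, seed = seed + 1L)
  list(dataset = ds, truth = truth)
}

#' Inject missing-completely-at-random cells
#'
#' @param x a `dyad_dataset`.
#' @param variable covariate to perturb (identifiers and timepoints are not
#'   eligible); ambiguous names use the `"clients.income"` syntax.
#' @param rate missingness probability per cell, in `[0, 1)`.
#' @param seed integer seed.
#' @return The dataset with cells set missing; mask recorded in provenance.
#' @export
inject_missingness <- function(x, variable, rate, seed = 1L) {
  stopifnot(inherits(x, "dyad_dataset"))
  if (rate < 0 || rate >= 1)
    stop("rate must be in [0, 1)", call. = FALSE)
  if (sub("^.*\\.", "", variable) %in% c("therapist_id", "client_id",
                                         "timepoint"))
    stop(sprintf("variable '%s' is not eligible for missingness", variable),
         call. = FALSE)
  rv <- resolve_variable(x, variable)
  if (rate == 0) return(x)
  set.seed(seed)
  n <- nrow(x[[rv$table]])
  mask <- stats::runif(n) < rate
  x[[rv$table]][[rv$name]][mask] <- NA
  x$provenance$missingness <- c(x$provenance$missingness,
                                list(list(variable = rv$key, rate = rate,
                                          seed = seed, mask = which(mask))))
  x
}

#' Per-variable moments of the generated covariates
#'
#' Used to confirm generator calibration: continuous covariates report
#' sample mean and sd; binary (character) covariates report one row per
#' level (`variable:level`) with the observed proportion.
#'
#' @param x a `dyad_dataset`.
#' @return data.frame with columns `variable`, `table`, `mean`, `sd`.
#' @export
covariate_moments <- function(x) {
  stopifnot(inherits(x, "dyad_dataset"))
  if (nrow(x$clients) == 0 && nrow(x$therapists) == 0)
    stop("empty dataset", call. = FALSE)
  out <- list()
  for (tab in c("therapists", "clients")) {
    df <- x[[tab]]
    if (nrow(df) == 0) stop("empty dataset", call. = FALSE)
    for (nm in setdiff(names(df), c("therapist_id", "client_id"))) {
      col <- df[[nm]]
      if (is.numeric(col)) {
        out[[length(out) + 1]] <- data.frame(
          variable = nm, table = tab, mean = mean(col, na.rm = TRUE),
          sd = sd(col, na.rm = TRUE), stringsAsFactors = FALSE)
      } else {
        for (lv in sort(unique(col[!is.na(col)]))) {
          p <- mean(col == lv, na.rm = TRUE)
          out[[length(out) + 1]] <- data.frame(
            variable = paste0(nm, ":", lv), table = tab, mean = p,
            sd = sqrt(p * (1 - p)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
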