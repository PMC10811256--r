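#' Nested dyadic study data
#'
#' A `dyad_dataset` holds the three tables of a dyadic psychotherapy study:
#' therapists, clients (nested in therapists), and long-format session
#' records. Referential integrity and the measurement design (alliance only
#' at sessions 1/3/5/7; symptom outcome at pre, sessions 1/3/5/7 and post)
#' are enforced at construction.
#'
#' @param therapists data.frame with columns `therapist_id`, `age`,
#'   `gender`, `income`, `fis_level`, `training`, `orientation`.
#' @param clients data.frame with columns `client_id`, `therapist_id`,
#'   `age`, `gender`, `income`, `ssi_total`, `iip_total`,
#'   `oq_total_baseline`, `oq_sub_symptom`, `oq_sub_interpersonal`,
#'   `oq_sub_social_role`, `prior_treatment`.
#' @param sessions long data.frame with columns `client_id`,
#'   `timepoint` (one of `pre`, `s1`, `s3`, `s5`, `s7`, `post`),
#'   `wai_client`, `wai_therapist`, `oq_total`.
#' @param provenance free-form list of metadata (source files, generator
#'   seed and configuration, preprocessing steps applied).
#' @return An object of class `dyad_dataset`.
#' @export
dyad_dataset <- function(therapists, clients, sessions, provenance = list()) {
  x <- structure(
    list(therapists = as.data.frame(therapists),
         clients = as.data.frame(clients),
         sessions = as.data.frame(sessions),
         provenance = provenance),
    class = "dyad_dataset")
  validate_dyad_dataset(x)
  x
}

required_columns <- list(
  therapists = c("therapist_id", "age", "gender", "income", "fis_level",
                 "training", "orientation"),
  clients = c("client_id", "therapist_id", "age", "gender", "income",
              "ssi_total", "iip_total", "oq_total_baseline",
              "oq_sub_symptom", "oq_sub_interpersonal",
              "oq_sub_social_role", "prior_treatment"),
  sessions = c("client_id", "timepoint", "wai_client", "wai_therapist",
               "oq_total"))

#' Validate a dyad_dataset
#'
#' Checks schemas, closed vocabularies, uniqueness and referential
#' integrity; emits warnings (not errors) for clients whose measurement
#' series are too sparse to support target derivation.
#'
#' @param x a `dyad_dataset`.
#' @return `x`, invisibly.
#' @export
validate_dyad_dataset <- function(x) {
  for (tab in names(required_columns)) {
    missing_cols <- setdiff(required_columns[[tab]], names(x[[tab]]))
    if (length(missing_cols))
      stop(sprintf("schema error: table '%s' is missing column(s): %s",
                   tab, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  th <- x$therapists; cl <- x$clients; se <- x$sessions
  if (anyDuplicated(th$therapist_id))
    stop("integrity error: duplicate therapist_id", call. = FALSE)
  if (anyDuplicated(cl$client_id))
    stop("integrity error: duplicate client_id", call. = FALSE)
  unknown <- setdiff(cl$therapist_id, th$therapist_id)
  if (length(unknown))
    stop(sprintf("integrity error: client references unknown therapist(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  bad_tp <- setdiff(unique(as.character(se$timepoint)), TIMEPOINTS)
  if (length(bad_tp))
    stop(sprintf("vocabulary error: unknown timepoint(s): %s (allowed: %s)",
                 paste(bad_tp, collapse = ", "),
                 paste(TIMEPOINTS, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(se[c("client_id", "timepoint")]))
    stop("integrity error: duplicate (client_id, timepoint) rows", call. = FALSE)
  unknown_cl <- setdiff(se$client_id, cl$client_id)
  if (length(unknown_cl))
    stop(sprintf("integrity error: session rows for unknown client(s): %s",
                 paste(unknown_cl, collapse = ", ")), call. = FALSE)
  off <- !(se$timepoint %in% WAI_TIMEPOINTS)
  if (any(off & (!is.na(se$wai_client) | !is.na(se$wai_therapist))))
    stop("integrity error: alliance (WAI) values outside sessions s1/s3/s5/s7",
         call. = FALSE)
  # soft design checks: sparse series are flagged here, excluded later
  oq_n <- tapply(!is.na(se$oq_total), se$client_id, sum)
  sparse <- names(oq_n)[oq_n < 2]
  if (length(sparse))
    warning(sprintf("client(s) with fewer than 2 observed oq_total values: %s",
                    paste(sparse, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' @export
print.dyad_dataset <- function(x, ...) {
  cat(sprintf("<dyad_dataset> %d therapists, %d clients, %d session rows\n",
              nrow(x$therapists), nrow(x$clients), nrow(x$sessions)))
  invisible(x)
}

#' Read the three study tables from CSV
#'
#' @param therapist_path,client_path,session_path paths to the three CSV
#'   files (see [dyad_dataset()] for the required columns). Empty cells and
#'   the literal string `NA` are read as missing.
#' @return A validated [dyad_dataset()].
#' @export
read_study_tables <- function(therapist_path, client_path, session_path) {
  for (p in c(therapist_path, client_path, session_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  rd <- function(p) read.csv(p, na.strings = c("", "NA"),
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  dyad_dataset(rd(therapist_path), rd(client_path), rd(session_path),
               provenance = list(source = list(therapists = therapist_path,
                                               clients = client_path,
                                               sessions = session_path)))
}

#' Write the three study tables to CSV
#'
#' Numeric cells are written with 17 significant digits so that a
#' write/read round trip reproduces values to full double precision.
#'
#' @param x a `dyad_dataset`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_study_tables <- function(x, dir) {
  stopifnot(inherits(x, "dyad_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, path) {
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) {
        v <- sprintf("%.17g", df[[j]])
        v[is.na(df[[j]])] <- NA
        df[[j]] <- v
      }
    }
    write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
              quote = FALSE)
  }
  paths <- file.path(dir, c("therapists.csv", "clients.csv", "sessions.csv"))
  wr(x$therapists, paths[1]); wr(x$clients, paths[2]); wr(x$sessions, paths[3])
  invisible(paths)
}

# Resolve a (possibly "table.name"-prefixed) variable name to its table.
resolve_variable <- function(x, name) {
  if (grepl("^(therapists|clients)\\.", name)) {
    tab <- sub("\\..*$", "", name)
    nm <- sub("^[^.]*\\.", "", name)
    if (!nm %in% names(x[[tab]]))
      stop(sprintf("unknown variable '%s' in table '%s'", nm, tab), call. = FALSE)
    return(list(table = tab, name = nm, key = name))
  }
  hits <- c("therapists", "clients")[c(name %in% names(x$therapists),
                                       name %in% names(x$clients))]
  hits <- setdiff(hits, if (name %in% c("therapist_id", "client_id")) hits else character())
  if (length(hits) == 0)
    stop(sprintf("unknown variable '%s'", name), call. = FALSE)
  if (length(hits) == 2)
    stop(sprintf("variable '%s' exists in both tables; use 'clients.%s' or 'therapists.%s'",
                 name, name, name), call. = FALSE)
  list(table = hits, name = name, key = paste(hits, name, sep = "."))
}

#' Z-score continuous baseline predictors
#'
#' Standardizes the named variables to mean 0, sd 1 (sample sd, denominator
#' n - 1). When `stats` is supplied (e.g. reusing training-fold statistics on
#' held-out data in cross-validation) those means/sds are applied unchanged.
#'
#' @param x a `dyad_dataset`.
#' @param variables character vector of variable names; names present in
#'   both tables must be disambiguated as `"clients.income"` /
#'   `"therapists.income"`.
#' @param stats optional scaling statistics as returned by this function: a
#'   data.frame with columns `variable`, `mean`, `sd`.
#' @return A list with elements `dataset` (the scaled `dyad_dataset`) and
#'   `stats` (the scaling statistics used).
#' @export
zscore_continuous <- function(x, variables, stats = NULL) {
  stopifnot(inherits(x, "dyad_dataset"))
  out <- x
  used <- data.frame(variable = character(), mean = double(), sd = double(),
                     stringsAsFactors = FALSE)
  for (v in variables) {
    rv <- resolve_variable(x, v)
    col <- out[[rv$table]][[rv$name]]
    if (!is.numeric(col))
      stop(sprintf("variable '%s' is not continuous", v), call. = FALSE)
    if (is.null(stats)) {
      m <- mean(col, na.rm = TRUE)
      s <- sd(col, na.rm = TRUE)
    } else {
      idx <- match(rv$key, stats$variable)
      if (is.na(idx)) idx <- match(v, stats$variable)
      if (is.na(idx))
        stop(sprintf("no scaling stats supplied for '%s'", v), call. = FALSE)
      m <- stats$mean[idx]; s <- stats$sd[idx]
    }
    if (!is.finite(s) || s <= 0)
      stop(sprintf("degenerate variable '%s': sd is zero", v), call. = FALSE)
    out[[rv$table]][[rv$name]] <- (col - m) / s
    used <- rbind(used, data.frame(variable = rv$key, mean = m, sd = s,
                                   stringsAsFactors = FALSE))
  }
  out$provenance$scaling <- used
  list(dataset = out, stats = used)
}

#' Recode binary predictors to -0.5 / +0.5
#'
#' @param x a `dyad_dataset`.
#' @param coding_map named list; each element is a named numeric vector of
#'   length 2 mapping the two levels to -0.5 and +0.5, e.g.
#'   `list(gender = c(female = -0.5, male = 0.5))`.
#' @return The recoded `dyad_dataset` (mapping recorded in provenance).
#' @export
code_binaries <- function(x, coding_map) {
  stopifnot(inherits(x, "dyad_dataset"))
  out <- x
  for (v in names(coding_map)) {
    map <- coding_map[[v]]
    if (length(map) != 2 || is.null(names(map)) ||
        !setequal(sort(unname(map)), c(-0.5, 0.5)))
      stop(sprintf("coding for '%s' must map exactly two levels to -0.5 and +0.5", v),
           call. = FALSE)
    rv <- resolve_variable(x, v)
    col <- as.character(out[[rv$table]][[rv$name]])
    extra <- setdiff(unique(col[!is.na(col)]), names(map))
    if (length(extra))
      stop(sprintf("vocabulary error: variable '%s' has unmapped level(s): %s",
                   v, paste(extra, collapse = ", ")), call. = FALSE)
    out[[rv$table]][[rv$name]] <- unname(map[col])
  }
  out$provenance$coding <- coding_map
  out
}

#' k-nearest-neighbour imputation
#'
#' Replaces each missing cell by the unweighted mean of that variable over
#' the `k` nearest reference rows. Distance is Euclidean over the variables
#' observed in both rows, rescaled by the fraction observed
#' (`d^2 = (p/m) * sum over the m shared variables`), the standard KNN
#' imputation convention for partially missing rows. The matrix should be
#' standardized beforehand so variables are commensurable.
#'
#' @param m numeric matrix or data.frame (rows = cases, columns = variables).
#' @param k number of neighbours (default 5).
#' @param reference_rows optional logical mask of rows usable as donors;
#'   defaults to the complete rows.
#' @return The imputed matrix, with an `imputation_log` attribute recording
#'   the donor rows for every imputed cell.
#' @export
knn_impute <- function(m, k = 5, reference_rows = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  p <- ncol(m)
  if (is.null(reference_rows)) reference_rows <- complete.cases(m)
  ref_idx <- which(reference_rows)
  if (k > length(ref_idx))
    stop(sprintf("k = %d exceeds the %d available reference rows",
                 k, length(ref_idx)), call. = FALSE)
  log <- list()
  out <- m
  for (i in seq_len(nrow(m))) {
    miss <- which(is.na(m[i, ]))
    if (!length(miss)) next
    for (v in miss) {
      donors <- ref_idx[!is.na(m[ref_idx, v]) & ref_idx != i]
      if (!length(donors))
        stop(sprintf("variable %d is missing in all reference rows", v),
             call. = FALSE)
      if (k > length(donors))
        stop(sprintf("k = %d exceeds the %d reference rows observed for variable %d",
                     k, length(donors), v), call. = FALSE)
      d <- vapply(donors, function(r) {
        shared <- which(!is.na(m[i, ]) & !is.na(m[r, ]))
        if (!length(shared)) return(Inf)
        sqrt(p / length(shared) * sum((m[i, shared] - m[r, shared])^2))
      }, numeric(1))
      ord <- order(d, donors)  # ties broken by row index for determinism
      sel <- donors[ord[seq_len(k)]]
      out[i, v] <- mean(m[sel, v])
      log[[length(log) + 1]] <- list(row = i, col = v, donors = sel)
    }
  }
  attr(out, "imputation_log") <- log
  out
}
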