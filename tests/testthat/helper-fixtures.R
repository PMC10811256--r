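# Fixtures are built in code; no data files.

# minimal valid three-table study: 2 therapists, 4 clients, 24 session rows
tiny_tables <- function() {
  therapists <- data.frame(
    therapist_id = c("T1", "T2"), age = c(30.5, 41.25),
    gender = c("female", "male"), income = c(1.5, -0.75),
    fis_level = c("low", "high"), training = c("trained", "untrained"),
    orientation = c("cog_dyn_hum", "eclectic_undetected"),
    stringsAsFactors = FALSE)
  clients <- data.frame(
    client_id = paste0("C", 1:4), therapist_id = rep(c("T1", "T2"), each = 2),
    age = c(19, 20, 21, 22), gender = c("female", "male", "male", "female"),
    income = c(0.25, NA, -1.5, 2.125),
    ssi_total = c(0.1, -0.2, 0.3, -0.4), iip_total = c(1, 2, 3, 4) / 8,
    oq_total_baseline = c(0.5, -0.5, 1.5, -1.5),
    oq_sub_symptom = c(0.2, 0.4, 0.6, 0.8),
    oq_sub_interpersonal = c(-0.2, -0.4, -0.6, -0.8),
    oq_sub_social_role = c(0.11, 0.22, 0.33, 0.44),
    prior_treatment = c("no", "yes", "no", "yes"), stringsAsFactors = FALSE)
  tps <- c("pre", "s1", "s3", "s5", "s7", "post")
  sessions <- do.call(rbind, lapply(1:4, function(i) data.frame(
    client_id = paste0("C", i), timepoint = tps,
    wai_client = ifelse(tps %in% c("s1", "s3", "s5", "s7"),
                        4 + i / 10 + seq_along(tps) / 7, NA_real_),
    wai_therapist = ifelse(tps %in% c("s1", "s3", "s5", "s7"),
                           3.5 + i / 9 + seq_along(tps) / 11, NA_real_),
    oq_total = 80 - 2 * i - 3 * (seq_along(tps) - 1) + i / 16,
    stringsAsFactors = FALSE)))
  rownames(sessions) <- NULL
  list(therapists = therapists, clients = clients, sessions = sessions)
}

tiny_dataset <- function() {
  tt <- tiny_tables()
  dyad_dataset(tt$therapists, tt$clients, tt$sessions)
}

# a dyad_dataset with fully deterministic linear series: every client's
# outcome is icpt + slope * t (index coding), alliance is a_icpt + a_slope * t
deterministic_dataset <- function(n_ther = 3, cpt = 2,
                                  oq_icpt = 100, oq_slope = -5,
                                  wai_icpt = 4, wai_slope = 1) {
  nt <- n_ther; nc <- nt * cpt
  tid <- sprintf("T%02d", seq_len(nt)); cid <- sprintf("C%02d", seq_len(nc))
  therapists <- data.frame(
    therapist_id = tid, age = 30, gender = "female", income = 0,
    fis_level = "low", training = "trained", orientation = "cog_dyn_hum",
    stringsAsFactors = FALSE)
  clients <- data.frame(
    client_id = cid, therapist_id = rep(tid, each = cpt), age = 20,
    gender = "male", income = 0, ssi_total = 0, iip_total = 0,
    oq_total_baseline = oq_icpt, oq_sub_symptom = 0,
    oq_sub_interpersonal = 0, oq_sub_social_role = 0,
    prior_treatment = "no", stringsAsFactors = FALSE)
  tps <- c("pre", "s1", "s3", "s5", "s7", "post")
  wai_tps <- c("s1", "s3", "s5", "s7")
  sessions <- do.call(rbind, lapply(seq_len(nc), function(i) data.frame(
    client_id = cid[i], timepoint = tps,
    wai_client = ifelse(tps %in% wai_tps,
                        wai_icpt + wai_slope * (match(tps, wai_tps) - 1),
                        NA_real_),
    wai_therapist = ifelse(tps %in% wai_tps,
                           wai_icpt + wai_slope * (match(tps, wai_tps) - 1),
                           NA_real_),
    oq_total = oq_icpt + oq_slope * (seq_along(tps) - 1),
    stringsAsFactors = FALSE)))
  dyad_dataset(therapists, clients, sessions)
}

# client-level analysis frame for engine/search tests: therapist random
# intercept tau_sd, residual sigma_sd, y = intercept + X beta + u + e
sim_client_frame <- function(n_ther, cpt, beta = c(), intercept = 0,
                             tau_sd = 0.4, sigma_sd = 1,
                             vars = names(beta)) {
  n <- n_ther * cpt
  d <- data.frame(therapist_id = factor(rep(sprintf("T%03d", 1:n_ther),
                                            each = cpt)))
  for (v in vars) d[[v]] <- rnorm(n)
  eta <- rep(intercept, n)
  for (v in names(beta)) eta <- eta + beta[[v]] * d[[v]]
  u <- rnorm(n_ther, 0, tau_sd)
  d$y <- eta + u[as.integer(d$therapist_id)] + rnorm(n, 0, sigma_sd)
  d
}

# independent heredity check working purely on term labels
satisfies_heredity_oracle <- function(u, idx, inter, quad) {
  labs <- u$labels[idx]
  lin <- labs[!grepl("[:^]", labs)]
  for (lb in labs) {
    if (grepl(":", lb)) {
      if (inter && !all(strsplit(lb, ":")[[1]] %in% lin)) return(FALSE)
    } else if (grepl("\\^2", lb, fixed = FALSE)) {
      if (quad && !(sub("\\^2", "", lb) %in% lin)) return(FALSE)
    }
  }
  TRUE
}

# fully deterministic alliance trajectory (all variances zero)
default_alliance_for_test <- function() {
  list(intercept = 0, slope = 0.15, intercept_sd = 0, slope_sd = 0,
       therapist_sd = 0, noise_sd = 0,
       level_terms = list(), slope_terms = list(),
       time_coding = c(s1 = 0, s3 = 1, s5 = 2, s7 = 3))
}

# direct multivariate-Gaussian log-density oracle for the two-level model
mvn_loglik_oracle <- function(y, X, beta, tau00, sigma2, group) {
  n <- length(y)
  Z <- outer(as.character(group), unique(as.character(group)), `==`) * 1
  V <- sigma2 * diag(n) + tau00 * Z %*% t(Z)
  r <- y - drop(X %*% beta)
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% solve(V, r)))
}
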