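test_that("build_design produces the documented columns in canonical order", {
  d <- data.frame(y = 1:3, x = c(-1, 0, 1), g = c(-0.5, 0.5, 0.5),
                  therapist_id = c("a", "a", "b"))
  sp <- model_spec("y", list(model_term("interaction", c("x", "g")),
                             model_term("quadratic", "x"),
                             model_term("linear", "x"),
                             model_term("linear", "g")))
  ds <- build_design(d, sp)
  expect_equal(colnames(ds$X), c("(Intercept)", "g", "x", "x^2", "g:x"))
  expect_equal(unname(ds$X[, "x"]), c(-1, 0, 1))
  expect_equal(unname(ds$X[, "x^2"]), c(1, 0, 1))
  expect_equal(unname(ds$X[, "g:x"]), c(0.5, 0, 0.5))
  d$x[2] <- NA
  expect_error(build_design(d, sp), "impute")
  expect_error(build_design(d, model_spec("y", model_term("linear", "zz"))),
               "unknown variable")
  expect_error(model_spec("y", list(model_term("linear", "x"),
                                    model_term("linear", "x"))),
               "duplicate")
  expect_error(model_spec("y", rep(list(model_term("linear", "x")), 2),
                          max_terms = 1), "duplicate|cap")
})

test_that("engine agrees with lme4 on grouped data", {
  for (s in 1:5) {
    set.seed(600 + s)
    d <- sim_client_frame(25, 3, beta = list(x1 = 0.4, x2 = -0.3),
                          tau_sd = 0.6, sigma_sd = 0.9)
    f <- fit_lmm(build_design(d, model_spec("y", list(
      model_term("linear", "x1"), model_term("linear", "x2")))))
    lf <- lme4::lmer(y ~ x1 + x2 + (1 | therapist_id), data = d,
                     REML = FALSE)
    expect_equal(unname(f$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
    expect_equal(f$loglik, as.numeric(logLik(lf)), tolerance = 1e-7)
    vc <- as.data.frame(lme4::VarCorr(lf))$vcov
    expect_equal(c(f$tau00, f$sigma2), vc, tolerance = 1e-4)
    expect_equal(f$coefficients$se,
                 unname(coef(summary(lf))[, "Std. Error"]),
                 tolerance = 1e-4)
  }
})

test_that("singleton-group fits match the OLS closed form", {
  # with one client per group, V* = (1 + lambda) I and GLS == OLS exactly
  for (s in 1:20) {
    set.seed(700 + s)
    d <- sim_client_frame(60, 1, beta = list(x1 = 0.5, x2 = -0.2),
                          tau_sd = 0, sigma_sd = 1)
    f <- fit_lmm(build_design(d, model_spec("y", list(
      model_term("linear", "x1"), model_term("linear", "x2")))))
    b_ols <- coef(lm(y ~ x1 + x2, data = d))
    expect_lt(max(abs(f$beta - b_ols)), 1e-4)
  }
})

test_that("balanced one-way variance components match the ANOVA ML closed form", {
  # intercept-only, g groups of size m: mu = grand mean,
  # sigma2 = SSW/(n-g), sigma2 + m*tau = m/g * sum((ybar_j - ybar)^2)
  for (s in 1:10) {
    set.seed(800 + s)
    g <- 40; m <- 5; n <- g * m
    grp <- factor(rep(1:g, each = m))
    y <- 2 + rep(rnorm(g, 0, 1.5), each = m) + rnorm(n, 0, 0.8)
    d <- data.frame(y = y, therapist_id = grp)
    f <- fit_lmm(build_design(d, model_spec("y")))
    ybar_j <- tapply(y, grp, mean)
    ssw <- sum((y - ybar_j[grp])^2)
    sigma2_ml <- ssw / (n - g)
    psi <- m * sum((ybar_j - mean(y))^2) / g
    tau_ml <- max((psi - sigma2_ml) / m, 0)
    expect_equal(unname(f$beta), mean(y), tolerance = 1e-6)
    expect_equal(f$sigma2, sigma2_ml, tolerance = 1e-4)
    expect_equal(f$tau00, tau_ml, tolerance = 1e-4)
  }
})

test_that("log-likelihood equals direct MVN evaluation on tiny data", {
  for (s in 1:10) {
    set.seed(900 + s)
    d <- sim_client_frame(4, 3, beta = list(x1 = 0.5), tau_sd = 0.7,
                          sigma_sd = 1)          # n = 12
    f <- fit_lmm(build_design(d, model_spec("y", model_term("linear", "x1"))))
    ll <- mvn_loglik_oracle(f$y, f$X, f$beta, f$tau00, f$sigma2,
                            d$therapist_id)
    expect_equal(f$loglik, ll, tolerance = 1e-8)
  }
})

test_that("AIC follows its definition and nesting is monotone", {
  set.seed(31)
  d <- sim_client_frame(30, 2, beta = list(x1 = 0.4), tau_sd = 0.5,
                        sigma_sd = 1, vars = c("x1", "noise"))
  f1 <- fit_lmm(build_design(d, model_spec("y", model_term("linear", "x1"))))
  expect_equal(model_aic(f1), -2 * f1$loglik + 2 * (2 + 2))
  expect_equal(model_aic(f1), f1$aic)
  # adding a pure-noise column cannot reduce the ML log-likelihood
  f2 <- fit_lmm(build_design(d, model_spec("y", list(
    model_term("linear", "x1"), model_term("linear", "noise")))))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_lte(f2$aic, f1$aic + 2 + 1e-6)
  # closed-form Gaussian log-likelihood for the intercept-only no-group case
  set.seed(32)
  d0 <- sim_client_frame(100, 1, tau_sd = 0, sigma_sd = 1, vars = "x1")
  f0 <- fit_lmm(build_design(d0, model_spec("y")))
  v_ml <- mean((d0$y - mean(d0$y))^2)
  ll0 <- -100 / 2 * (log(2 * pi * v_ml) + 1)
  expect_equal(f0$loglik, ll0, tolerance = 1e-6)
})

test_that("marginal R2 and ICC honor their algebraic identities", {
  set.seed(41)
  d <- sim_client_frame(30, 2, beta = list(x1 = 0.6), tau_sd = 0.5,
                        sigma_sd = 0.8)
  f <- fit_lmm(build_design(d, model_spec("y", model_term("linear", "x1"))))
  eta <- drop(f$X %*% f$beta)
  vf <- mean((eta - mean(eta))^2)
  expect_equal(marginal_r2(f), vf / (vf + f$tau00 + f$sigma2),
               tolerance = 1e-12)
  expect_equal(icc(f), f$tau00 / (f$tau00 + f$sigma2), tolerance = 1e-12)
  expect_true(f$r2_marginal >= 0 && f$r2_marginal <= 1)
  expect_true(f$icc >= 0 && f$icc < 1)
  # beta = 0 for all non-intercept terms -> R2m = 0
  d$flat <- 0 * d$x1
  expect_equal(icc_from_components(0, f$sigma2), 0)
  # near-deterministic data -> R2m -> 1
  d2 <- d; d2$y <- 0.5 * d2$x1 + rnorm(nrow(d2), 0, 1e-4)
  f2 <- fit_lmm(build_design(d2, model_spec("y", model_term("linear", "x1"))))
  expect_gt(f2$r2_marginal, 0.999)
})

test_that("inference columns are coherent and invariant to row permutation", {
  set.seed(51)
  d <- sim_client_frame(25, 2, beta = list(x1 = 0.5, x2 = 0), tau_sd = 0.4,
                        sigma_sd = 1)
  sp <- model_spec("y", list(model_term("linear", "x1"),
                             model_term("linear", "x2")))
  f <- fit_lmm(build_design(d, sp))
  co <- f$coefficients
  expect_true(all(co$ci_lower <= co$estimate & co$estimate <= co$ci_upper))
  expect_true(all(co$p_value >= 0 & co$p_value <= 1))
  expect_equal(co$df, rep(nrow(d) - 3 - 1, 3))
  expect_gt(f$sigma2, 0)
  expect_gte(f$tau00, 0)
  perm <- sample(nrow(d))
  fp <- fit_lmm(build_design(d[perm, ], sp))
  expect_equal(fp$beta, f$beta, tolerance = 1e-8)
  expect_equal(fp$loglik, f$loglik, tolerance = 1e-8)
  expect_equal(fp$tau00, f$tau00, tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  set.seed(61)
  d <- sim_client_frame(20, 2, beta = list(x1 = 0.5), tau_sd = 0.4,
                        sigma_sd = 1)
  d$x1dup <- d$x1
  expect_error(fit_lmm(build_design(d, model_spec("y", list(
    model_term("linear", "x1"), model_term("linear", "x1dup"))))),
    "collinear.*x1dup")
  expect_error(fit_lmm(build_design(d[1:4, ], model_spec("y", list(
    model_term("linear", "x1"), model_term("linear", "x1dup"))))),
    "too few")
})

test_that("predictions decompose into fixed and conditional parts", {
  set.seed(71)
  d <- sim_client_frame(20, 3, beta = list(x1 = 0.5), tau_sd = 0.8,
                        sigma_sd = 0.7)
  f <- fit_lmm(build_design(d, model_spec("y", model_term("linear", "x1"))))
  zero_row <- data.frame(x1 = 0, therapist_id = "T001")
  expect_equal(predict(f, zero_row, type = "fixed"),
               unname(f$beta["(Intercept)"]))
  # known vs unknown therapist differ by exactly the BLUP, and the BLUP
  # matches its closed form lambda * sum(resid_j) / (1 + lambda * n_j)
  known <- predict(f, zero_row, type = "conditional")
  expect_equal(known - predict(f, zero_row, type = "fixed"),
               unname(f$blup["T001"]))
  r <- f$y - f$fitted_fixed
  j <- d$therapist_id == "T001"
  expect_equal(unname(f$blup["T001"]),
               f$lambda * sum(r[j]) / (1 + f$lambda * sum(j)),
               tolerance = 1e-10)
  expect_message(
    unk <- predict(f, data.frame(x1 = 0, therapist_id = "NEW"),
                   type = "conditional"), "unknown therapist")
  expect_equal(unk, predict(f, zero_row, type = "fixed"))
  # tau00 = 0 -> both modes identical
  set.seed(72)
  d0 <- sim_client_frame(30, 1, beta = list(x1 = 0.5), tau_sd = 0,
                         sigma_sd = 1)
  f0 <- fit_lmm(build_design(d0, model_spec("y", model_term("linear", "x1"))))
  nd <- data.frame(x1 = c(-1, 2), therapist_id = c("T001", "T002"))
  if (f0$tau00 == 0)
    expect_equal(predict(f0, nd, "conditional"), predict(f0, nd, "fixed"))
})

test_that("residual diagnostics reject degenerate input and flag strong heteroscedasticity", {
  ds <- deterministic_dataset()
  sl <- outcome_slope(ds)
  d <- data.frame(y = sl$slope, therapist_id = ds$clients$therapist_id)
  expect_error(
    residual_diagnostics(structure(list(residuals = rep(0, 20),
                                        fitted = rnorm(20)),
                                   class = "lmm_fit")),
    "constant")
  set.seed(81)
  d2 <- sim_client_frame(100, 2, beta = list(x1 = 1), tau_sd = 0,
                         sigma_sd = 1)
  d2$y <- 1 + 1 * d2$x1 + rnorm(200, 0, 0.2 + 0.5 * abs(1 + d2$x1))
  f2 <- fit_lmm(build_design(d2, model_spec("y", model_term("linear", "x1"))))
  dg <- residual_diagnostics(f2)
  expect_false(dg$heteroscedasticity_pass)
  expect_true(dg$normality_p >= 0 && dg$normality_p <= 1)
  small <- sim_client_frame(3, 2, beta = list(x1 = 0.1), tau_sd = 0.1,
                            sigma_sd = 1)
  fs <- fit_lmm(build_design(small, model_spec("y")))
  expect_error(residual_diagnostics(fs), "fewer than 8")
})

test_that("likelihood correctness holds at fixed parameters on small data", {
  # engine profile likelihood evaluated against the direct MVN density for
  # externally fixed (beta, tau00, sigma2), n <= 12
  set.seed(91)
  d <- sim_client_frame(4, 3, beta = list(x1 = 0.3), tau_sd = 0.5,
                        sigma_sd = 0.9)
  des <- build_design(d, model_spec("y", model_term("linear", "x1")))
  f <- fit_lmm(des)
  for (lam in c(0, 0.3, 1, 2.7)) {
    # recompute the engine's profile quantities at this fixed lambda in R
    grp <- droplevels(des$group)
    Z <- outer(as.integer(grp), seq_len(nlevels(grp)), `==`) * 1
    Vs <- diag(12) + lam * Z %*% t(Z)
    W <- solve(Vs)
    A <- t(des$X) %*% W %*% des$X
    b <- t(des$X) %*% W %*% des$y
    beta <- solve(A, b)
    sig2 <- drop(t(des$y) %*% W %*% des$y - t(b) %*% beta) / 12
    ll_prof <- -0.5 * 12 * log(2 * pi) - 0.5 * 12 * log(sig2) -
      0.5 * determinant(Vs, TRUE)$modulus[1] - 6
    ll_direct <- mvn_loglik_oracle(des$y, des$X, drop(beta),
                                   lam * sig2, sig2, d$therapist_id)
    expect_equal(drop(ll_prof), ll_direct, tolerance = 1e-8)
  }
})
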