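test_that("Real's functional response has its defining properties", {
  expect_equal(real_fr(100, 6.7, 100, 1.9), 6.7 / 2)   # half saturation
  expect_equal(real_fr(123.4, 5, 123.4, 1), 2.5)
  expect_equal(real_fr(1e12, 6.7, 100, 1), 6.7, tolerance = 1e-9)
  expect_equal(real_fr(50, 6.7, 100, 1.284),
               6.7 * 50^1.284 / (100^1.284 + 50^1.284))
  expect_error(real_fr(10, 6.7, -1, 1), "positive")
  expect_error(real_fr(10, 6.7, 100, 0), "positive")
})

test_that("the Poisson GLM intercept has its closed form", {
  mf <- fit_max_feeding(rep(7, 20))
  expect_equal(mf$ln_fmax, log(7))
  mf2 <- fit_max_feeding(c(5, 6, 7, 8))
  expect_equal(mf2$ln_fmax, log(6.5))
  expect_equal(mf2$se, 1 / sqrt(26), tolerance = 1e-6)
  expect_error(fit_max_feeding(c(0, 0, 0)), "zero")
  expect_error(fit_max_feeding(integer(0)))
})

test_that("nb_loglik equals the brute-force probability-mass oracle", {
  d <- data.frame(area_m2 = c(0.04, 0.04, 1, 1, 2.56),
                  refuge_fraction = c(0.1, 0.6, 0.1, 0.6, 0.3),
                  density_per_m2 = c(25, 50, 4, 128, 10),
                  eaten = c(0L, 2L, 1L, 6L, 3L))
  n0s <- scaling_spec(area = TRUE, refuge = TRUE)
  hs <- scaling_spec()
  par <- c(4.2, -0.05, 1.5, 0.2, log(3))
  ll <- nb_loglik(par, d, n0s, hs, ln_fmax = log(6.7))
  # independent evaluation from the written-out pmf
  N0 <- exp(4.2 - 0.05 * log(d$area_m2) + 1.5 * d$refuge_fraction)
  h <- exp(0.2)
  mu <- 6.7 * d$density_per_m2^h / (N0^h + d$density_per_m2^h)
  expect_equal(ll, sum(nb_logpmf_oracle(d$eaten, mu, 3)), tolerance = 1e-10)

  # additivity: a duplicated table doubles the log-likelihood
  d2 <- rbind(d, d)
  expect_equal(nb_loglik(par, d2, n0s, hs, log(6.7)), 2 * ll)

  # k -> infinity recovers the Poisson log-likelihood
  par_inf <- c(4.2, -0.05, 1.5, 0.2, 30)
  expect_equal(nb_loglik(par_inf, d, n0s, hs, log(6.7)),
               sum(dpois(d$eaten, mu, log = TRUE)), tolerance = 1e-4)

  expect_identical(nb_loglik(c(NA, par[-1]), d, n0s, hs, log(6.7)), -Inf)
})

test_that("the scaling-spec admissibility rule is enforced", {
  expect_error(scaling_spec(area = TRUE, refuge = FALSE, interaction = TRUE),
               "interaction")
  expect_error(scaling_spec(area = FALSE, refuge = FALSE, interaction = TRUE))
  s <- scaling_spec(TRUE, TRUE, TRUE)
  expect_equal(n_spec_par(s), 4L)
  expect_equal(n_spec_par(scaling_spec()), 1L)
})

test_that("predictions exponentiate the fitted linear predictors", {
  p <- fr_params(ln_c_n0 = 4.577, b_n0 = 1.777, ln_c_h = 0.25,
                 ln_fmax = 1.902)
  pr <- predict_n0_h(p, 1, 0.35)
  expect_equal(pr$N0, exp(4.577 + 1.777 * 0.35))
  expect_equal(pr$h, exp(0.25))
  # intercept-only model is flat in both covariates
  p0 <- fr_params(ln_c_n0 = 4, ln_c_h = 0.1, ln_fmax = 1.9)
  pr0 <- predict_n0_h(p0, c(0.04, 100), c(0.05, 0.75))
  expect_equal(pr0$N0, rep(exp(4), 2))
  expect_equal(pr0$h, rep(exp(0.1), 2))
  # without interaction terms the prediction is separable in A and R
  pab <- fr_params(ln_c_n0 = 4, a_n0 = -0.3, b_n0 = 1.2, ln_c_h = 0,
                   ln_fmax = 1.9)
  n0 <- function(A, R) predict_n0_h(pab, A, R)$N0
  expect_equal(n0(4, 0.6) * n0(1, 0.1), n0(4, 0.1) * n0(1, 0.6))
})

test_that("the MLE recovers known parameters from synthetic data", {
  truth <- fr_params(ln_c_n0 = 4.6, b_n0 = 1.7, ln_c_h = 0.25,
                     ln_fmax = log(6.7))
  d <- make_synthetic_feeding_table(truth, k = 6, reps = 4, seed = 303)
  fit <- fr_fit(d, scaling_spec(refuge = TRUE), scaling_spec(),
                ln_fmax = log(6.7))
  cf <- coef(fit)
  se <- fit$se
  expect_lt(abs(cf["n0.intercept"] - 4.6) / se["n0.intercept"], 3)
  expect_lt(abs(cf["n0.refuge"] - 1.7) / se["n0.refuge"], 3)
  expect_lt(abs(cf["h.intercept"] - 0.25) / se["h.intercept"], 3)
  expect_lt(abs(cf["ln_k"] - log(6)) / se["ln_k"], 3)
  expect_equal(fit$bic, -2 * fit$logLik + fit$n_par * log(nrow(d)))
})

test_that("refitting in other density units shifts only the intercept", {
  truth <- fr_params(ln_c_n0 = 4.6, b_n0 = 1.7, ln_c_h = 0,
                     ln_fmax = log(6.7))
  d <- make_synthetic_feeding_table(truth, k = 8, reps = 4, seed = 17)
  spec <- scaling_spec(refuge = TRUE)
  f1 <- fr_fit(d, spec, scaling_spec(), log(6.7))
  d2 <- d
  d2$density_per_m2 <- d$density_per_m2 / 1e4   # per cm^2
  f2 <- fr_fit(d2, spec, scaling_spec(), log(6.7))
  expect_equal(coef(f2)["n0.intercept"] - coef(f1)["n0.intercept"],
               c(n0.intercept = -log(1e4)), tolerance = 0.02)
  expect_equal(coef(f2)["n0.refuge"], coef(f1)["n0.refuge"],
               tolerance = 0.02)
  expect_equal(coef(f2)["h.intercept"], coef(f1)["h.intercept"],
               tolerance = 0.02)
})

test_that("the Hill test is a Wald test of ln(C_h) against zero", {
  truth <- fr_params(ln_c_n0 = 4.6, b_n0 = 1.7, ln_c_h = 0.25,
                     ln_fmax = log(6.7))
  d <- make_synthetic_feeding_table(truth, k = 6, reps = 4, seed = 303)
  fit <- fr_fit(d, scaling_spec(refuge = TRUE), scaling_spec(), log(6.7))
  ht <- hill_test(fit)
  expect_equal(ht$h, exp(coef(fit)["h.intercept"]), ignore_attr = TRUE)
  expect_equal(ht$z, ht$ln_c_h / ht$se)
  expect_equal(ht$p_value, 2 * pnorm(-abs(ht$z)))
  expect_error(hill_test(fr_params(ln_c_n0 = 1, ln_fmax = 1)),
               "standard error")
})

test_that("fr_fit model methods are mutually consistent", {
  truth <- fr_params(ln_c_n0 = 4.6, b_n0 = 1.7, ln_c_h = 0.25,
                     ln_fmax = log(6.7))
  d <- make_synthetic_feeding_table(truth, k = 6, reps = 2, seed = 4)
  fit <- fr_fit(d, scaling_spec(refuge = TRUE), scaling_spec(), log(6.7))
  expect_s3_class(fit, "fr_fit")
  expect_equal(unname(BIC(fit)), fit$bic)
  expect_length(fitted(fit), nrow(d))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, d[3:5, ]), fitted(fit)[3:5], ignore_attr = TRUE)
  r <- residuals(fit, type = "response")
  expect_equal(r, d$eaten - fitted(fit))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3L))
  expect_true(all(sims >= 0))
  expect_output(print(summary(fit)), "negative binomial")
})
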