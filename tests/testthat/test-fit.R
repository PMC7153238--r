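test_that("hinge basis is zero at and below its knot", {
  expect_equal(unname(knot_basis(0, knot_pair(0, 6))), cbind(0, 0, 0))
  expect_equal(unname(knot_basis(-10, knot_pair(0, 6))), cbind(-10, 0, 0))
  expect_equal(unname(knot_basis(12, knot_pair(-6, 6))), cbind(12, 18, 6))
  expect_error(knot_pair(6, 6), "tau1")
})

test_that("marginal loglik at sigma_b = 0 equals the independent NB2 sum", {
  cells <- small_cells(small_sim_config(n_states = 4, seed = 3))
  cells <- cells[cells$stdm >= -12 & cells$stdm <= 12, ] # <= 200 cells
  expect_lte(nrow(cells), 200)
  kp <- knot_pair(-6, 6)
  p <- list(beta0 = log(2.5e-4), beta1 = 0.002, gamma1 = 0.02,
            gamma2 = -0.03, dispersion = 0.35, sigma_b = 0)
  expect_lt(abs(nb_glmm_loglik(p, cells, kp) -
                  nb_loglik_oracle(p, cells, kp)), 1e-6)

  one <- cells[1, , drop = FALSE]
  mu <- one$athlete_exposures * exp(p$beta0 + p$beta1 * one$stdm)
  expect_lt(abs(nb_glmm_loglik(p, one, kp) -
                  dnbinom(one$event_count, size = 1 / p$dispersion,
                          mu = mu, log = TRUE)), 1e-9)
})

test_that("the NB2 likelihood approaches the Poisson limit", {
  cells <- small_cells(small_sim_config(n_states = 3, seed = 4))
  cells <- cells[cells$stdm >= -10 & cells$stdm <= 10, ]
  kp <- knot_pair(-6, 6)
  p <- list(beta0 = log(3e-4), beta1 = 0, gamma1 = 0.01, gamma2 = -0.02,
            dispersion = NA, sigma_b = 0)
  mu <- cells$athlete_exposures * exp(p$beta0 + p$gamma1 *
    pmax(0, cells$stdm + 6) + p$gamma2 * pmax(0, cells$stdm - 6))
  pois <- sum(dpois(cells$event_count, mu, log = TRUE))
  gaps <- sapply(c(1e-2, 1e-4, 1e-6), function(a) {
    p$dispersion <- a
    abs(nb_glmm_loglik(p, cells, kp) - pois)
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-3)
})

test_that("loglik is exactly invariant to cell order and state labels", {
  cells <- small_cells(small_sim_config(n_states = 5, seed = 8))
  kp <- knot_pair(-12, 18)
  p <- list(beta0 = log(3e-4), beta1 = 0.001, gamma1 = 0.02,
            gamma2 = -0.04, dispersion = 0.3, sigma_b = 0.25)
  base <- nb_glmm_loglik(p, cells, kp)
  for (seed in 1:3) {
    set.seed(seed)
    shuffled <- cells[sample.int(nrow(cells)), ]
    expect_identical(nb_glmm_loglik(p, shuffled, kp), base)
  }
  relabeled <- cells
  relabeled$state <- setNames(paste0("Z", rev(seq_along(unique(cells$state)))),
                              unique(cells$state))[cells$state]
  expect_identical(nb_glmm_loglik(p, relabeled, kp), base)
})

test_that("quadrature is converged at the default node count", {
  cells <- small_cells(small_sim_config(n_states = 6, seed = 12))
  kp <- knot_pair(-12, 18)
  p <- list(beta0 = log(3e-4), beta1 = 0, gamma1 = 0.03, gamma2 = -0.05,
            dispersion = 0.25, sigma_b = 0.4)
  expect_lt(abs(nb_glmm_loglik(p, cells, kp, nodes = 15) -
                  nb_glmm_loglik(p, cells, kp, nodes = 30)), 1e-4)
})

test_that("maximized fixed-effects loglik matches an IRLS-fitted NB model", {
  skip_if_not_installed("MASS")
  cells <- small_cells(small_sim_config(n_states = 4, seed = 15,
                                        sigma_b = 0))
  cells <- cells[cells$stdm >= -12 & cells$stdm <= 12, ]
  expect_lte(nrow(cells), 200)
  kp <- knot_pair(-6, 6)
  fit <- fit_piecewise_model(cells, kp, random_intercept = FALSE)
  X <- knot_basis(cells$stdm, kp)
  df <- data.frame(y = cells$event_count, stdm = X[, 1], h1 = X[, 2],
                   h2 = X[, 3], off = log(cells$athlete_exposures))
  gnb <- MASS::glm.nb(y ~ stdm + h1 + h2 + offset(off), data = df,
                      control = glm.control(epsilon = 1e-12, maxit = 100))
  expect_lt(abs(fit$loglik - as.numeric(logLik(gnb))), 1e-6)
  expect_equal(unname(fit$coefficients),
               unname(coef(gnb)), tolerance = 1e-4)
})

test_that("flat data recovers null slopes within two standard errors", {
  cfg <- sim_config(n_states = 12, stdm_range = c(-36, 36), beta1 = 0,
                    gamma1 = 0, gamma2 = 0, tau1 = -12, tau2 = 18,
                    seed = 33)
  fit <- fit_piecewise_model(small_cells(cfg), knot_pair(-12, 18))
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coefficients["gamma1"]), 2 * se["gamma1"])
  expect_lt(abs(fit$coefficients["gamma2"]), 2 * se["gamma2"])
})

test_that("rescaling exposures shifts only the intercept, by -log(c)", {
  cells <- small_cells(small_sim_config(n_states = 6, seed = 18))
  kp <- knot_pair(-12, 18)
  f1 <- fit_piecewise_model(cells, kp)
  scaled <- cells
  scaled$athlete_exposures <- scaled$athlete_exposures * 1000
  f2 <- fit_piecewise_model(scaled, kp)
  expect_equal(f2$coefficients["beta0"] - f1$coefficients["beta0"],
               c(beta0 = -log(1000)), tolerance = 1e-5)
  expect_equal(f2$coefficients[2:4], f1$coefficients[2:4], tolerance = 1e-5)
})

test_that("random restarts land on the same maximum", {
  cells <- small_cells(small_sim_config(n_states = 6, seed = 20))
  kp <- knot_pair(-12, 18)
  ref <- fit_piecewise_model(cells, kp)
  set.seed(77)
  for (r in 1:5) {
    s <- ref$par + rnorm(6, 0, 0.5)
    fit <- fit_piecewise_model(cells, kp, start = s)
    expect_true(fit$converged)
    expect_lt(abs(fit$loglik - ref$loglik), 1e-6)
  }
})

test_that("degenerate change points are flagged, invalid cells rejected", {
  cells <- small_cells(small_sim_config(n_states = 4, seed = 25))
  fit <- fit_piecewise_model(cells, knot_pair(29, 30))
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  bad <- cells
  bad$athlete_exposures[3] <- 0
  expect_error(fit_piecewise_model(bad, knot_pair(-12, 18)),
               "athlete_exposures")
  p <- list(beta0 = 700, beta1 = 0, gamma1 = 0, gamma2 = 0,
            dispersion = 0.2, sigma_b = 0.1)
  expect_error(nb_glmm_loglik(p, cells, knot_pair(-12, 18)),
               "linear predictor")
})

test_that("fitted models summarize, predict, simulate and serialize", {
  cells <- small_cells(small_sim_config(n_states = 6, seed = 30))
  kp <- knot_pair(-12, 18)
  fit <- fit_piecewise_model(cells, kp)
  s <- summary(fit)
  expect_s3_class(s, "summary.piecewise_nb")
  expect_identical(nrow(s$slopes), 2L)
  expect_equal(s$slopes$percent_per_stdm[1],
               100 * expm1(fit$coefficients["gamma1"]),
               ignore_attr = TRUE)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)

  pr <- predict(fit, data.frame(stdm = c(-12, 0, 18)), type = "rate")
  expect_true(all(pr > 0))
  expect_identical(length(residuals(fit)), nrow(cells))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(length(sims), 2L)
  expect_identical(nrow(sims[[1]]), nrow(cells))

  td <- withr::local_tempdir()
  path <- file.path(td, "fit.json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$vcov, fit$vcov)
  expect_equal(back$loglik, fit$loglik)
  expect_equal(back$knots$tau1, fit$knots$tau1)
})

test_that("estimates agree with an independent mixed-model fitter", {
  skip_if_not_installed("glmmTMB")
  cells <- small_cells(small_sim_config(n_states = 8, seed = 9))
  kp <- knot_pair(-12, 18)
  fit <- fit_piecewise_model(cells, kp)
  X <- knot_basis(cells$stdm, kp)
  d <- cbind(cells, h1 = X[, "h1"], h2 = X[, "h2"])
  ref <- glmmTMB::glmmTMB(
    event_count ~ stdm + h1 + h2 + (1 | state) +
      offset(log(athlete_exposures)),
    family = glmmTMB::nbinom2, data = d)
  expect_equal(unname(fit$coefficients),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
  expect_equal(unname(fit$sigma_b),
               unname(sqrt(glmmTMB::VarCorr(ref)$cond$state[1])),
               tolerance = 0.01)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(ref)$cond))), tolerance = 1e-2)
  # our quadrature integrates more accurately than the Laplace reference,
  # so the maximized marginal loglik can only be (weakly) larger
  expect_gte(fit$loglik, as.numeric(logLik(ref)) - 1e-4)
})
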