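# minimal converged fit object for transform/comparison unit tests
fake_fit <- function(gamma1 = 0, gamma2 = 0, se1 = 0.005, se2 = 0.005) {
  nm <- c("beta0", "beta1", "gamma1", "gamma2")
  structure(list(
    coefficients = setNames(c(-8, 0, gamma1, gamma2), nm),
    vcov = diag(c(0.1, 0.001, se1, se2)^2) |>
      `dimnames<-`(list(nm, nm)),
    converged = TRUE, degenerate = FALSE,
    knots = knot_pair(-12, 18)
  ), class = "piecewise_nb")
}

test_that("percent transform is the log-link bijection", {
  expect_identical(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100)
  expect_equal(percent_change(-log(2)), -50)
  x <- seq(-0.2, 0.2, by = 0.01)
  expect_equal(percent_to_log(percent_change(x)), x)
  expect_true(all(diff(percent_change(x)) > 0))
})

test_that("Wald slope intervals behave as normal-quantile arithmetic", {
  sc <- slope_wald_ci(0, 0.01)
  expect_equal(sc$p_value, 1)
  expect_equal(percent_to_log(sc$ci_high), -percent_to_log(sc$ci_low))

  # frozen oracle: z = 0.0183/0.00343 = 5.335, CI 0.0183 +/- 1.959964*0.00343
  sc2 <- slope_wald_ci(0.0183, 0.00343)
  expect_lt(sc2$p_value, 0.05)
  expect_gt(sc2$ci_low, 0)
  expect_equal(sc2$percent_per_stdm, 100 * (exp(0.0183) - 1))
  expect_equal(sc2$ci_low, 100 * (exp(0.0183 - qnorm(0.975) * 0.00343) - 1))
  expect_equal(sc2$p_value, 2 * pnorm(-0.0183 / 0.00343))

  wide <- slope_wald_ci(0.01, 0.004, alpha = 0.05)
  narrow <- slope_wald_ci(0.01, 0.004, alpha = 0.10)
  expect_gt(narrow$ci_low, wide$ci_low)
  expect_lt(narrow$ci_high, wide$ci_high)
  expect_error(slope_wald_ci(0.01, 0), "se")
})

test_that("slope comparisons match the two-sample normal statistic", {
  fa <- fake_fit(gamma2 = 0.02)
  fb <- fake_fit(gamma2 = 0)
  cmp <- compare_slopes(fa, fb, "gamma2")
  # frozen: 0.02 / sqrt(2 * 0.005^2) = 2.8284, p = 0.004678
  expect_equal(cmp$statistic, 2.828427, tolerance = 1e-6)
  expect_equal(cmp$p_value, 0.004677735, tolerance = 1e-6)

  same <- compare_slopes(fa, fa, "gamma2")
  expect_equal(same$difference_percent, 0)
  expect_equal(same$p_value, 1)

  rev <- compare_slopes(fb, fa, "gamma2")
  expect_equal(rev$difference_percent, -cmp$difference_percent)
  expect_equal(rev$statistic, -cmp$statistic)
  expect_equal(rev$p_value, cmp$p_value)

  bad <- fa; bad$converged <- FALSE
  expect_error(compare_slopes(bad, fb, "gamma2"), "converged")
})

test_that("bootstrap with the identity resample reproduces the fit", {
  cells <- small_cells(small_sim_config(n_states = 6, seed = 51))
  kp <- knot_pair(-12, 18)
  cb <- cluster_bootstrap(cells, kp, n_boot = 1, seed = 5,
                          resamples = list(unique(cells$state)))
  expect_equal(unname(cb$replicates[1, ]), unname(coef(cb$fit)),
               tolerance = 1e-5)
  expect_identical(cb$n_failed, 0L)
})

test_that("bootstrap SEs track Wald SEs on a well-behaved panel", {
  cfg <- sim_config(n_states = 40, stdm_range = c(-30, 30), seed = 61,
                    sigma_b = 0.1, ae_log_sd = 0.2, ae_log_mean = log(6000))
  sim <- simulate_surveillance(cfg)
  cells <- sim$cells[sim$cells$classification == "incident", ]
  cb <- cluster_bootstrap(cells, knot_pair(-12, 18), n_boot = 120, seed = 3)
  wald <- sqrt(diag(vcov(cb$fit)))
  ratio <- cb$summary$boot_se / wald
  expect_true(all(abs(ratio - 1) < 0.25))
  expect_false(any(cb$summary$flagged))
  expect_lte(cb$n_failed, 6)
})

test_that("an influential state raises the skewness flag", {
  cfg <- sim_config(n_states = 10, stdm_range = c(-30, 30), seed = 62,
                    sigma_b = 0.1, ae_log_sd = 0.2, ae_log_mean = log(4000))
  sim <- simulate_surveillance(cfg)
  cells <- sim$cells[sim$cells$classification == "incident", ]
  set.seed(9)
  big <- cells$state == "AK"
  cells$athlete_exposures[big] <- cells$athlete_exposures[big] * 40
  cells$event_count[big] <- rnbinom(sum(big), size = 4,
    mu = cells$athlete_exposures[big] * 3e-4 *
      exp(0.12 * pmax(0, cells$stdm[big] - 18)))
  states <- unique(cells$state)
  others <- setdiff(states, "AK")
  # balanced resamples plus two dominated by the influential state
  res <- c(lapply(1:12, function(i) c(others, others[(i %% 9) + 1])),
           lapply(1:2, function(i) c(rep("AK", 5), others[1:5])))
  cb <- cluster_bootstrap(cells, knot_pair(-12, 18), n_boot = length(res),
                          seed = 1, resamples = res)
  expect_gt(abs(cb$summary$skewness[cb$summary$coefficient == "gamma2"]), 1)
  expect_true(cb$summary$flagged[cb$summary$coefficient == "gamma2"])
})

test_that("report tables have the stratified shape and consistent stars", {
  sim <- simulate_surveillance(sim_config(n_states = 30,
                                          stdm_range = c(-24, 30),
                                          tau1 = -12, tau2 = 18, seed = 71))
  kp <- knot_pair(-12, 18)
  fits <- run_model_plan(sim$cells, knots = kp)
  expect_identical(length(fits), 14L)
  rep <- report_tables(fits)
  expect_identical(nrow(rep$trends), 14L)   # 7 strata x 2 change points
  expect_identical(length(unique(paste(rep$trends$stratum_variable,
                                       rep$trends$stratum_level))), 7L)
  expect_identical(nrow(rep$comparisons), 12L) # 3 dichotomies x 2 x 2

  # star <=> CI excludes zero
  for (side in c("incident", "recurrent")) {
    lo <- rep$trends[[paste0(side, "_ci_low")]]
    hi <- rep$trends[[paste0(side, "_ci_high")]]
    star <- rep$trends[[paste0(side, "_significant")]]
    ok <- !is.na(star)
    expect_identical(star[ok], (lo > 0 | hi < 0)[ok])
  }

  td <- withr::local_tempdir()
  write_report_csv(rep, td)
  back <- read.csv(file.path(td, "trends.csv"))
  expect_equal(back$incident_percent, rep$trends$incident_percent)
  expect_equal(back$difference_ci_high, rep$trends$difference_ci_high)

  # a missing plan entry yields a warning and NA cells, not a crash
  fits2 <- fits
  fits2[["overall:all:recurrent"]] <- NULL
  expect_warning(rep2 <- report_tables(fits2), "gaps")
  miss <- rep2$trends$stratum_variable == "overall"
  expect_true(all(is.na(rep2$trends$recurrent_percent[miss])))
})

test_that("parametric bootstrap resimulates from the fitted model", {
  cells <- small_cells(small_sim_config(n_states = 6, seed = 52))
  cb <- cluster_bootstrap(cells, knot_pair(-12, 18), n_boot = 10,
                          seed = 2, type = "parametric")
  expect_identical(cb$type, "parametric")
  expect_true(all(is.finite(cb$summary$boot_se)))
  expect_lte(cb$n_failed, 2)
  # replicates genuinely vary
  expect_gt(sd(cb$replicates[, "gamma2"], na.rm = TRUE), 0)
})
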