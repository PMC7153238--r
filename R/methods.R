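# S3 methods for fitted piecewise_nb models

#' @export
print.piecewise_nb <- function(x, ...) {
  cat("Piecewise NB2 mixed model with change points at",
      sprintf("tau1 = %g, tau2 = %g (STDM)\n", x$knots$tau1, x$knots$tau2))
  if (x$degenerate) {
    cat("  degenerate: no data strictly on both sides of each change point\n")
    return(invisible(x))
  }
  cat(sprintf("  %d cells, %d states; log-likelihood %.4f%s\n",
              x$n_cells, x$n_states, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, 6))
  cat(sprintf("  dispersion (NB2 alpha): %.4f   sigma_b: %.4f\n",
              x$dispersion, x$sigma_b))
  invisible(x)
}

#' Summarize a fitted piecewise trend model
#'
#' Reports the fixed effects with Wald standard errors and the slope changes
#' after each change point on the percent-per-STDM scale
#' (\code{100*(exp(gamma)-1)}) with confidence intervals. Intervals are
#' unadjusted for the change-point selection performed by the profile scan
#' and are therefore narrower than they likely should be.
#'
#' @param object a \code{piecewise_nb} fit.
#' @param alpha significance level for the intervals (default 0.05).
#' @param ... unused.
#' @return object of class \code{summary.piecewise_nb}.
#' @export
summary.piecewise_nb <- function(object, alpha = 0.05, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  coefs <- data.frame(
    estimate = object$coefficients,
    se = se,
    z = object$coefficients / se,
    p_value = 2 * pnorm(-abs(object$coefficients / se))
  )
  slopes <- rbind(
    slope_wald_ci(object$coefficients["gamma1"], se["gamma1"], alpha,
                  label = "after_first_change_point"),
    slope_wald_ci(object$coefficients["gamma2"], se["gamma2"], alpha,
                  label = "after_second_change_point")
  )
  structure(list(fit = object, coefficients = coefs, slopes = slopes,
                 alpha = alpha),
            class = "summary.piecewise_nb")
}

#' @export
print.summary.piecewise_nb <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects (log scale):\n")
  print(round(x$coefficients, 6))
  cat(sprintf("\nAdditional rate of change per STDM (%.0f%% Wald CI, %s):\n",
              100 * (1 - x$alpha),
              "unadjusted for change-point selection"))
  print(x$slopes, row.names = FALSE)
  invisible(x)
}

#' @export
coef.piecewise_nb <- function(object, ...) object$coefficients

#' @export
vcov.piecewise_nb <- function(object, ...) object$vcov

#' @export
logLik.piecewise_nb <- function(object, ...) {
  structure(object$loglik,
            df = 4L + 1L + as.integer(object$sigma_b > 0),
            nobs = object$n_cells, class = "logLik")
}

# posterior modes of the state random intercepts at the fitted parameters
ranef_modes <- function(object) {
  d <- prepare_cells(object$cells, object$knots)
  k <- 1 / object$dispersion
  mu0 <- exp(d$off + d$X %*% object$coefficients)
  sig2 <- object$sigma_b^2
  modes <- numeric(length(d$states))
  if (object$sigma_b == 0) return(setNames(modes, d$states))
  for (g in seq_along(d$states)) {
    idx <- (d$group_start[g] + 1L):(d$group_start[g] + d$group_len[g])
    y <- d$y[idx]; m0 <- mu0[idx]
    b <- 0
    for (it in 1:100) {
      v <- m0 * exp(b)
      g1 <- sum((y - v) * k / (k + v)) - b / sig2
      g2 <- -sum((y + k) * k * v / (k + v)^2) - 1 / sig2
      step <- -g1 / g2
      b <- b + max(min(step, 4), -4)
      if (abs(step) < 1e-10) break
    }
    modes[g] <- b
  }
  setNames(modes, d$states)
}

#' @export
residuals.piecewise_nb <- function(object, type = c("pearson", "response"),
                                   ...) {
  type <- match.arg(type)
  d <- prepare_cells(object$cells, object$knots)
  b <- ranef_modes(object)
  mu <- exp(d$off + d$X %*% object$coefficients + b[match(d$cells$state,
                                                          names(b))])
  r <- d$y - mu
  if (type == "pearson") r <- r / sqrt(mu + object$dispersion * mu^2)
  as.numeric(r)
}

#' Predicted rates or counts from a fitted piecewise trend model
#'
#' @param object a \code{piecewise_nb} fit.
#' @param newdata data frame with \code{stdm} (and \code{athlete_exposures}
#'   when \code{type = "count"}); defaults to the fitting cells.
#' @param type \code{"rate"} (events per AE at the population level, random
#'   intercept 0), \code{"count"} (expected events), or \code{"link"} (log
#'   rate).
#' @param ... unused.
#' @export
predict.piecewise_nb <- function(object, newdata = NULL,
                                 type = c("rate", "count", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$cells
  eta <- drop(knot_basis(newdata$stdm, object$knots) %*%
                object$coefficients[2:4]) + object$coefficients[1]
  switch(type,
         link = eta,
         rate = exp(eta),
         count = newdata$athlete_exposures * exp(eta))
}

#' Parametric simulation from a fitted piecewise trend model
#'
#' Draws new state random intercepts and NB2 counts at the fitted
#' parameters, keeping the observed design (states, STDM values and
#' athlete-exposures). Used by the parametric cluster bootstrap.
#'
#' @param object a converged \code{piecewise_nb} fit.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of \code{nsim} cell data frames.
#' @export
simulate.piecewise_nb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cells <- object$cells
  states <- unique(cells$state)
  eta_fix <- log(cells$athlete_exposures) +
    drop(knot_basis(cells$stdm, object$knots) %*%
           object$coefficients[2:4]) + object$coefficients[1]
  lapply(seq_len(nsim), function(i) {
    b <- setNames(rnorm(length(states), 0, object$sigma_b), states)
    mu <- exp(eta_fix + b[cells$state])
    out <- cells
    out$event_count <- rnbinom(nrow(cells), size = 1 / object$dispersion,
                               mu = mu)
    out
  })
}

#' Plot observed and fitted surveillance rates
#'
#' Pooled observed rates (total events over total athlete-exposures per
#' STDM) with the fitted population-level trend and the change points.
#'
#' @param x a \code{piecewise_nb} fit.
#' @param per athlete-exposure multiple for the rate axis (default 10,000).
#' @param ... passed to [graphics::plot()].
#' @export
plot.piecewise_nb <- function(x, per = 1e4, ...) {
  cells <- x$cells
  obs_e <- tapply(cells$event_count, cells$stdm, sum)
  obs_a <- tapply(cells$athlete_exposures, cells$stdm, sum)
  m <- as.integer(names(obs_e))
  graphics::plot(m, per * obs_e / obs_a, pch = 16, col = "grey50",
                 xlab = "standardized month (0 = law passage)",
                 ylab = sprintf("events per %s AE",
                                format(per, big.mark = ",")), ...)
  grid_m <- seq(min(m), max(m), by = 0.5)
  graphics::lines(grid_m, per * predict(x, data.frame(stdm = grid_m),
                                        type = "rate"), lwd = 2)
  graphics::abline(v = c(x$knots$tau1, x$knots$tau2), lty = 3)
  graphics::abline(v = 0, lty = 2, col = "grey70")
  invisible(x)
}

#' Serialize a fitted model to JSON (and back)
#'
#' Writes every scalar component of the fit (coefficients, dispersion,
#' random-intercept SD, log-likelihood, covariance, convergence flags, sizes
#' and change points); the fitting cells are not serialized.
#'
#' @param fit a \code{piecewise_nb} object.
#' @param path JSON path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    coefficients = as.list(fit$coefficients),
    dispersion = fit$dispersion, sigma_b = fit$sigma_b,
    loglik = fit$loglik,
    vcov = unname(as.list(as.data.frame(fit$vcov))),
    converged = fit$converged, degenerate = fit$degenerate,
    n_cells = fit$n_cells, n_states = fit$n_states,
    knots = list(tau1 = fit$knots$tau1, tau2 = fit$knots$tau2)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- c("beta0", "beta1", "gamma1", "gamma2")
  structure(list(
    coefficients = unlist(obj$coefficients)[nm],
    dispersion = obj$dispersion, sigma_b = obj$sigma_b,
    loglik = obj$loglik,
    vcov = matrix(unlist(obj$vcov), 4, 4, dimnames = list(nm, nm)),
    converged = obj$converged, degenerate = obj$degenerate,
    n_cells = obj$n_cells, n_states = obj$n_states,
    knots = knot_pair(obj$knots$tau1, obj$knots$tau2),
    cells = NULL
  ), class = "piecewise_nb")
}
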