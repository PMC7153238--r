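# Piecewise log-linear NB2 mixed model: log(E[count]) = log(AE) + beta0 +
# b_state + beta1*stdm + gamma1*(stdm - tau1)+ + gamma2*(stdm - tau2)+,
# b_state ~ N(0, sigma_b^2), counts NB2 with dispersion alpha
# (variance mu + alpha*mu^2). The state random intercept is integrated out
# by adaptive Gauss-Hermite quadrature (compiled code); all parameters are
# estimated jointly by maximum likelihood.

#' Candidate change-point pair
#'
#' @param tau1,tau2 change points on the STDM axis, \code{tau1 < tau2}.
#' @return object of class \code{knot_pair}.
#' @export
knot_pair <- function(tau1, tau2) {
  if (!is.numeric(tau1) || !is.numeric(tau2) || tau1 >= tau2)
    stop("knot_pair: tau1 must be strictly less than tau2")
  structure(list(tau1 = tau1, tau2 = tau2), class = "knot_pair")
}

#' @export
print.knot_pair <- function(x, ...) {
  cat(sprintf("change points: tau1 = %g, tau2 = %g (STDM)\n", x$tau1, x$tau2))
  invisible(x)
}

#' Truncated-line basis for the piecewise trend
#'
#' Returns the three trend covariates at each STDM value: the month itself
#' and the two hinge terms \code{(stdm - tau1)+} and \code{(stdm - tau2)+},
#' which are zero at and below their knot so the fitted log-rate is
#' continuous with slope breaks only.
#'
#' @param stdm integer vector of standardized months.
#' @param knots a [knot_pair()].
#' @return numeric matrix with columns \code{stdm, h1, h2}.
#' @examples
#' knot_basis(c(-10, 0, 12), knot_pair(-6, 6))
#' @export
knot_basis <- function(stdm, knots) {
  stopifnot(inherits(knots, "knot_pair"))
  cbind(stdm = stdm,
        h1 = pmax(0, stdm - knots$tau1),
        h2 = pmax(0, stdm - knots$tau2))
}

#' Fitting control parameters
#'
#' @param quadrature_nodes Gauss-Hermite node count for the random-intercept
#'   integral (1 = Laplace approximation).
#' @param max_iter optimizer iteration cap.
#' @param tol relative convergence tolerance passed to [stats::nlminb()].
#' @param n_restarts jittered restarts attempted if the first optimization
#'   does not converge.
#' @param seed seed for restart jitter.
#' @return a list of class \code{fit_control}.
#' @export
fit_control <- function(quadrature_nodes = 15L, max_iter = 500L,
                        tol = 1e-12, n_restarts = 2L, seed = 1L) {
  stopifnot(quadrature_nodes >= 1, max_iter >= 1, tol > 0, n_restarts >= 0)
  structure(list(quadrature_nodes = as.integer(quadrature_nodes),
                 max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "fit_control")
}

# canonicalize cells for the likelihood: validate, sort deterministically,
# and precompute the design pieces the compiled code needs
prepare_cells <- function(cells, knots) {
  req <- c("state", "stdm", "event_count", "athlete_exposures")
  check_columns(cells, req, "analysis cells")
  if (any(!is.finite(cells$athlete_exposures) | cells$athlete_exposures <= 0))
    stop("all cells entering a model must have athlete_exposures > 0")
  if (any(cells$event_count < 0) ||
      any(cells$event_count != round(cells$event_count)))
    stop("event_count must be non-negative integers")
  ord <- order(cells$state, cells$stdm, cells$event_count,
               cells$athlete_exposures)
  cells <- cells[ord, , drop = FALSE]
  states <- unique(cells$state)
  gidx <- match(cells$state, states)
  len <- tabulate(gidx, length(states))
  start <- cumsum(c(0L, len[-length(len)]))
  list(cells = cells,
       y = as.integer(cells$event_count),
       off = log(cells$athlete_exposures),
       X = cbind(intercept = 1, knot_basis(cells$stdm, knots)),
       group_start = as.integer(start),
       group_len = as.integer(len),
       states = states)
}

#' Marginal log-likelihood of the piecewise NB2 mixed model
#'
#' Evaluates the state-random-intercept marginal log-likelihood at given
#' parameter values, integrating each state's intercept by adaptive
#' Gauss-Hermite quadrature centred and scaled at the mode of the integrand.
#' With \code{sigma_b = 0} this reduces exactly to the sum of independent
#' NB2 log-likelihood terms.
#'
#' @param params named list or vector with \code{beta0, beta1, gamma1,
#'   gamma2, dispersion, sigma_b}.
#' @param cells analysis-cell data frame (one injury classification).
#' @param knots a [knot_pair()].
#' @param nodes quadrature node count (default 15).
#' @return the marginal log-likelihood (scalar).
#' @export
nb_glmm_loglik <- function(params, cells, knots, nodes = 15L) {
  p <- as.list(params)
  for (nm in c("beta0", "beta1", "gamma1", "gamma2", "dispersion", "sigma_b"))
    if (is.null(p[[nm]]) || !is.finite(p[[nm]]))
      stop("params must contain finite '", nm, "'")
  if (p$dispersion <= 0) stop("dispersion must be > 0")
  if (p$sigma_b < 0) stop("sigma_b must be >= 0")
  d <- prepare_cells(cells, knots)
  beta <- c(p$beta0, p$beta1, p$gamma1, p$gamma2)
  eta <- d$off + d$X %*% beta
  if (any(!is.finite(eta)) || any(eta > 600)) {
    i <- which(!is.finite(eta) | eta > 600)[1]
    stop(sprintf("non-finite linear predictor at cell %d (state %s, stdm %d)",
                 i, d$cells$state[i], d$cells$stdm[i]))
  }
  gh <- gauss_hermite(nodes)
  nbglmm_loglik_cpp(beta, p$dispersion, p$sigma_b, d$y, d$off, d$X,
                    d$group_start, d$group_len, gh$nodes, log(gh$weights))
}

# negative log-likelihood and its exact gradient over the working
# parameterization par = (beta0, beta1, gamma1, gamma2, log_alpha,
# [log_sigma]); value and gradient come from one compiled evaluation,
# memoized because nlminb asks for them separately
make_objfns <- function(d, gh, random_intercept) {
  logw <- log(gh$weights)
  last <- NULL
  fg <- function(par) {
    if (!is.null(last) && identical(par, last$par)) return(last)
    r <- nbglmm_nll_grad_cpp(par[1:4], par[5],
                             if (random_intercept) par[6] else 0,
                             random_intercept, d$y, d$off, d$X,
                             d$group_start, d$group_len, gh$nodes, logw)
    out <- if (!is.finite(r$value) || any(!is.finite(r$grad))) {
      list(par = par, value = 1e10, grad = rep(0, length(par)))
    } else list(par = par, value = -r$value, grad = -r$grad)
    last <<- out
    out
  }
  # Hessians by differencing the analytic score: a cheap forward-difference
  # version for the optimizer's Newton model, a central-difference version
  # for the reported covariance
  hess_fwd <- function(par) {
    p <- length(par)
    g0 <- fg(par)$grad
    H <- matrix(0, p, p)
    for (j in seq_len(p)) {
      h <- 1e-6 * max(1, abs(par[j]))
      up <- par; up[j] <- up[j] + h
      H[, j] <- (fg(up)$grad - g0) / h
    }
    (H + t(H)) / 2
  }
  hess <- function(par) {
    p <- length(par)
    H <- matrix(0, p, p)
    for (j in seq_len(p)) {
      h <- 1e-5 * max(1, abs(par[j]))
      up <- par; up[j] <- up[j] + h
      dn <- par; dn[j] <- dn[j] - h
      H[, j] <- (fg(up)$grad - fg(dn)$grad) / (2 * h)
    }
    (H + t(H)) / 2
  }
  list(fn = function(par) fg(par)$value,
       gr = function(par) fg(par)$grad,
       hess_fwd = hess_fwd, hess = hess)
}

# moment-style starting values from a fixed-effects Poisson fit
starting_values <- function(d) {
  fe <- tryCatch(
    glm.fit(d$X, d$y, offset = d$off, family = poisson()),
    error = function(e) NULL)
  if (is.null(fe) || !fe$converged || any(!is.finite(coef(fe)))) {
    beta <- c(log(max(sum(d$y), 1) / sum(exp(d$off))), 0, 0, 0)
  } else beta <- coef(fe)
  mu <- exp(d$off + d$X %*% beta)
  alpha <- mean((d$y - mu)^2 / mu^2 - 1 / mu)
  alpha <- min(max(alpha, 1e-3), 10)
  c(beta, log(alpha), log(0.1))
}

#' Fit the piecewise NB2 mixed model at fixed change points
#'
#' Maximizes the marginal likelihood over the intercept, the three trend
#' slopes, the NB2 dispersion and the random-intercept SD, starting from a
#' fixed-effects Poisson fit. The covariance of the fixed effects is the
#' corresponding block of the inverse observed information (numerical
#' Hessian at the optimum). If no cell lies strictly beyond (or before) a
#' knot the two hinge slopes are not identifiable and the fit is returned
#' flagged \code{degenerate} instead of erroring, so grid scans can skip it.
#'
#' @param cells analysis-cell data frame for one injury classification:
#'   columns \code{state, stdm, event_count, athlete_exposures}.
#' @param knots a [knot_pair()].
#' @param control a [fit_control()].
#' @param start optional numeric(6) warm start \code{(beta0, beta1, gamma1,
#'   gamma2, log dispersion, log sigma_b)}.
#' @param random_intercept set \code{FALSE} to fix \code{sigma_b = 0} and
#'   fit the fixed-effects NB2 model.
#' @param compute_vcov set \code{FALSE} to skip the observed-information
#'   covariance (used by grid scans, where only the log-likelihood matters).
#' @return an object of class \code{piecewise_nb}; see
#'   [summary.piecewise_nb()].
#' @examples
#' sim <- simulate_surveillance(sim_config(n_states = 6,
#'   stdm_range = c(-18, 18), tau1 = -6, tau2 = 6,
#'   ae_log_mean = log(2000), seed = 42))
#' cells <- sim$cells[sim$cells$classification == "incident", ]
#' fit <- fit_piecewise_model(cells, knot_pair(-6, 6))
#' coef(fit)
#' @export
fit_piecewise_model <- function(cells, knots, control = fit_control(),
                                start = NULL, random_intercept = TRUE,
                                compute_vcov = TRUE) {
  stopifnot(inherits(knots, "knot_pair"), inherits(control, "fit_control"))
  d <- prepare_cells(cells, knots)
  if (length(d$states) < 2L && random_intercept)
    stop("at least 2 states are required to fit a state random intercept")

  degenerate <- !(any(d$cells$stdm < knots$tau1) &&
                    any(d$cells$stdm > knots$tau1) &&
                    any(d$cells$stdm < knots$tau2) &&
                    any(d$cells$stdm > knots$tau2))
  template <- structure(list(
    coefficients = setNames(rep(NA_real_, 4),
                            c("beta0", "beta1", "gamma1", "gamma2")),
    dispersion = NA_real_, sigma_b = NA_real_, loglik = NA_real_,
    vcov = matrix(NA_real_, 4, 4,
                  dimnames = rep(list(c("beta0", "beta1", "gamma1",
                                        "gamma2")), 2)),
    converged = FALSE, degenerate = degenerate,
    n_cells = nrow(d$cells), n_states = length(d$states),
    knots = knots, control = control, random_intercept = random_intercept,
    par = NULL, cells = d$cells
  ), class = "piecewise_nb")
  if (degenerate) return(template)

  gh <- gauss_hermite(control$quadrature_nodes)
  obj <- make_objfns(d, gh, random_intercept)
  np <- if (random_intercept) 6L else 5L
  lower <- c(rep(-Inf, 4), -14, -10)[seq_len(np)]
  upper <- c(rep(Inf, 4), 6, 3)[seq_len(np)]
  s0 <- if (is.null(start)) starting_values(d) else start
  s0 <- pmin(pmax(s0[seq_len(np)], lower + 1e-6), upper - 1e-6)

  run <- function(s) {
    nlminb(s, obj$fn, gradient = obj$gr, hessian = obj$hess_fwd,
           lower = lower, upper = upper,
           control = list(rel.tol = control$tol,
                          iter.max = control$max_iter,
                          eval.max = 4L * control$max_iter))
  }
  opt <- run(s0)
  if (opt$convergence != 0 && control$n_restarts > 0) {
    # jittered restarts must not disturb the caller's RNG stream
    old_seed <- if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    for (r in seq_len(control$n_restarts)) {
      set.seed(control$seed + r)
      opt2 <- run(s0 + rnorm(np, 0, 0.3))
      if (opt2$objective < opt$objective ||
          (opt2$convergence == 0 && opt$convergence != 0)) opt <- opt2
      if (opt$convergence == 0) break
    }
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }

  par <- opt$par
  fit <- template
  fit$coefficients[] <- par[1:4]
  fit$dispersion <- exp(par[5])
  fit$sigma_b <- if (random_intercept) {
    if (par[6] <= lower[6] + 1e-6) 0 else exp(par[6])
  } else 0
  fit$loglik <- -opt$objective
  # PORT reports 'singular convergence' at flat or boundary optima; accept
  # any point whose free-parameter score is numerically zero
  converged <- opt$convergence == 0 && is.finite(opt$objective)
  if (!converged && is.finite(opt$objective)) {
    g <- obj$gr(par)
    interior <- par > lower + 1e-6 & par < upper - 1e-6
    converged <- max(abs(g[interior]), 0) < 1e-2
  }
  fit$converged <- converged
  fit$par <- par
  if (compute_vcov)
    fit$vcov <- fixed_effect_vcov(obj$hess, par, lower, upper)
  fit$opt <- list(convergence = opt$convergence, message = opt$message,
                  iterations = opt$iterations)
  fit
}

# inverse observed information, fixed-effects block: Jacobian of the
# analytic score at the optimum; parameters at a box bound are held fixed
# when differentiating
fixed_effect_vcov <- function(hess, par, lower, upper) {
  at_bound <- par <= lower + 1e-6 | par >= upper - 1e-6
  free <- which(!at_bound | seq_along(par) <= 4)
  V4 <- matrix(NA_real_, 4, 4)
  H <- tryCatch(hess(par)[free, free, drop = FALSE],
                error = function(e) NULL)
  if (!is.null(H)) {
    H <- (H + t(H)) / 2
    Vi <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Vi)) { # ridge fallback for near-singular information
      e <- eigen(H, symmetric = TRUE)
      vals <- pmax(e$values, max(abs(e$values)) * 1e-10)
      Vi <- e$vectors %*% (t(e$vectors) / vals)
    }
    k <- match(1:4, free)
    V4 <- Vi[k, k]
    V4 <- (V4 + t(V4)) / 2
  }
  dimnames(V4) <- rep(list(c("beta0", "beta1", "gamma1", "gamma2")), 2)
  V4
}
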