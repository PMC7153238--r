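# Exhaustive profile-likelihood scan for the two change points over a
# six-month grid: refit the full model (all nuisance parameters
# re-estimated) at every admissible ordered knot pair and keep the pair with
# the largest log-likelihood.

#' Enumerate the candidate change-point grid
#'
#' Grid points are every multiple of \code{step} inside
#' \code{[stdm_min, stdm_max]} (anchored at STDM 0, the law-passage month);
#' candidates are all ordered pairs \code{tau1 < tau2}, so \code{m} grid
#' points give \code{choose(m, 2)} pairs. The observed incident range
#' -96..+108 with the default six-month step gives 35 points and 595 pairs.
#'
#' @param stdm_min,stdm_max inclusive STDM range of the observed data.
#' @param step grid increment in months (default 6).
#' @return data frame of class \code{knot_grid} with columns \code{tau1,
#'   tau2}.
#' @examples
#' nrow(enumerate_knot_grid(-96, 108))  # 595
#' @export
enumerate_knot_grid <- function(stdm_min, stdm_max, step = 6L) {
  if (stdm_min >= stdm_max) stop("stdm_min must be < stdm_max")
  if (step <= 0) stop("step must be > 0")
  pts <- seq.int(ceiling(stdm_min / step) * step,
                 floor(stdm_max / step) * step, by = step)
  if (length(pts) < 2L)
    stop("fewer than 2 grid points in the STDM range; widen the range")
  idx <- which(upper.tri(diag(length(pts))), arr.ind = TRUE)
  grid <- data.frame(tau1 = pts[idx[, "row"]], tau2 = pts[idx[, "col"]])
  grid <- grid[order(grid$tau1, grid$tau2), ]
  rownames(grid) <- NULL
  class(grid) <- c("knot_grid", "data.frame")
  grid
}

#' Profile-likelihood search for the change points
#'
#' Fits the piecewise NB2 mixed model at every pair in \code{grid},
#' re-estimating all other parameters each time (full profile likelihood),
#' and selects the pair with the largest converged log-likelihood; exact
#' ties (within \code{1e-6}) are broken toward the smallest \code{tau1},
#' then \code{tau2}. Pairs with no data strictly on both sides of each knot
#' are recorded as ineligible rather than fitted. Consecutive fits are
#' warm-started from the last converged parameter vector; the final
#' inference model is refit from cold at the selected pair.
#'
#' @param cells analysis-cell data frame for one injury classification.
#' @param grid a [enumerate_knot_grid()] result (or any data frame with
#'   \code{tau1, tau2}).
#' @param control a [fit_control()].
#' @return object of class \code{profile_surface}: \code{surface} (one row
#'   per pair: \code{tau1, tau2, loglik, converged, eligible}), \code{best}
#'   (a [knot_pair()]), \code{best_loglik}, and \code{fit} (the refit at the
#'   best pair).
#' @export
profile_search <- function(cells, grid, control = fit_control()) {
  if (!nrow(grid)) stop("empty change-point grid")
  surface <- data.frame(tau1 = grid$tau1, tau2 = grid$tau2,
                        loglik = NA_real_, converged = FALSE,
                        eligible = TRUE, reason = "")
  warm <- NULL
  for (i in seq_len(nrow(grid))) {
    kp <- knot_pair(grid$tau1[i], grid$tau2[i])
    fit <- fit_piecewise_model(cells, kp, control, start = warm,
                               compute_vcov = FALSE)
    if (fit$degenerate) {
      surface$eligible[i] <- FALSE
      surface$reason[i] <- "no data beyond a change point"
      next
    }
    surface$loglik[i] <- fit$loglik
    surface$converged[i] <- fit$converged
    if (!fit$converged) surface$reason[i] <- "optimizer did not converge"
    if (fit$converged) warm <- fit$par
  }
  cand <- select_best_pair(surface)
  best <- knot_pair(surface$tau1[cand], surface$tau2[cand])
  fit <- fit_piecewise_model(cells, best, control)
  structure(list(surface = surface, best = best,
                 best_loglik = surface$loglik[cand], fit = fit,
                 n_ineligible = sum(!surface$eligible),
                 n_nonconverged = sum(surface$eligible & !surface$converged)),
            class = "profile_surface")
}

# row index of the winning pair: largest converged log-likelihood, ties
# within tol broken toward the smallest tau1, then tau2
select_best_pair <- function(surface, tol = 1e-6) {
  ok <- surface$eligible & surface$converged
  if (!any(ok)) stop("no eligible converged change-point pair in the grid")
  best_ll <- max(surface$loglik[ok])
  cand <- which(ok & surface$loglik >= best_ll - tol)
  cand[order(surface$tau1[cand], surface$tau2[cand])][1]
}

#' @export
print.profile_surface <- function(x, ...) {
  cat(sprintf("Profile-likelihood scan over %d change-point pairs\n",
              nrow(x$surface)))
  cat(sprintf("  best: tau1 = %g, tau2 = %g  (loglik %.4f)\n",
              x$best$tau1, x$best$tau2, x$best_loglik))
  if (x$n_ineligible || x$n_nonconverged)
    cat(sprintf("  skipped: %d ineligible, %d non-converged\n",
                x$n_ineligible, x$n_nonconverged))
  invisible(x)
}

#' Heatmap of the profile-likelihood surface
#'
#' @param x a \code{profile_surface}.
#' @param ... passed to [graphics::image()].
#' @export
plot.profile_surface <- function(x, ...) {
  s <- x$surface
  t1 <- sort(unique(s$tau1)); t2 <- sort(unique(s$tau2))
  z <- matrix(NA_real_, length(t1), length(t2))
  z[cbind(match(s$tau1, t1), match(s$tau2, t2))] <- s$loglik
  graphics::image(t1, t2, z, xlab = expression(tau[1]),
                  ylab = expression(tau[2]),
                  main = "profile log-likelihood", ...)
  graphics::points(x$best$tau1, x$best$tau2, pch = 4, cex = 1.5, lwd = 2)
  invisible(x)
}

#' Write a profile surface to CSV
#'
#' @param surface a \code{profile_surface}.
#' @param path CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  write.csv(surface$surface[, c("tau1", "tau2", "loglik", "converged")],
            path, row.names = FALSE)
  invisible(path)
}
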