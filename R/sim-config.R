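#' Configuration for the synthetic surveillance-data generator
#'
#' Bundles and validates every parameter of the generative model used by
#' [simulate_surveillance()] and [simulate_raw_records()]: a piecewise
#' log-linear event rate per athlete-exposure (AE) with two change points on
#' the standardized-month (STDM) axis, NB2 overdispersion, a normal state
#' random intercept, lognormal AE denominators, an incident/recurrent split,
#' and per-field missingness for testing the exclusion filters.
#'
#' The expected count in a state-month cell is
#' \deqn{AE \cdot \exp(\beta_0 + b + \beta_1 m + \gamma_1 (m-\tau_1)_+ +
#'   \gamma_2 (m-\tau_2)_+), \quad b \sim N(0, \sigma_b^2),}
#' with counts drawn NB2 (variance \eqn{\mu + \alpha\mu^2}). The defaults
#' mirror a national high-school panel: 49 reporting jurisdictions, an STDM
#' window of -96..+108 months around law passage, passage years 2009-2014
#' with the observed staggering, a baseline rate of 3 events per 10,000 AE,
#' and a 9.1% recurrent share.
#'
#' @param n_states number of states (positive integer).
#' @param stdm_range integer pair, inclusive STDM window (months; negative =
#'   pre-law).
#' @param passage_year_weights named numeric vector of probabilities by
#'   passage year; default is the observed 2009-2014 distribution of state
#'   law passages (2/51, 8/51, 27/51, 7/51, 6/51, 1/51).
#' @param beta0 baseline log-rate (log events per AE).
#' @param beta1 log-linear slope per STDM before the first change point.
#' @param gamma1,gamma2 additional log-slopes after \code{tau1}, \code{tau2}.
#' @param tau1,tau2 true change points (STDM months, \code{tau1 < tau2}).
#' @param dispersion NB2 overdispersion \eqn{\alpha > 0}.
#' @param sigma_b state random-intercept SD (>= 0).
#' @param ae_log_mean,ae_log_sd lognormal parameters of the per-cell AE draw.
#' @param recurrent_fraction probability an event is recurrent.
#' @param missingness_rates named list of per-field corruption probabilities
#'   for [simulate_raw_records()]; recognised names: \code{injury_date},
#'   \code{state}, \code{classification}, \code{ae_link},
#'   \code{injury_type_unknown}, \code{injury_type_other},
#'   \code{recurrent_nonsport}. Unlisted fields default to 0.
#' @param seed integer RNG seed; identical configs give byte-identical data.
#' @return an object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_states = 10, stdm_range = c(-24, 24), seed = 7)
#' cfg$tau1
#' @export
sim_config <- function(n_states = 49L,
                       stdm_range = c(-96L, 108L),
                       passage_year_weights = c(
                         "2009" = 2, "2010" = 8, "2011" = 27,
                         "2012" = 7, "2013" = 6, "2014" = 1) / 51,
                       beta0 = log(3e-4),
                       beta1 = 0,
                       gamma1 = 0.03,
                       gamma2 = -0.05,
                       tau1 = -12L,
                       tau2 = 18L,
                       dispersion = 0.25,
                       sigma_b = 0.25,
                       ae_log_mean = log(8000),
                       ae_log_sd = 0.5,
                       recurrent_fraction = 0.091,
                       missingness_rates = list(),
                       seed = 1L) {
  if (!is.numeric(n_states) || length(n_states) != 1L || n_states < 1 ||
      n_states != round(n_states))
    stop_field("n_states", "must be a positive integer")
  if (!is.numeric(stdm_range) || length(stdm_range) != 2L ||
      stdm_range[1] >= stdm_range[2])
    stop_field("stdm_range", "must be an increasing pair of months")
  if (!is.numeric(passage_year_weights) || any(passage_year_weights < 0) ||
      is.null(names(passage_year_weights)) ||
      abs(sum(passage_year_weights) - 1) > 1e-8)
    stop_field("passage_year_weights",
               "must be named non-negative probabilities summing to 1")
  for (f in c("beta0", "beta1", "gamma1", "gamma2")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_field(f, "must be a finite number")
  }
  if (!is.numeric(tau1) || !is.numeric(tau2) || tau1 >= tau2)
    stop_field("tau1", "must satisfy tau1 < tau2")
  if (tau1 < stdm_range[1] || tau2 > stdm_range[2])
    stop_field("tau2", "change points must lie within stdm_range")
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop_field("dispersion", "must be > 0")
  if (!is.numeric(sigma_b) || sigma_b < 0)
    stop_field("sigma_b", "must be >= 0")
  if (!is.numeric(ae_log_sd) || ae_log_sd < 0)
    stop_field("ae_log_sd", "must be >= 0")
  if (!is.numeric(recurrent_fraction) || recurrent_fraction < 0 ||
      recurrent_fraction > 1)
    stop_field("recurrent_fraction", "must be in [0, 1]")
  known <- c("injury_date", "state", "classification", "ae_link",
             "injury_type_unknown", "injury_type_other",
             "recurrent_nonsport")
  if (!is.list(missingness_rates) ||
      (length(missingness_rates) && (is.null(names(missingness_rates)) ||
       !all(names(missingness_rates) %in% known))))
    stop_field("missingness_rates",
               paste("must be a named list with names among:",
                     paste(known, collapse = ", ")))
  mr <- as.list(setNames(rep(0, length(known)), known))
  for (nm in names(missingness_rates)) {
    v <- missingness_rates[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_field("missingness_rates", sprintf("'%s' must be in [0, 1]", nm))
    mr[[nm]] <- v
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop_field("seed", "must be an integer")

  structure(list(
    n_states = as.integer(n_states),
    stdm_range = as.integer(round(stdm_range)),
    passage_year_weights = passage_year_weights,
    beta0 = beta0, beta1 = beta1, gamma1 = gamma1, gamma2 = gamma2,
    tau1 = tau1, tau2 = tau2,
    dispersion = dispersion, sigma_b = sigma_b,
    ae_log_mean = ae_log_mean, ae_log_sd = ae_log_sd,
    recurrent_fraction = recurrent_fraction,
    missingness_rates = mr,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read a generator configuration from a YAML file
#'
#' @param path path to a YAML file whose keys are [sim_config()] arguments.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$passage_year_weights))
    vals$passage_year_weights <- unlist(vals$passage_year_weights)
  if (!is.null(vals$stdm_range)) vals$stdm_range <- unlist(vals$stdm_range)
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic surveillance generator config\n")
  cat(sprintf("  states: %d   STDM window: %d..%d   seed: %d\n",
              x$n_states, x$stdm_range[1], x$stdm_range[2], x$seed))
  cat(sprintf("  rate: exp(%.4g %+.4g*m %+.4g*(m-%d)+ %+.4g*(m-%d)+)\n",
              x$beta0, x$beta1, x$gamma1, x$tau1, x$gamma2, x$tau2))
  cat(sprintf("  dispersion: %.3g   sigma_b: %.3g   recurrent: %.3f\n",
              x$dispersion, x$sigma_b, x$recurrent_fraction))
  invisible(x)
}
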