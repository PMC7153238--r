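# Synthetic surveillance data with known piecewise rate structure.
# Everything downstream (ingest, alignment, fitting, the profile scan and the
# inference layer) is exercised against these generators, since the real
# national surveillance data is restricted-access.

# Observed marginal proportions of the 51 jurisdictions by law language,
# used to label simulated states: 27/51 specify the RTP provider; 7 of those
# 27 are physicians-only; 40/51 require education of both coaches and
# parents/guardians.
.law_language_probs <- list(specified = 27 / 51,
                            physicians_only = 7 / 27,
                            education_both = 40 / 51)

draw_laws <- function(states, config) {
  yrs <- as.integer(names(config$passage_year_weights))
  year <- sample(yrs, length(states), replace = TRUE,
                 prob = config$passage_year_weights)
  month <- sample.int(12L, length(states), replace = TRUE)
  passage <- as.Date(sprintf("%d-%02d-01", year, month))
  specified <- runif(length(states)) < .law_language_probs$specified
  phys <- runif(length(states)) < .law_language_probs$physicians_only
  both <- runif(length(states)) < .law_language_probs$education_both
  data.frame(
    state = states,
    passage_date = passage,
    rtp_provider = ifelse(specified, "specified", "not_specified"),
    provider_breadth = ifelse(specified,
                              ifelse(phys, "physicians_only", "multiple"),
                              "not_applicable"),
    education = ifelse(both, "both", "either"),
    stringsAsFactors = FALSE
  )
}

piecewise_lograte <- function(m, config) {
  config$beta0 + config$beta1 * m +
    config$gamma1 * pmax(0, m - config$tau1) +
    config$gamma2 * pmax(0, m - config$tau2)
}

#' Simulate an aggregated state-by-month surveillance panel
#'
#' Draws, for each simulated state, a law-passage date (staggered across
#' years per the config weights), a normal random intercept, and for every
#' standardized month (STDM) in the configured window a lognormal
#' athlete-exposure denominator and an NB2 event count whose mean follows the
#' piecewise log-linear rate with change points \code{tau1 < tau2}. Events
#' are split into incident and recurrent by independent binomial thinning,
#' which preserves the NB2 dispersion within each classification.
#'
#' @param config a [sim_config()].
#' @return a list of class \code{lawbend_sim} with elements \code{cells}
#'   (data frame: state, stdm, classification, event_count,
#'   athlete_exposures, rtp_group, breadth_group, education_group) and
#'   \code{laws} (one law record per state).
#' @examples
#' sim <- simulate_surveillance(sim_config(n_states = 4,
#'   stdm_range = c(-12, 12), tau1 = -6, tau2 = 6, seed = 1))
#' head(sim$cells)
#' @export
simulate_surveillance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  states <- sim_state_codes(config$n_states)
  laws <- draw_laws(states, config)
  b <- rnorm(config$n_states, 0, config$sigma_b)
  m <- seq.int(config$stdm_range[1], config$stdm_range[2])
  lograte <- piecewise_lograte(m, config)

  per_state <- vector("list", config$n_states)
  for (s in seq_len(config$n_states)) {
    ae <- rlnorm(length(m), config$ae_log_mean, config$ae_log_sd)
    mu <- ae * exp(lograte + b[s])
    total <- rnbinom(length(m), size = 1 / config$dispersion, mu = mu)
    recur <- rbinom(length(m), total, config$recurrent_fraction)
    per_state[[s]] <- data.frame(
      state = states[s],
      stdm = rep(m, 2L),
      classification = rep(c("incident", "recurrent"), each = length(m)),
      event_count = c(total - recur, recur),
      athlete_exposures = rep(ae, 2L),
      stringsAsFactors = FALSE
    )
  }
  cells <- do.call(rbind, per_state)
  rownames(cells) <- NULL
  groups <- classify_states(laws)
  cells <- merge(cells, groups, by = "state", sort = FALSE)
  cells <- cells[order(cells$state, cells$stdm, cells$classification), ]
  rownames(cells) <- NULL
  structure(list(cells = cells, laws = laws, config = config),
            class = "lawbend_sim")
}

#' @export
print.lawbend_sim <- function(x, ...) {
  cat(sprintf("Simulated surveillance panel: %d states, STDM %d..%d, %d cells\n",
              x$config$n_states, x$config$stdm_range[1],
              x$config$stdm_range[2], nrow(x$cells)))
  invisible(x)
}

# first Monday of August: the default week-1 anchor of an academic year
first_monday_august <- function(year) {
  d <- as.Date(sprintf("%d-08-01", year))
  wd <- as.POSIXlt(d)$wday # 0 = Sunday
  d + (8L - wd) %% 7L
}

#' Simulate event-level and weekly-exposure surveillance records
#'
#' Produces the raw-record counterpart of [simulate_surveillance()]: weekly
#' athlete-exposure rows (exposure weeks 1-52 per academic year, 2005/06
#' through 2017/18) and one row per concussion event with calendar injury
#' date, incident/recurrent classification, injury type and recurrence
#' mechanism. Per-field corruption is injected independently at the
#' configured \code{missingness_rates} so the exclusion filters can be tested
#' against known truth: the returned events carry a logical column
#' \code{expected_excluded} flagging every record the generator corrupted
#' into one of the exclusion categories.
#'
#' @param config a [sim_config()].
#' @return a list of class \code{lawbend_rawsim} with \code{events},
#'   \code{exposures} and \code{laws} data frames.
#' @export
simulate_raw_records <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  states <- sim_state_codes(config$n_states)
  laws <- draw_laws(states, config)
  b <- rnorm(config$n_states, 0, config$sigma_b)
  years <- 2005:2017
  mr <- config$missingness_rates

  n_wk <- length(years) * 52L
  exp_list <- vector("list", config$n_states)
  evt_list <- vector("list", config$n_states)
  for (s in seq_len(config$n_states)) {
    week <- rep(1:52, times = length(years))
    ayear <- rep(years, each = 52L)
    # weekly AE: monthly lognormal scale spread over ~4.33 weeks
    ae <- rlnorm(n_wk, config$ae_log_mean - log(4.33), config$ae_log_sd)
    exp_list[[s]] <- data.frame(state = states[s], academic_year = ayear,
                                exposure_week = week, athlete_exposures = ae,
                                stringsAsFactors = FALSE)
    wk_start <- first_monday_august(ayear) + (week - 1L) * 7L
    stdm <- month_index(wk_start + 3L) - month_index(laws$passage_date[s])
    mu <- ae * exp(piecewise_lograte(stdm, config) + b[s])
    n_ev <- rnbinom(n_wk, size = 1 / config$dispersion, mu = mu)
    if (sum(n_ev) == 0L) next
    idx <- rep.int(seq_len(n_wk), n_ev)
    n <- length(idx)
    date <- wk_start[idx] + sample.int(7L, n, replace = TRUE) - 1L
    recurrent <- runif(n) < config$recurrent_fraction
    ev <- data.frame(
      state = states[s],
      injury_date = date,
      classification = ifelse(recurrent, "recurrent", "incident"),
      injury_type = "concussion",
      recurrent_mechanism_sport = ifelse(recurrent, TRUE, NA),
      ae_linked = TRUE,
      stringsAsFactors = FALSE
    )
    # independent per-field corruption
    ev$injury_date[runif(n) < mr$injury_date] <- NA
    ev$state[runif(n) < mr$state] <- NA
    ev$classification[runif(n) < mr$classification] <- "missing"
    ev$ae_linked[runif(n) < mr$ae_link] <- FALSE
    ev$injury_type[runif(n) < mr$injury_type_unknown] <- "unknown"
    ev$injury_type[ev$injury_type == "concussion" &
                     runif(n) < mr$injury_type_other] <- "other"
    flip <- ev$classification == "recurrent" & runif(n) < mr$recurrent_nonsport
    ev$recurrent_mechanism_sport[flip] <- FALSE
    evt_list[[s]] <- ev
  }
  events <- do.call(rbind, evt_list)
  rownames(events) <- NULL
  events$expected_excluded <-
    is.na(events$injury_date) | is.na(events$state) |
    events$classification %in% c("missing", "unknown") |
    !events$ae_linked |
    events$injury_type %in% c("unknown", "other") |
    (events$classification == "recurrent" &
       !is.na(events$recurrent_mechanism_sport) &
       !events$recurrent_mechanism_sport)
  exposures <- do.call(rbind, exp_list)
  rownames(exposures) <- NULL
  structure(list(events = events, exposures = exposures, laws = laws,
                 config = config),
            class = "lawbend_rawsim")
}
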