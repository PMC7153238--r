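# shared fixture builders; everything is generated in code at test time

# a small, fast panel with clear piecewise structure
small_sim_config <- function(n_states = 8, seed = 42, ...) {
  sim_config(n_states = n_states, stdm_range = c(-24, 30),
             tau1 = -12, tau2 = 18, ae_log_mean = log(3000),
             seed = seed, ...)
}

small_cells <- function(config = small_sim_config(),
                        classification = "incident") {
  sim <- simulate_surveillance(config)
  sim$cells[sim$cells$classification == classification, ]
}

# hand-built event records hitting every exclusion rule
make_event <- function(state = "IA", injury_date = as.Date("2012-01-15"),
                       classification = "incident",
                       injury_type = "concussion",
                       recurrent_mechanism_sport = NA, ae_linked = TRUE) {
  data.frame(state = state, injury_date = injury_date,
             classification = classification, injury_type = injury_type,
             recurrent_mechanism_sport = recurrent_mechanism_sport,
             ae_linked = ae_linked, stringsAsFactors = FALSE)
}

law_table_path <- function() {
  system.file("extdata", "tbi_laws_table_synthetic_dates.csv",
              package = "lawbend", mustWork = TRUE)
}

# independent NB2 log-likelihood oracle, summed term by term with dnbinom
nb_loglik_oracle <- function(params, cells, knots) {
  mu <- cells$athlete_exposures * exp(
    params$beta0 + params$beta1 * cells$stdm +
      params$gamma1 * pmax(0, cells$stdm - knots$tau1) +
      params$gamma2 * pmax(0, cells$stdm - knots$tau2))
  sum(dnbinom(cells$event_count, size = 1 / params$dispersion, mu = mu,
              log = TRUE))
}
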