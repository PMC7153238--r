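# internal helpers shared across modules

# Gauss-Hermite nodes/weights (weight function exp(-z^2)) by Golub-Welsch:
# eigen-decomposition of the symmetric tridiagonal Jacobi matrix.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# US states + DC, the 51 jurisdictions with youth TBI laws
jurisdictions <- c(
  "AK", "AL", "AR", "AZ", "CA", "CO", "CT", "DC", "DE", "FL", "GA", "HI",
  "IA", "ID", "IL", "IN", "KS", "KY", "LA", "MA", "MD", "ME", "MI", "MN",
  "MO", "MS", "MT", "NC", "ND", "NE", "NH", "NJ", "NM", "NV", "NY", "OH",
  "OK", "OR", "PA", "RI", "SC", "SD", "TN", "TX", "UT", "VA", "VT", "WA",
  "WI", "WV", "WY"
)

# state codes for a simulated panel; falls back to synthetic codes past 51
sim_state_codes <- function(n) {
  if (n <= length(jurisdictions)) return(jurisdictions[seq_len(n)])
  c(jurisdictions, sprintf("X%02d", seq_len(n - length(jurisdictions))))
}

# calendar-month index (year*12 + month), the arithmetic behind STDM
month_index <- function(date) {
  lt <- as.POSIXlt(date)
  lt$year * 12L + lt$mon
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
       call. = FALSE)
}
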