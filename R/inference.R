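# Slope inference on the percent-per-month scale and comparisons between
# fitted trend models (injury classifications or law-language groups).

#' Percent change per standardized month implied by a log-linear slope
#'
#' The log-link transform \code{100 * (exp(slope) - 1)}: a strictly
#' increasing bijection with inverse [percent_to_log()]. For slopes of a few
#' percent this is numerically close to \code{100 * slope}.
#'
#' @param log_slope log-scale slope (per STDM).
#' @return percent change per STDM.
#' @examples
#' percent_change(log(2))   # 100
#' percent_change(-log(2))  # -50
#' @export
percent_change <- function(log_slope) 100 * expm1(log_slope)

#' @rdname percent_change
#' @param percent percent change per STDM.
#' @export
percent_to_log <- function(percent) log1p(percent / 100)

#' Wald interval for a slope change, on the percent scale
#'
#' @param coef log-scale slope estimate.
#' @param se its standard error (> 0).
#' @param alpha two-sided significance level.
#' @param label slope label, conventionally
#'   \code{"after_first_change_point"} or
#'   \code{"after_second_change_point"}.
#' @return data frame of class \code{slope_change}: label, the source
#'   coefficient and SE, the percent-per-STDM estimate with CI, and the
#'   two-sided Wald p-value. Intervals are unadjusted for change-point
#'   selection.
#' @export
slope_wald_ci <- function(coef, se, alpha = 0.05, label = "slope") {
  if (!is.finite(coef)) stop("coef must be finite")
  if (!is.finite(se) || se <= 0) stop("se must be > 0")
  z <- qnorm(1 - alpha / 2)
  out <- data.frame(
    label = label,
    log_slope = as.numeric(coef),
    se = as.numeric(se),
    percent_per_stdm = percent_change(coef),
    ci_low = percent_change(coef - z * se),
    ci_high = percent_change(coef + z * se),
    p_value = 2 * pnorm(-abs(coef / se)),
    stringsAsFactors = FALSE
  )
  attr(out, "note") <- "Wald interval, unadjusted for change-point selection"
  class(out) <- c("slope_change", "data.frame")
  out
}

#' Compare a slope change between two fitted models
#'
#' Large-sample two-sample test of a slope coefficient between two
#' independently fitted trend models (e.g. incident vs recurrent, or two
#' law-language groups): the statistic
#' \code{(coef_a - coef_b) / sqrt(se_a^2 + se_b^2)} is referred to the
#' standard normal. The difference is reported on the percent-per-STDM
#' scale as \code{percent_change(coef_a) - percent_change(coef_b)} relative
#' to fit \code{b} (the reference), with a delta-method Wald interval; this
#' makes the reported difference antisymmetric under swapping the fits.
#'
#' @param fit_a,fit_b converged \code{piecewise_nb} fits; \code{fit_b} is
#'   the reference group.
#' @param which \code{"gamma1"} or \code{"gamma2"}: which slope change to
#'   compare.
#' @param alpha two-sided significance level.
#' @param labels length-2 character: names of the two groups.
#' @return data frame of class \code{group_comparison} with the percent
#'   difference, CI, statistic and p-value.
#' @export
compare_slopes <- function(fit_a, fit_b, which = c("gamma2", "gamma1"),
                           alpha = 0.05, labels = c("a", "b")) {
  which <- match.arg(which)
  for (f in list(fit_a, fit_b))
    if (!inherits(f, "piecewise_nb") || !isTRUE(f$converged))
      stop("compare_slopes requires two converged piecewise_nb fits")
  ca <- fit_a$coefficients[which]; cb <- fit_b$coefficients[which]
  sa <- sqrt(fit_a$vcov[which, which]); sb <- sqrt(fit_b$vcov[which, which])
  if (!is.finite(sa) || !is.finite(sb) || sa <= 0 || sb <= 0)
    stop("non-positive or missing standard error for ", which)
  stat <- (ca - cb) / sqrt(sa^2 + sb^2)
  p <- 2 * pnorm(-abs(stat))
  d_pct <- percent_change(ca) - percent_change(cb)
  se_pct <- sqrt((100 * exp(ca) * sa)^2 + (100 * exp(cb) * sb)^2)
  z <- qnorm(1 - alpha / 2)
  out <- data.frame(
    comparison = paste(labels[1], "vs", labels[2]),
    which = which,
    reference = labels[2],
    difference_percent = as.numeric(d_pct),
    ci_low = as.numeric(d_pct - z * se_pct),
    ci_high = as.numeric(d_pct + z * se_pct),
    statistic = as.numeric(stat),
    p_value = as.numeric(p),
    stringsAsFactors = FALSE
  )
  attr(out, "note") <- "Wald interval, unadjusted for change-point selection"
  class(out) <- c("group_comparison", "data.frame")
  out
}
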