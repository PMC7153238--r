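# Report writers shaping fitted trends and group comparisons the way
# surveillance policy evaluations tabulate them: one row per law-language
# stratum with the additional percent change per STDM after each change
# point for incident and recurrent concussions, the incident-vs-recurrent
# contrast, and between-group contrasts per dichotomy.

# reference level of each dichotomy for between-group comparisons
.dichotomies <- list(
  rtp = c(level = "not_specified", reference = "specified"),
  breadth = c(level = "multiple", reference = "physicians_only"),
  education = c(level = "both", reference = "either")
)

slope_cells <- function(fit, which, alpha) {
  if (is.null(fit) || !isTRUE(fit$converged))
    return(data.frame(percent = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      significant = NA))
  se <- sqrt(fit$vcov[which, which])
  sc <- slope_wald_ci(fit$coefficients[which], se, alpha)
  data.frame(percent = sc$percent_per_stdm, ci_low = sc$ci_low,
             ci_high = sc$ci_high, p_value = sc$p_value,
             significant = sc$p_value < alpha)
}

#' Tabulate fitted trends and group comparisons
#'
#' Assembles the stratified trend report from a named list of fits keyed by
#' the \code{model_id} values of [enumerate_model_plan()]
#' (\code{"stratum_variable:stratum_level:classification"}). Produces two
#' tables: \code{trends} with one row per stratum and change point carrying
#' the incident and recurrent percent changes per STDM (with CI and
#' significance at \code{alpha}) and their incident-vs-recurrent
#' difference; and \code{comparisons} with the between-group differences
#' per dichotomy, classification and change point. Missing or unconverged
#' fits yield NA cells and a warning, never a silent drop.
#'
#' @param fits named list of \code{piecewise_nb} fits.
#' @param alpha significance level (default 0.05).
#' @return object of class \code{trend_report} with data frames
#'   \code{trends} and \code{comparisons}; all intervals are Wald,
#'   unadjusted for change-point selection.
#' @export
report_tables <- function(fits, alpha = 0.05) {
  plan <- enumerate_model_plan()
  missing_ids <- setdiff(plan$model_id, names(fits))
  bad <- intersect(plan$model_id, names(fits))
  bad <- bad[!vapply(fits[bad], function(f) isTRUE(f$converged), logical(1))]
  if (length(missing_ids) || length(bad))
    warning("report has gaps; missing or unconverged fits: ",
            paste(c(missing_ids, bad), collapse = ", "))
  get_fit <- function(id) {
    f <- fits[[id]]
    if (!is.null(f) && isTRUE(f$converged)) f else NULL
  }

  strata <- unique(plan[, c("stratum_variable", "stratum_level")])
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    sv <- strata$stratum_variable[i]; sl <- strata$stratum_level[i]
    fi <- get_fit(paste(sv, sl, "incident", sep = ":"))
    fr <- get_fit(paste(sv, sl, "recurrent", sep = ":"))
    for (w in c("gamma1", "gamma2")) {
      cp <- if (w == "gamma1") "after_first_change_point" else
        "after_second_change_point"
      inc <- slope_cells(fi, w, alpha)
      rec <- slope_cells(fr, w, alpha)
      dif <- if (!is.null(fi) && !is.null(fr)) {
        cmp <- compare_slopes(fi, fr, which = w, alpha = alpha,
                              labels = c("incident", "recurrent"))
        data.frame(percent = cmp$difference_percent, ci_low = cmp$ci_low,
                   ci_high = cmp$ci_high, p_value = cmp$p_value,
                   significant = cmp$p_value < alpha)
      } else slope_cells(NULL, w, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum_variable = sv, stratum_level = sl, change_point = cp,
        incident_percent = inc$percent, incident_ci_low = inc$ci_low,
        incident_ci_high = inc$ci_high, incident_significant = inc$significant,
        recurrent_percent = rec$percent, recurrent_ci_low = rec$ci_low,
        recurrent_ci_high = rec$ci_high,
        recurrent_significant = rec$significant,
        difference_percent = dif$percent, difference_ci_low = dif$ci_low,
        difference_ci_high = dif$ci_high,
        difference_significant = dif$significant,
        stringsAsFactors = FALSE)
    }
  }
  trends <- do.call(rbind, rows)

  rows <- list()
  for (dv in names(.dichotomies)) {
    lv <- .dichotomies[[dv]][["level"]]
    rf <- .dichotomies[[dv]][["reference"]]
    for (cl in c("incident", "recurrent")) {
      fa <- get_fit(paste(dv, lv, cl, sep = ":"))
      fb <- get_fit(paste(dv, rf, cl, sep = ":"))
      for (w in c("gamma1", "gamma2")) {
        cp <- if (w == "gamma1") "after_first_change_point" else
          "after_second_change_point"
        if (is.null(fa) || is.null(fb)) {
          cmp <- data.frame(difference_percent = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_)
        } else {
          cmp <- compare_slopes(fa, fb, which = w, alpha = alpha,
                                labels = c(lv, rf))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          dichotomy = dv, group = lv, reference = rf,
          classification = cl, change_point = cp,
          difference_percent = cmp$difference_percent,
          ci_low = cmp$ci_low, ci_high = cmp$ci_high,
          p_value = cmp$p_value,
          significant = if (is.na(cmp$p_value)) NA else
            cmp$p_value < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  comparisons <- do.call(rbind, rows)
  structure(list(trends = trends, comparisons = comparisons, alpha = alpha),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, digits = 3, ...) {
  cat("Stratified trend report (percent per STDM;",
      "Wald CIs unadjusted for change-point selection)\n\n")
  print(x$trends, row.names = FALSE, digits = digits)
  cat("\nGroup comparisons:\n")
  print(x$comparisons, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Write a trend report to CSV files
#'
#' Writes \code{trends.csv} and \code{comparisons.csv} under \code{dir};
#' re-reading with [read.csv()] reproduces the numeric cells exactly (full
#' precision is written).
#'
#' @param report a \code{trend_report}.
#' @param dir output directory (created if needed).
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t_path <- file.path(dir, "trends.csv")
  c_path <- file.path(dir, "comparisons.csv")
  old <- options(digits = 17); on.exit(options(old))
  write.csv(report$trends, t_path, row.names = FALSE)
  write.csv(report$comparisons, c_path, row.names = FALSE)
  invisible(c(t_path, c_path))
}

#' Run the stratified analysis plan over an analysis table
#'
#' Convenience driver: for each of the 14 planned models, subsets the
#' analysis table to the stratum and classification, locates the change
#' points by [profile_search()] over \code{grid} (or fits at fixed
#' \code{knots} when supplied), and returns the named fit list that
#' [report_tables()] consumes. Strata with too little data to fit are
#' returned as \code{NULL} entries with a warning.
#'
#' @param cells full analysis table (both classifications, all strata).
#' @param grid knot grid for the profile scan, or \code{NULL} when
#'   \code{knots} is given.
#' @param knots optional fixed [knot_pair()] bypassing the scan.
#' @param control a [fit_control()].
#' @return named list of \code{piecewise_nb} fits keyed by model id.
#' @export
run_model_plan <- function(cells, grid = NULL, knots = NULL,
                           control = fit_control()) {
  if (is.null(grid) && is.null(knots))
    stop("supply either a knot grid to scan or fixed knots")
  plan <- enumerate_model_plan()
  fits <- setNames(vector("list", nrow(plan)), plan$model_id)
  for (i in seq_len(nrow(plan))) {
    sub <- cells[cells$classification == plan$classification[i], ,
                 drop = FALSE]
    sv <- plan$stratum_variable[i]
    if (sv != "overall") {
      col <- paste0(sv, "_group")
      sub <- sub[sub[[col]] == plan$stratum_level[i], , drop = FALSE]
    }
    fits[[i]] <- tryCatch({
      if (is.null(knots)) profile_search(sub, grid, control)$fit
      else fit_piecewise_model(sub, knots, control)
    }, error = function(e) {
      warning(sprintf("model %s failed: %s", plan$model_id[i],
                      conditionMessage(e)))
      NULL
    })
  }
  fits
}
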