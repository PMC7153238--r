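# Reading surveillance and law CSVs, exclusion filters, law-language
# classification, and the stratified model plan.
#
# CSV dialects (ISO dates throughout):
#   events:    state,injury_date,classification,injury_type,recurrent_mechanism_sport
#   exposures: state,academic_year,exposure_week,athlete_exposures
#   laws:      state,passage_date,rtp_provider,provider_breadth,education

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s file is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
}

parse_date_safely <- function(x) {
  # unparseable cells become NA (candidates for exclusion), never defaults
  suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
}

parse_logical_safely <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "true", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "false", "F", "0")] <- FALSE
  out
}

#' Read concussion event records from CSV
#'
#' @param path CSV with columns \code{state, injury_date, classification,
#'   injury_type, recurrent_mechanism_sport}. Unparseable dates or booleans
#'   become \code{NA}; blank strings become \code{NA}.
#' @return data frame of typed event records.
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", na.strings = c("", "NA"))
  check_columns(df, c("state", "injury_date", "classification",
                      "injury_type", "recurrent_mechanism_sport"), "events")
  data.frame(
    state = df$state,
    injury_date = parse_date_safely(df$injury_date),
    classification = df$classification,
    injury_type = df$injury_type,
    recurrent_mechanism_sport = parse_logical_safely(df$recurrent_mechanism_sport),
    stringsAsFactors = FALSE
  )
}

#' Read weekly athlete-exposure records from CSV
#'
#' @param path CSV with columns \code{state, academic_year, exposure_week,
#'   athlete_exposures}.
#' @return data frame of typed exposure records.
#' @export
read_exposures_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  check_columns(df, c("state", "academic_year", "exposure_week",
                      "athlete_exposures"), "exposures")
  data.frame(
    state = as.character(df$state),
    academic_year = as.integer(df$academic_year),
    exposure_week = as.integer(df$exposure_week),
    athlete_exposures = as.numeric(df$athlete_exposures),
    stringsAsFactors = FALSE
  )
}

#' Read both surveillance files and link events to exposure coverage
#'
#' Events gain a logical \code{ae_linked} column: whether exposure data
#' exists for the event's state (events in states with no exposure stream
#' cannot enter a rate and are excluded downstream).
#'
#' @param events_path,exposures_path CSV paths.
#' @return list with \code{events} and \code{exposures} data frames.
#' @export
read_surveillance_csv <- function(events_path, exposures_path) {
  events <- read_events_csv(events_path)
  exposures <- read_exposures_csv(exposures_path)
  events$ae_linked <- !is.na(events$state) &
    events$state %in% unique(exposures$state)
  list(events = events, exposures = exposures)
}

#' Read the state law table from CSV
#'
#' @param path CSV with columns \code{state, passage_date, rtp_provider,
#'   provider_breadth, education}.
#' @return data frame of law records.
#' @export
read_law_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  check_columns(df, c("state", "passage_date", "rtp_provider",
                      "provider_breadth", "education"), "laws")
  data.frame(
    state = as.character(df$state),
    passage_date = parse_date_safely(df$passage_date),
    rtp_provider = df$rtp_provider,
    provider_breadth = df$provider_breadth,
    education = df$education,
    stringsAsFactors = FALSE
  )
}

#' Write event/exposure/law records to their CSV dialects
#'
#' @param events,exposures,laws data frames as produced by the generators.
#' @param path output path.
#' @name write_surveillance
#' @export
write_events_csv <- function(events, path) {
  cols <- c("state", "injury_date", "classification", "injury_type",
            "recurrent_mechanism_sport")
  write.csv(events[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_surveillance
#' @export
write_exposures_csv <- function(exposures, path) {
  cols <- c("state", "academic_year", "exposure_week", "athlete_exposures")
  write.csv(exposures[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_surveillance
#' @export
write_law_csv <- function(laws, path) {
  cols <- c("state", "passage_date", "rtp_provider", "provider_breadth",
            "education")
  write.csv(laws[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the surveillance exclusion rules
#'
#' Removes events that cannot enter a rate model: missing injury date,
#' missing state, missing/unknown incident-recurrent classification, no
#' linked athlete-exposure data, injury type recorded as unknown or other,
#' and recurrent injuries from a non-sport mechanism. A record is removed
#' once however many rules it violates; the per-reason counts record every
#' applicable reason, so they may sum to more than the total excluded.
#'
#' @param events data frame of event records; an absent \code{ae_linked}
#'   column is treated as all linked.
#' @return list with \code{kept} (the surviving records) and \code{report}
#'   (an \code{exclusion_report}: totals and per-reason counts).
#' @examples
#' ev <- data.frame(state = c("IA", NA), injury_date = as.Date("2011-01-05"),
#'   classification = "incident", injury_type = "concussion",
#'   recurrent_mechanism_sport = NA)
#' apply_exclusions(ev)$report
#' @export
apply_exclusions <- function(events) {
  ae_linked <- if ("ae_linked" %in% names(events)) {
    !is.na(events$ae_linked) & events$ae_linked
  } else rep(TRUE, nrow(events))
  cls <- events$classification
  reasons <- list(
    missing_date = is.na(events$injury_date),
    missing_state = is.na(events$state),
    missing_classification = is.na(cls) | cls %in% c("missing", "unknown"),
    missing_ae = !ae_linked,
    type_unknown = !is.na(events$injury_type) &
      events$injury_type == "unknown",
    type_other = !is.na(events$injury_type) & events$injury_type == "other",
    recurrent_nonsport = !is.na(cls) & cls == "recurrent" &
      !is.na(events$recurrent_mechanism_sport) &
      !events$recurrent_mechanism_sport
  )
  excluded <- Reduce(`|`, reasons)
  report <- structure(list(
    n_input = nrow(events),
    n_kept = sum(!excluded),
    n_excluded = sum(excluded),
    pct_excluded = if (nrow(events)) 100 * sum(excluded) / nrow(events) else 0,
    reasons = vapply(reasons, sum, integer(1))
  ), class = "exclusion_report")
  list(kept = events[!excluded, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d of %d records excluded (%.1f%%), %d kept\n",
              x$n_excluded, x$n_input, x$pct_excluded, x$n_kept))
  for (nm in names(x$reasons))
    if (x$reasons[[nm]] > 0) cat(sprintf("  %-24s %d\n", nm, x$reasons[[nm]]))
  cat("  (reasons overlap; each record is excluded once)\n")
  invisible(x)
}

#' Classify states into law-language groups
#'
#' Maps each state's law record onto the three dichotomies used for
#' stratified trend models: whether the law names the category of healthcare
#' provider allowed to give return-to-play (RTP) clearance; among those that
#' do, physicians-only versus multiple provider categories; and whether
#' concussion education is required of both coaches and parents/guardians or
#' of either. Illinois-style laws with no RTP clearance requirement belong to
#' the not-specified group with breadth \code{not_applicable}.
#'
#' @param laws data frame of law records, one per state.
#' @return data frame \code{state, rtp_group, breadth_group,
#'   education_group} with a \code{group_sizes} attribute (counts per level
#'   of each dichotomy).
#' @export
classify_states <- function(laws) {
  if (anyDuplicated(laws$state))
    stop("duplicate law records for state(s): ",
         paste(unique(laws$state[duplicated(laws$state)]), collapse = ", "))
  ok_rtp <- laws$rtp_provider %in% c("specified", "not_specified")
  if (!all(ok_rtp))
    stop("invalid rtp_provider for state(s): ",
         paste(laws$state[!ok_rtp], collapse = ", "))
  ok_br <- ifelse(laws$rtp_provider == "specified",
                  laws$provider_breadth %in% c("physicians_only", "multiple"),
                  laws$provider_breadth == "not_applicable")
  if (!all(ok_br))
    stop("provider_breadth inconsistent with rtp_provider for state(s): ",
         paste(laws$state[!ok_br], collapse = ", "))
  ok_ed <- laws$education %in% c("both", "either")
  if (!all(ok_ed))
    stop("education must be 'both' or 'either' (states requiring neither ",
         "are outside the dichotomy); offending state(s): ",
         paste(laws$state[!ok_ed], collapse = ", "))
  out <- data.frame(state = laws$state,
                    rtp_group = laws$rtp_provider,
                    breadth_group = laws$provider_breadth,
                    education_group = laws$education,
                    stringsAsFactors = FALSE)
  attr(out, "group_sizes") <- list(
    rtp = table(out$rtp_group),
    breadth = table(out$breadth_group[out$breadth_group != "not_applicable"]),
    education = table(out$education_group)
  )
  out
}

#' Enumerate the stratified analysis plan
#'
#' The full plan is 14 models: incident and recurrent trend models overall,
#' and for each level of the three law-language dichotomies (provider
#' specified vs not; multiple providers vs physicians only; education for
#' both vs either).
#'
#' @return data frame with columns \code{model_id, stratum_variable,
#'   stratum_level, classification}; exactly 14 rows.
#' @examples
#' nrow(enumerate_model_plan())
#' @export
enumerate_model_plan <- function() {
  strata <- rbind(
    data.frame(stratum_variable = "overall", stratum_level = "all"),
    data.frame(stratum_variable = "rtp",
               stratum_level = c("specified", "not_specified")),
    data.frame(stratum_variable = "breadth",
               stratum_level = c("multiple", "physicians_only")),
    data.frame(stratum_variable = "education",
               stratum_level = c("both", "either"))
  )
  plan <- merge(strata, data.frame(classification = c("incident", "recurrent")))
  plan <- plan[order(match(plan$stratum_variable,
                           c("overall", "rtp", "breadth", "education")),
                     plan$stratum_level, plan$classification), ]
  plan$model_id <- paste(plan$stratum_variable, plan$stratum_level,
                         plan$classification, sep = ":")
  rownames(plan) <- NULL
  plan[, c("model_id", "stratum_variable", "stratum_level", "classification")]
}
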