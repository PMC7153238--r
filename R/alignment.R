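# The standardized-month (STDM) axis and the four-week aggregation that
# turns weekly exposure streams and dated events into state-by-month
# analysis cells.

#' Standardized month of an injury relative to law passage
#'
#' Calendar-month difference between the injury date and the state's
#' law-passage date: 0 in the passage month, negative before, positive
#' after. Day-of-month is ignored (pure year*12+month arithmetic).
#'
#' @param injury_date,passage_date \code{Date} vectors (recycled).
#' @return integer vector of STDM values.
#' @examples
#' compute_stdm(as.Date("2011-07-15"), as.Date("2011-07-01")) # 0
#' compute_stdm(as.Date("2012-01-03"), as.Date("2010-01-28")) # 24
#' @export
compute_stdm <- function(injury_date, passage_date) {
  if (anyNA(injury_date) || anyNA(passage_date))
    stop("compute_stdm: missing date(s); such records must be excluded first")
  as.integer(month_index(as.Date(injury_date)) -
               month_index(as.Date(passage_date)))
}

# academic year containing a date, given the week-1 anchor rule
date_to_academic_week <- function(dates, anchor = first_monday_august) {
  y <- as.POSIXlt(dates)$year + 1900L
  ay <- ifelse(dates >= anchor(y), y, y - 1L)
  wk <- as.integer(floor(as.numeric(dates - anchor(ay)) / 7)) + 1L
  data.frame(academic_year = as.integer(ay),
             exposure_week = pmin(wk, 52L)) # the 1-2 day year-end overhang
}

#' Aggregate weekly exposures and dated events into four-week blocks
#'
#' Sums athlete-exposures and event counts across four-week increments
#' (weeks 1-4, 5-8, ..., 49-52), giving 13 blocks per state per academic
#' year. Events are mapped to exposure weeks through the academic calendar:
#' week 1 starts at the \code{anchor} date (default: the first Monday of
#' August).
#'
#' @param exposures data frame of weekly exposure records.
#' @param events data frame of kept event records (complete dates/states).
#' @param anchor function(year) -> Date giving the week-1 start.
#' @return data frame with one row per state, academic year and block:
#'   \code{state, academic_year, block, center_date, athlete_exposures,
#'   events_incident, events_recurrent}. \code{center_date} is the midpoint
#'   of the 28-day block, used downstream to place the block on the STDM
#'   axis.
#' @export
aggregate_four_week <- function(exposures, events,
                                anchor = first_monday_august) {
  if (any(exposures$exposure_week < 1L | exposures$exposure_week > 52L))
    stop("exposure_week outside 1..52")
  if (any(exposures$athlete_exposures < 0))
    stop("negative athlete_exposures")
  exposures$block <- ceiling(exposures$exposure_week / 4)
  ae <- aggregate(athlete_exposures ~ state + academic_year + block,
                  data = exposures, FUN = sum)

  if (anyNA(events$injury_date) || anyNA(events$state))
    stop("events with missing date or state must be excluded before aggregation")
  empty_cnt <- data.frame(state = character(), academic_year = integer(),
                          block = integer(), n = integer())
  if (nrow(events)) {
    aw <- date_to_academic_week(events$injury_date, anchor)
    ev <- data.frame(state = events$state,
                     academic_year = aw$academic_year,
                     block = ceiling(aw$exposure_week / 4),
                     classification = events$classification,
                     stringsAsFactors = FALSE)
    cnt <- aggregate(cbind(n = rep(1L, nrow(ev))) ~
                       state + academic_year + block + classification,
                     data = ev, FUN = sum)
    inc <- cnt[cnt$classification == "incident",
               c("state", "academic_year", "block", "n")]
    rec <- cnt[cnt$classification == "recurrent",
               c("state", "academic_year", "block", "n")]
  } else {
    inc <- rec <- empty_cnt
  }
  names(inc)[4] <- "events_incident"
  names(rec)[4] <- "events_recurrent"

  out <- merge(ae, inc, by = c("state", "academic_year", "block"), all = TRUE)
  out <- merge(out, rec, by = c("state", "academic_year", "block"), all = TRUE)
  out$athlete_exposures[is.na(out$athlete_exposures)] <- 0
  out$events_incident[is.na(out$events_incident)] <- 0L
  out$events_recurrent[is.na(out$events_recurrent)] <- 0L
  out$center_date <- anchor(out$academic_year) +
    (out$block - 1L) * 28L + 14L
  out <- out[order(out$state, out$academic_year, out$block), ]
  rownames(out) <- NULL
  out
}

#' Assemble the state-by-STDM analysis table
#'
#' Places each four-week block on the STDM axis (the calendar month
#' containing the block's central week, relative to the state's law-passage
#' month), attaches the law-language stratum labels, and reshapes to one row
#' per state, STDM and injury classification. Blocks mapping to the same
#' calendar month are summed. Cells with zero exposure and zero events are
#' dropped (the log-AE offset is undefined); their count is recorded in the
#' \code{n_dropped_zero} attribute. A cell with events but no exposure is an
#' error, since its rate is undefined.
#'
#' @param blocks output of [aggregate_four_week()].
#' @param laws law table with one record per state present in \code{blocks}.
#' @return data frame of analysis cells: \code{state, stdm, classification,
#'   event_count, athlete_exposures, rtp_group, breadth_group,
#'   education_group}.
#' @export
build_analysis_table <- function(blocks, laws) {
  missing_laws <- setdiff(unique(blocks$state), laws$state)
  if (length(missing_laws))
    stop("no law record for state(s): ", paste(missing_laws, collapse = ", "))
  groups <- classify_states(laws)
  passage <- setNames(laws$passage_date, laws$state)
  stdm <- as.integer(month_index(blocks$center_date) -
                       month_index(passage[blocks$state]))

  long <- rbind(
    data.frame(state = blocks$state, stdm = stdm,
               classification = "incident",
               event_count = blocks$events_incident,
               athlete_exposures = blocks$athlete_exposures,
               stringsAsFactors = FALSE),
    data.frame(state = blocks$state, stdm = stdm,
               classification = "recurrent",
               event_count = blocks$events_recurrent,
               athlete_exposures = blocks$athlete_exposures,
               stringsAsFactors = FALSE)
  )
  cells <- aggregate(cbind(event_count, athlete_exposures) ~
                       state + stdm + classification,
                     data = long, FUN = sum)
  bad <- cells$athlete_exposures <= 0 & cells$event_count > 0
  if (any(bad))
    stop(sprintf("%d cell(s) have events but zero athlete-exposures; %s",
                 sum(bad), "rates are undefined"))
  idle <- cells$athlete_exposures <= 0 & cells$event_count == 0
  cells <- cells[!idle, , drop = FALSE]
  cells <- merge(cells, groups, by = "state", sort = FALSE)
  cells <- cells[order(cells$state, cells$stdm, cells$classification), ]
  rownames(cells) <- NULL
  attr(cells, "n_dropped_zero") <- sum(idle)
  cells
}

#' Write/read an analysis table CSV
#'
#' @param cells analysis table from [build_analysis_table()] or
#'   [simulate_surveillance()].
#' @param path CSV path.
#' @export
write_analysis_csv <- function(cells, path) {
  cols <- c("state", "stdm", "classification", "event_count",
            "athlete_exposures", "rtp_group", "breadth_group",
            "education_group")
  write.csv(cells[, intersect(cols, names(cells))], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_analysis_csv
#' @export
read_analysis_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("state", "stdm", "classification", "event_count",
                      "athlete_exposures"), "analysis table")
  df
}
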