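test_that("CSV round-trip preserves generated records", {
  raw <- simulate_raw_records(small_sim_config(n_states = 3, seed = 9))
  td <- withr::local_tempdir()
  ep <- file.path(td, "events.csv")
  xp <- file.path(td, "exposures.csv")
  lp <- file.path(td, "laws.csv")
  write_events_csv(raw$events, ep)
  write_exposures_csv(raw$exposures, xp)
  write_law_csv(raw$laws, lp)
  got <- read_surveillance_csv(ep, xp)
  cols <- c("state", "injury_date", "classification", "injury_type",
            "recurrent_mechanism_sport")
  expect_equal(got$events[cols], raw$events[cols],
               ignore_attr = "row.names")
  expect_equal(got$exposures, raw$exposures, ignore_attr = "row.names",
               tolerance = 1e-12)
  expect_equal(read_law_csv(lp), raw$laws, ignore_attr = "row.names")
  # all generated events belong to covered states
  expect_true(all(got$events$ae_linked))
})

test_that("malformed cells become NA, missing columns are a schema error", {
  td <- withr::local_tempdir()
  p <- file.path(td, "ev.csv")
  writeLines(c(
    "state,injury_date,classification,injury_type,recurrent_mechanism_sport",
    "IA,2012-01-15,incident,concussion,",
    "RI,not-a-date,recurrent,concussion,TRUE"), p)
  ev <- read_events_csv(p)
  expect_identical(nrow(ev), 2L)
  expect_true(is.na(ev$injury_date[2]))
  expect_identical(ev$state[2], "RI")

  p2 <- file.path(td, "bad.csv")
  writeLines("state,injury_date", p2)
  expect_error(read_events_csv(p2), "classification")

  p3 <- file.path(td, "empty.csv")
  writeLines(
    "state,injury_date,classification,injury_type,recurrent_mechanism_sport",
    p3)
  expect_identical(nrow(read_events_csv(p3)), 0L)
})

test_that("exclusion rules remove the right records, once each", {
  ev <- rbind(
    make_event(), make_event(state = "RI"),
    make_event(injury_date = as.Date(NA)),
    make_event(injury_date = as.Date(NA)),
    make_event(injury_type = "other"),
    make_event(classification = "recurrent",
               recurrent_mechanism_sport = FALSE),
    make_event(classification = "recurrent",
               recurrent_mechanism_sport = TRUE),
    make_event(state = "OH"), make_event(state = "TX"),
    make_event(state = "MN"))
  res <- apply_exclusions(ev)
  expect_identical(res$report$n_input, 10L)
  expect_identical(res$report$n_kept, 6L)
  expect_identical(res$report$n_excluded, 4L)
  expect_identical(unname(res$report$reasons[["missing_date"]]), 2L)
  expect_identical(unname(res$report$reasons[["type_other"]]), 1L)
  expect_identical(unname(res$report$reasons[["recurrent_nonsport"]]), 1L)

  # overlapping reasons still count the record once in the total
  both <- make_event(state = NA, injury_date = as.Date(NA))
  res2 <- apply_exclusions(rbind(make_event(), both))
  expect_identical(res2$report$n_excluded, 1L)
  expect_identical(unname(res2$report$reasons[["missing_date"]]), 1L)
  expect_identical(unname(res2$report$reasons[["missing_state"]]), 1L)

  # idempotence: already-kept records pass unchanged
  res3 <- apply_exclusions(res$kept)
  expect_identical(res3$report$n_excluded, 0L)
  expect_equal(res3$kept, res$kept)
})

test_that("kept + excluded always equals input", {
  for (seed in 1:5) {
    raw <- simulate_raw_records(small_sim_config(
      n_states = 2, seed = seed,
      missingness_rates = list(injury_date = 0.1, state = 0.05,
                               classification = 0.1,
                               injury_type_unknown = 0.02)))
    res <- apply_exclusions(raw$events)
    expect_identical(res$report$n_kept + res$report$n_excluded,
                     res$report$n_input)
    expect_gte(sum(res$report$reasons), res$report$n_excluded)
  }
})

test_that("law language classification matches the published table", {
  laws <- read_law_csv(law_table_path())
  cls <- classify_states(laws)
  expect_identical(nrow(cls), 51L)
  row <- function(st) cls[cls$state == st, ]
  expect_identical(row("RI")$rtp_group, "specified")
  expect_identical(row("RI")$breadth_group, "physicians_only")
  expect_identical(row("RI")$education_group, "both")
  expect_identical(row("IA")$rtp_group, "specified")
  expect_identical(row("IA")$breadth_group, "multiple")
  expect_identical(row("IL")$rtp_group, "not_specified")
  expect_identical(row("IL")$breadth_group, "not_applicable")
  expect_identical(row("IL")$education_group, "both")

  gs <- attr(cls, "group_sizes")
  expect_identical(as.integer(gs$rtp[c("specified", "not_specified")]),
                   c(27L, 24L))
  expect_identical(as.integer(gs$breadth[c("physicians_only", "multiple")]),
                   c(7L, 20L))
  expect_identical(as.integer(gs$education[c("both", "either")]),
                   c(40L, 11L))
  # each dichotomy partitions the states supplied
  expect_identical(sum(gs$rtp), 51L)
  expect_identical(sum(gs$education), 51L)
  expect_identical(sum(gs$breadth), 27L)
})

test_that("classification rejects malformed law tables", {
  laws <- read_law_csv(law_table_path())
  expect_error(classify_states(rbind(laws, laws[1, ])), "duplicate")
  bad <- laws
  bad$provider_breadth[bad$state == "IL"] <- "multiple"
  expect_error(classify_states(bad), "IL")
  bad2 <- laws
  bad2$education[bad2$state == "IA"] <- "neither"
  expect_error(classify_states(bad2), "IA")
})

test_that("the analysis plan enumerates 14 stratified models", {
  plan <- enumerate_model_plan()
  expect_identical(nrow(plan), 14L)
  expect_false(anyDuplicated(plan$model_id) > 0)
  overall <- plan[plan$stratum_variable == "overall", ]
  expect_setequal(overall$classification, c("incident", "recurrent"))
  expect_identical(nrow(overall), 2L)
  for (v in c("rtp", "breadth", "education")) {
    sub <- plan[plan$stratum_variable == v, ]
    expect_identical(nrow(sub), 4L)
    expect_identical(length(unique(sub$stratum_level)), 2L)
    expect_setequal(unique(sub$classification), c("incident", "recurrent"))
  }
})
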