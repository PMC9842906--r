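# a juvenile record for constructed tracks: hatched 2016-05-01
JUV <- data.frame(individual_id = "bird1", nest_lon = NEST[1],
                  nest_lat = NEST[2],
                  hatching_date = as.Date("2016-05-01"),
                  stringsAsFactors = FALSE)

test_that("outside runs are maximal, fix-to-fix, and inside-terminated", {
  # all fixes within the radius -> no runs
  tr <- make_track(0:10, rep(500, 11), rep(0, 11))
  expect_identical(nrow(outside_runs(tr, NEST, 2000)), 0L)

  # outside from day 10 to day 13 with one inside fix in between:
  # two maximal runs of 1.25 and 2.25 days (fix-to-fix durations)
  hours <- c(seq(240, 270, by = 3), 273, seq(276, 330, by = 3))
  east <- rep(3000, length(hours))
  east[hours == 273] <- 100
  tr <- make_track(hours, east, rep(0, length(hours)))
  runs <- outside_runs(tr, NEST, 2000)
  expect_identical(nrow(runs), 2L)
  expect_equal(runs$duration_days, c(1.25, 2.25))
  # agrees with the exhaustive window-scan oracle at each threshold
  for (thr in c(1, 2)) {
    expect_identical(
      detect_departure(tr, JUV, departure_params(min_outside_days = thr))$
        departure_t,
      oracle_departure(tr, NEST, 2000, thr))
  }

  # a single outside fix is a degenerate run of duration 0
  tr1 <- make_track(5, 3000, 0)
  runs1 <- outside_runs(tr1, NEST, 2000)
  expect_identical(nrow(runs1), 1L)
  expect_equal(runs1$duration_days, 0)

  # empty track
  expect_identical(nrow(outside_runs(tr1[0, ], NEST, 2000)), 0L)
})

test_that("gaps inherit the state of flanking fixes only if both outside", {
  # outside at 20:00, gap overnight, outside at 04:00 -> one run spanning 8 h
  tr <- make_track(c(18, 19, 20, 28, 29, 30),
                   c(100, 3000, 3000, 3000, 3000, 100), rep(0, 6))
  runs <- outside_runs(tr, NEST, 2000)
  expect_identical(nrow(runs), 1L)
  expect_equal(runs$duration_days, 10 / 24)
  # same gap but inside on one flank -> the run ends before the gap
  tr2 <- make_track(c(18, 19, 20, 28, 29, 30),
                    c(100, 3000, 3000, 100, 3000, 3000), rep(0, 6))
  runs2 <- outside_runs(tr2, NEST, 2000)
  expect_equal(runs2$duration_days, c(1 / 24, 1 / 24))
})

test_that("departure is the first strictly-longer-than-threshold run", {
  # excursion of 1.5 d at day 60, true departure at day 80 lasting 10 d
  hours <- c(seq(59 * 24, 59 * 24 + 36, by = 3),       # 1.5 d excursion
             seq(62 * 24, 79 * 24, by = 12),           # back at the nest
             seq(80 * 24, 90 * 24, by = 3))            # departure
  east <- c(rep(3000, 13), rep(200, 35), rep(4000, 81))
  tr <- make_track(hours, east, rep(0, length(hours)))
  res <- detect_departure(tr, JUV, departure_params())
  expect_identical(res$status, "departed")
  # hatched May 1, track origin July 1 = 61 d later; departure hour 80*24
  expect_equal(res$departure_age_days, 61 + 80)
  expect_equal(res$pfdp_days, 61 + 80 - 55)

  # the 1.5 d excursion is found at threshold 1 d, skipped at >= 2 d
  sens <- threshold_sensitivity(tr, JUV, departure_params())
  expect_equal(sens$departure_age_days[sens$threshold_days == 1], 61 + 59)
  expect_equal(sens$departure_age_days[sens$threshold_days == 2], 61 + 80)
  # ages non-decreasing in the threshold
  ages <- sens$departure_age_days
  expect_true(all(diff(ages[!is.na(ages)]) >= 0))
  # censored at 9 d is impossible here because a >10 d run exists
  expect_identical(unique(sens$status), "departed")
})

test_that("strictness: a run of exactly the threshold does not qualify", {
  hours <- seq(0, 48, by = 6)  # exactly 2.0 days outside
  tr <- make_track(hours, rep(3000, length(hours)), rep(0, length(hours)))
  res <- detect_departure(tr, JUV,
                          departure_params(min_outside_days = 2))
  expect_identical(res$status, "censored_no_departure")
})

test_that("never-departing tracks are censored and errors are raised", {
  tr <- make_track(0:20, rep(300, 21), rep(0, 21))
  res <- detect_departure(tr, JUV)
  expect_identical(res$status, "censored_no_departure")
  expect_true(is.na(res$departure_age_days))
  bad <- JUV; bad$hatching_date <- as.Date("2013-05-01")
  expect_error(detect_departure(tr, bad), "implausible")
})

test_that("full-day returns are counted per UTC day, partial days ignored", {
  # departure at hour 0; day 2 entirely inside; day 3 partially inside
  hours <- c(seq(0, 24, 6),            # day 0-1 outside
             seq(48, 66, 6),           # day 2: all inside
             seq(72, 90, 6))           # day 3: mixed
  east <- c(rep(4000, 5), rep(100, 4), c(100, 4000, 4000, 4000))
  tr <- make_track(hours, east, rep(0, length(hours)))
  dep_t <- tr$t[1]
  expect_identical(
    count_full_day_returns(tr, NEST, 2000, dep_t), 1L)
  # no post-departure inside fixes -> 0
  tr2 <- make_track(0:10, rep(4000, 11), rep(0, 11))
  expect_identical(count_full_day_returns(tr2, NEST, 2000, tr2$t[1]), 0L)
})

test_that("exclusion filters keep only scored departures without flags", {
  roster <- generate_exclusion_roster(239, 64, 17)
  out <- apply_exclusions(roster)
  expect_identical(unname(out$counts["included"]), 158L)
  expect_identical(unname(out$counts["tagged"]), 239L)
  # conservation of individuals across filter categories
  expect_identical(sum(out$counts[c("failed", "migrated", "censored",
                                    "included")]),
                   unname(out$counts["tagged"]))
  expect_identical(nrow(apply_exclusions(roster[0, ])$analysis_set), 0L)
  all_clear <- data.frame(individual_id = c("x", "y"),
                          fate = "included", stringsAsFactors = FALSE)
  expect_identical(nrow(apply_exclusions(all_clear)$analysis_set), 2L)
  bad <- data.frame(individual_id = "x", fate = "vanished")
  expect_error(apply_exclusions(bad), "unknown fate")
})

test_that("exclusion roster validates counts", {
  expect_error(generate_exclusion_roster(5, -1, 0), "non-negative")
  expect_error(generate_exclusion_roster(5, 4, 2), "exceeds")
  expect_identical(sum(generate_exclusion_roster(10, 0, 0)$fate ==
                         "included"), 10L)
  expect_identical(sum(generate_exclusion_roster(5, 5, 0)$fate ==
                         "included"), 0L)
})

test_that("migration flag requires early, unreturned long displacement", {
  # directed movement to 60 km with no return, before a 2 d absence elapses
  hours <- seq(0, 72, by = 3)
  east <- 1000 * hours  # 1 km/h outward
  tr <- make_track(hours, east, rep(0, length(hours)))
  expect_true(flag_migration(tr, NEST))
  # a local disperser settling 6 km away never trips the 50 km rule
  tr2 <- make_track(hours, pmin(1000 * hours, 6000), rep(0, length(hours)))
  expect_false(flag_migration(tr2, NEST))
})
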