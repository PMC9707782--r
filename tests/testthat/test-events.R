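ts_at <- function(minutes, day = "2018-08-01 12:00:00") {
  as.POSIXct(day, tz = "UTC") + minutes * 60
}

test_that("independence filter opens events per the quiet-period rule", {
  rec <- tibble::tibble(site_id = "A", timestamp = ts_at(c(0, 10, 29, 61)))
  ev <- independent_events(rec, gap = 30)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$event_time, ts_at(c(0, 61)))
  expect_equal(ev$n_records, c(3L, 1L))

  expect_equal(nrow(independent_events(rec[1, ], gap = 30)), 1)

  # a gap of exactly 30 minutes counts as independent
  rec30 <- tibble::tibble(site_id = "A", timestamp = ts_at(c(0, 30)))
  expect_equal(nrow(independent_events(rec30, gap = 30)), 2)

  # sites are filtered independently
  rec2 <- tibble::tibble(site_id = rep(c("A", "B"), each = 2),
                         timestamp = ts_at(c(0, 10, 5, 50)))
  expect_equal(nrow(independent_events(rec2, gap = 30)), 3)
})

test_that("independence filter rejects unsorted input", {
  rec <- tibble::tibble(site_id = "A", timestamp = ts_at(c(10, 0)))
  expect_error(independent_events(rec), "not sorted")
})

test_that("independence filter is idempotent and monotone in the gap", {
  withr::with_seed(9, {
    for (rep in 1:20) {
      n <- sample(2:40, 1)
      rec <- tibble::tibble(
        site_id = "A",
        timestamp = ts_at(sort(cumsum(rexp(n, rate = 1 / 25))))
      )
      ev30 <- independent_events(rec, gap = 30)
      # idempotence: re-filtering the events changes nothing
      again <- independent_events(
        tibble::tibble(site_id = "A", timestamp = ev30$event_time), gap = 30)
      expect_equal(again$event_time, ev30$event_time)
      # monotonicity: wider gap never yields more events
      ev60 <- independent_events(rec, gap = 60)
      expect_lte(nrow(ev60), nrow(ev30))
      # all records accounted for
      expect_equal(sum(ev30$n_records), n)
    }
  })
})

test_that("event-start rule differs only when bursts chain past the gap", {
  # records every 20 min for 100 min: previous-record rule chains them into
  # one event; event-start rule reopens once 30 min from the opener passes
  rec <- tibble::tibble(site_id = "A", timestamp = ts_at(seq(0, 100, by = 20)))
  expect_equal(nrow(independent_events(rec, gap = 30)), 1)
  expect_equal(nrow(independent_events(rec, gap = 30, rule = "event-start")), 3)
})

test_that("diel classification respects the sunrise/sunset boundary", {
  dep <- tibble::tibble(site_id = "A", lat = 48.37, lon = -123.73,
                        stratum = "wild")
  st <- sun_times(48.37, -123.73, as.Date("2018-09-15"), utc_offset = -8)
  ev <- tibble::tibble(
    site_id = "A",
    event_time = c(
      st$sunrise + 3600 * 4,   # mid-day
      st$sunrise - 60,         # one minute before sunrise -> night
      st$sunrise,              # at sunrise -> day (closed lower bound)
      st$sunset,               # at sunset -> night (open upper bound)
      st$sunset + 3600 * 3     # evening
    )
  )
  out <- classify_diel(ev, dep, utc_offset = -8)
  expect_equal(out$diel, c("day", "night", "day", "night", "night"))
})

test_that("diel labels are invariant to the stored UTC offset convention", {
  dep <- tibble::tibble(site_id = "A", lat = 48.37, lon = -123.73,
                        stratum = "wild")
  withr::with_seed(4, {
    ev <- tibble::tibble(
      site_id = "A",
      event_time = as.POSIXct("2018-09-15 00:00:00", tz = "UTC") +
        runif(50, 0, 86400 * 300)
    )
  })
  a <- classify_diel(ev, dep, utc_offset = -8)
  b <- classify_diel(ev, dep, utc_offset = -7)
  expect_equal(a$diel, b$diel)
})

test_that("season mapping follows the phenology-adjusted calendar", {
  expect_equal(as.character(season_of(2)), "spring")
  expect_equal(as.character(season_of(4)), "spring")
  expect_equal(as.character(season_of(5)), "summer")
  expect_equal(as.character(season_of(7)), "summer")
  expect_equal(as.character(season_of(8)), "autumn")
  expect_equal(as.character(season_of(10)), "autumn")
  expect_equal(as.character(season_of(11)), "winter")
  expect_equal(as.character(season_of(1)), "winter")
  expect_equal(levels(season_of(1)),
               c("spring", "summer", "autumn", "winter"))
  expect_equal(as.character(season_of("2018-09")), "autumn")
})

test_that("monthly counts produce the full site-by-month grid", {
  dep <- flat_deployments(c(urban = 2, rural = 2, wild = 2),
                          months = c("2018-07", "2018-08"), effort = 28)
  ev <- tibble::tibble(
    site_id = c("S001", "S001", "S002"),
    event_time = as.POSIXct(c("2018-07-10 20:00", "2018-07-11 20:00",
                              "2018-08-03 10:00"), tz = "UTC")
  )
  sm <- monthly_counts(ev, dep, utc_offset = -8)
  expect_equal(nrow(sm), 12) # 6 sites x 2 months, zeros included
  expect_equal(sm$count[sm$site_id == "S001" & sm$month == "2018-07"], 2)
  expect_equal(sm$count[sm$site_id == "S002" & sm$month == "2018-08"], 1)
  expect_equal(sum(sm$count), nrow(ev))
  expect_equal(unique(sm$effort), 28)
  expect_s3_class(sm$season, "factor")
})

test_that("events outside any deployment site-month raise an error", {
  dep <- flat_deployments(c(urban = 1, rural = 1, wild = 1),
                          months = "2018-07")
  ev <- tibble::tibble(site_id = "S001",
                       event_time = as.POSIXct("2019-01-05 10:00",
                                               tz = "UTC"))
  expect_error(monthly_counts(ev, dep), "outside any deployment")
})

test_that("detection rate rescales by days in month and flags zero effort", {
  sm <- tibble::tibble(
    site_id = c("a", "b", "c"), month = c("2018-06", "2018-06", "2018-06"),
    count = c(3L, 0L, 2L), effort = c(15, 20, 0),
    season = season_of(c(6, 6, 6))
  )
  out <- detection_rate(sm)
  expect_equal(out$rate, c(6, 0, NA)) # 3/15*30; 0; undefined
  # full effort: rate equals the count
  sm2 <- tibble::tibble(site_id = "a", month = "2018-09", count = 7L,
                        effort = 30, season = season_of(9))
  expect_equal(detection_rate(sm2)$rate, 7)
})

test_that("monthly counts equal generator bookkeeping on a synthetic bundle", {
  b <- study_bundle()
  ev <- independent_events(b$records, gap = b$truth$gap)
  sm <- monthly_counts(ev, b$deployments, utc_offset = b$truth$utc_offset)
  truth_counts <- b$site_months |>
    dplyr::arrange(site_id, month)
  expect_equal(sm$count, truth_counts$count)
  expect_equal(sum(sm$count), nrow(ev))
})
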