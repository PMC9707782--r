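#' Collapse raw detections into independent events
#'
#' Camera traps fire repeatedly while an animal lingers, so consecutive
#' detections are not independent observations. A record opens a new event
#' when it is separated from the *immediately preceding record* at the same
#' site by at least `gap` minutes (a gap of exactly `gap` counts as
#' independent); otherwise it extends the current event. The first record at
#' a site always opens an event. Under the alternative `rule =
#' "event-start"` the gap is measured from the record that opened the
#' current event instead.
#'
#' @param records A data frame of raw detections with columns `site_id`,
#'   `timestamp` (POSIXct), and optionally `species`. Must be sorted by
#'   timestamp within site.
#' @param gap Minimum separation in minutes for independence (default 30).
#' @param species Focal species label; if `records` has a `species` column,
#'   only matching rows are used.
#' @param rule How the gap is measured: from the previous record
#'   (`"previous-record"`, the default) or from the event's opening record.
#' @return A tibble with one row per independent event: `site_id`,
#'   `event_time` (time of the first record in the event), `n_records`.
#' @examples
#' rec <- tibble::tibble(
#'   site_id = "A",
#'   timestamp = as.POSIXct("2018-08-01 12:00", tz = "UTC") +
#'     c(0, 10, 29, 61) * 60
#' )
#' independent_events(rec) # two events, at minutes 0 and 61
#' @export
independent_events <- function(records, gap = 30,
                               species = NULL,
                               rule = c("previous-record", "event-start")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(records), gap > 0)
  if (!all(c("site_id", "timestamp") %in% names(records))) {
    stop("records must have columns site_id and timestamp", call. = FALSE)
  }
  if (!is.null(species) && "species" %in% names(records)) {
    records <- dplyr::filter(records, .data$species == !!species)
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(site_id = character(), event_time = records$timestamp[0],
                          n_records = integer()))
  }
  records |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(d, key) {
      ts <- d$timestamp
      if (is.unsorted(as.numeric(ts))) {
        stop("records are not sorted by timestamp within site ",
             key$site_id[[1]], call. = FALSE)
      }
      event_id <- assign_events(as.numeric(ts), gap * 60, rule)
      tibble::tibble(
        event_time = ts[!duplicated(event_id)],
        n_records = as.integer(table(event_id))
      )
    }) |>
    dplyr::ungroup()
}

assign_events <- function(t_sec, gap_sec, rule) {
  n <- length(t_sec)
  if (rule == "previous-record") {
    # gap >= threshold starts a new event ("separated by >= gap")
    cumsum(c(TRUE, diff(t_sec) >= gap_sec))
  } else {
    id <- integer(n)
    id[1] <- 1L
    opening <- t_sec[1]
    for (i in seq_len(n)[-1]) {
      if (t_sec[i] - opening >= gap_sec) {
        id[i] <- id[i - 1] + 1L
        opening <- t_sec[i]
      } else {
        id[i] <- id[i - 1]
      }
    }
    id
  }
}

#' Label events diurnal or nocturnal
#'
#' An event is `day` if sunrise <= event time < sunset for its site and
#' local civil date, `night` otherwise. Sunrise and sunset come from
#' [sun_times()]; the comparison is done on absolute instants so the stored
#' UTC offset of the timestamps does not affect the labels.
#'
#' @param events Tibble from [independent_events()] (columns `site_id`,
#'   `event_time`).
#' @param deployments Deployment table with `site_id`, `lat`, `lon` and
#'   `stratum` columns.
#' @param utc_offset Hours added to UTC for the local civil date (default -8).
#' @return `events` with `stratum` and `diel` (`"day"`/`"night"`) columns.
#' @export
classify_diel <- function(events, deployments, utc_offset = -8) {
  stopifnot(all(c("site_id", "event_time") %in% names(events)))
  dep <- dplyr::distinct(deployments, .data$site_id, .data$lat, .data$lon,
                         .data$stratum)
  missing_sites <- setdiff(events$site_id, dep$site_id)
  if (length(missing_sites) > 0) {
    stop("events at sites absent from deployments: ",
         paste(utils::head(missing_sites, 5), collapse = ", "), call. = FALSE)
  }
  ev <- dplyr::left_join(events, dep, by = "site_id")
  local_date <- as.Date(ev$event_time + utc_offset * 3600, tz = "UTC")
  st <- sun_times(ev$lat, ev$lon, local_date, utc_offset)
  ev$diel <- ifelse(ev$event_time >= st$sunrise & ev$event_time < st$sunset,
                    "day", "night")
  ev
}

#' Season of a calendar month
#'
#' Seasons follow the study's phenology-adjusted mapping: spring is
#' February-April, summer May-July, autumn August-October, winter
#' November-January (autumn shifted to cover peak berry abundance and
#' hyperphagia). Spring is the factor reference level so that seasonal
#' model coefficients are contrasts against spring.
#'
#' @param month Integer month 1-12, a `Date`, or a `"YYYY-MM"` string.
#' @return Factor with levels spring, summer, autumn, winter.
#' @examples
#' season_of(2) # spring
#' season_of(10) # autumn
#' @export
season_of <- function(month) {
  if (inherits(month, "Date")) {
    month <- as.integer(format(month, "%m"))
  } else if (is.character(month)) {
    month <- as.integer(substr(month, 6, 7))
  }
  stopifnot(all(month %in% 1:12))
  season <- dplyr::case_when(
    month %in% 2:4 ~ "spring",
    month %in% 5:7 ~ "summer",
    month %in% 8:10 ~ "autumn",
    TRUE ~ "winter"
  )
  factor(season, levels = c("spring", "summer", "autumn", "winter"))
}

#' Site-by-month count and effort table
#'
#' Sums independent events per site and calendar month and joins the
#' active-day effort from the deployment table, producing the modelling
#' unit: one row per site x month (the full study grid, e.g. 54 cameras x
#' 13 months = 702 rows), with the season attached. Months are bounded in
#' local civil time.
#'
#' @param events Tibble from [independent_events()].
#' @param deployments Deployment table with `site_id`, `stratum`, `month`
#'   (`"YYYY-MM"`) and `active_days` columns (one row per site-month).
#' @param utc_offset Hours added to UTC when assigning events to months.
#' @return Tibble with `site_id`, `month`, `stratum`, `count`, `effort`,
#'   `season`.
#' @export
monthly_counts <- function(events, deployments, utc_offset = -8) {
  stopifnot(all(c("site_id", "month", "active_days") %in% names(deployments)))
  ev_month <- format(events$event_time + utc_offset * 3600, "%Y-%m", tz = "UTC")
  key_dep <- paste(deployments$site_id, deployments$month)
  key_ev <- paste(events$site_id, ev_month)
  bad <- !(key_ev %in% key_dep)
  if (any(bad)) {
    stop("events fall outside any deployment site-month: ",
         paste(utils::head(unique(key_ev[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  counts <- tibble::tibble(site_id = events$site_id, month = ev_month) |>
    dplyr::count(.data$site_id, .data$month, name = "count")
  deployments |>
    dplyr::select(dplyr::any_of(c("site_id", "month", "stratum", "active_days"))) |>
    dplyr::left_join(counts, by = c("site_id", "month")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      effort = .data$active_days,
      season = season_of(.data$month)
    ) |>
    dplyr::select(-"active_days") |>
    dplyr::arrange(.data$site_id, .data$month)
}

#' Monthly detection rate
#'
#' The detection rate used for plotting habitat use:
#' `(count / active days) * days in month`, i.e. the count rescaled to a
#' fully active month. Site-months with zero effort have no defined rate
#' and get `NA` (not zero).
#'
#' @param site_months Tibble from [monthly_counts()].
#' @return Input with a `rate` column appended.
#' @export
detection_rate <- function(site_months) {
  dim_days <- days_in_month(site_months$month)
  dplyr::mutate(site_months,
    rate = dplyr::if_else(.data$effort > 0,
                          .data$count / .data$effort * dim_days,
                          NA_real_)
  )
}

days_in_month <- function(month) {
  first <- as.Date(paste0(month, "-01"))
  nxt <- vapply(first, function(d) seq(d, by = "month", length.out = 2)[2],
                numeric(1))
  as.integer(nxt - as.numeric(first))
}
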