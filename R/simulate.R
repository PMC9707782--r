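#' Configuration of a synthetic camera-trap study
#'
#' Collects every parameter of the synthetic-study generator. The defaults
#' emulate the motivating study design: 54 cameras in three strata (11
#' urban, 19 rural, 24 wild) monitored over 13 monthly occasions starting
#' mid-July, variable monthly effort with camera outages, detection counts
#' from a zero-inflated negative binomial with a site random intercept and
#' a strong seasonal cycle peaking in early autumn (about 80 percent of
#' site-months have zero detections), and stratum-dependent nocturnal
#' fractions (urban 0.52, rural 0.47, wild 0.22).
#'
#' The generating count model is
#' `log mu = beta0 + beta_stratum + season_amp * cos(2 pi (m - season_peak)
#' / 12) + u_site + log(effort)`, `u_site ~ N(0, sigma_site^2)`, with
#' zero-inflation probability `zi_prob` and nb2 dispersion `theta`.
#'
#' @param strata_sizes Named integer vector of cameras per stratum.
#' @param start_month First survey month, `"YYYY-MM"`.
#' @param n_months Number of monthly occasions.
#' @param beta0 Baseline (wild) log detection rate per active day.
#' @param beta_stratum Named log-rate contrasts for urban and rural against
#'   wild.
#' @param season_amp,season_peak Amplitude (log scale) and peak calendar
#'   month of the seasonal activity cycle.
#' @param sigma_site Random-intercept standard deviation.
#' @param family `"nb2"` or `"nb1"`; `dispersion` is theta (nb2) or alpha
#'   (nb1).
#' @param dispersion NB dispersion parameter.
#' @param zi_prob Zero-inflation probability.
#' @param nocturnal_probs Named per-stratum probability that an event is
#'   nocturnal.
#' @param outage_prob Daily probability a camera is inactive.
#' @param center_latlon Latitude/longitude of the study-area centre, used
#'   for solar geometry.
#' @param utc_offset Local civil offset from UTC in hours.
#' @param gap Independence gap in minutes enforced between generated
#'   records.
#' @param seed RNG seed for the whole bundle.
#' @return List of class `btk_truth`.
#' @export
truth_config <- function(strata_sizes = c(urban = 11, rural = 19, wild = 24),
                         start_month = "2018-07",
                         n_months = 13,
                         beta0 = -4.93,
                         beta_stratum = c(urban = 0.5, rural = 1.5),
                         season_amp = 1.8,
                         season_peak = 8.7,
                         sigma_site = 0.8,
                         family = "nb2",
                         dispersion = 0.8,
                         zi_prob = 0.33,
                         nocturnal_probs = c(urban = 0.52, rural = 0.47,
                                             wild = 0.22),
                         outage_prob = 0.12,
                         center_latlon = c(48.37, -123.73),
                         utc_offset = -8,
                         gap = 30,
                         seed = 1) {
  stopifnot(all(strata_sizes > 0), n_months >= 1,
            zi_prob >= 0, zi_prob <= 1,
            all(nocturnal_probs >= 0 & nocturnal_probs <= 1),
            outage_prob >= 0, outage_prob < 1,
            sigma_site >= 0, dispersion > 0)
  structure(as.list(environment()), class = "btk_truth")
}

study_months <- function(start_month, n_months) {
  format(seq(as.Date(paste0(start_month, "-01")), by = "month",
             length.out = n_months), "%Y-%m")
}

# planar metre offsets -> lat/lon around the study centre
planar_to_latlon <- function(x, y, center_latlon) {
  lat <- center_latlon[1] + y / 111320
  lon <- center_latlon[2] + x / (111320 * cos(center_latlon[1] * pi / 180))
  list(lat = lat, lon = lon)
}

# Site layout: urban cluster at the town centre, rural ring, wild outskirts.
simulate_sites <- function(truth) {
  sizes <- truth$strata_sizes
  strata <- rep(names(sizes), sizes)
  n <- sum(sizes)
  r <- numeric(n)
  r[strata == "urban"] <- stats::runif(sizes[["urban"]], 100, 900)
  r[strata == "rural"] <- stats::runif(sizes[["rural"]], 1000, 2500)
  r[strata == "wild"] <- stats::runif(sizes[["wild"]], 3000, 5000)
  theta <- stats::runif(n, 0, 2 * pi)
  x <- r * cos(theta)
  y <- r * sin(theta)
  ll <- planar_to_latlon(x, y, truth$center_latlon)
  tibble::tibble(
    site_id = sprintf("S%02d", seq_len(n)),
    stratum = factor(strata, levels = c("wild", "rural", "urban")),
    x = x, y = y, lat = ll$lat, lon = ll$lon
  )
}

# Per-site and per-site-month covariates with the study's broad structure:
# human/road/trail densities decline from town outward, elevation rises,
# EVI follows a summer-peaked sinusoid (higher in wild forest), conflict
# probability tracks human density and season.
simulate_covariates <- function(truth, sites) {
  months <- study_months(truth$start_month, truth$n_months)
  d <- sqrt(sites$x^2 + sites$y^2)
  n <- nrow(sites)
  hd <- 2000 * exp(-d / 900) * exp(stats::rnorm(n, 0, 0.4)) +
    stats::runif(n, 0, 10)
  rd <- pmax(0, 8 * exp(-d / 1500) + stats::rnorm(n, 0, 1.5))
  td <- pmax(0, 2 + 1.5 * (sites$stratum == "wild") + stats::rnorm(n, 0, 1))
  ele <- pmax(0, 30 + 0.06 * d + stats::rnorm(n, 0, 25))
  durb <- pmax(0, d - 900 + stats::rnorm(n, 0, 100))
  # agriculture sits in the rural ring
  dag <- pmax(0, abs(d - 1800) + stats::rnorm(n, 0, 150))
  dw <- pmax(0, abs(sites$y - 500) * 0.8 + stats::rnorm(n, 0, 80))
  con <- stats::rpois(n, lambda = 4 * hd / (max(hd) + 1) + 0.1)

  per_site <- tibble::tibble(
    site_id = sites$site_id, stratum = sites$stratum,
    HD = hd, RD = rd, TD = td, Ele = ele,
    DUrb = durb, DAg = dag, DW = dw, Con = con
  )

  mnum <- as.integer(substr(months, 6, 7))
  grid <- tidyr::expand_grid(site_id = sites$site_id, month = months)
  grid$mnum <- mnum[match(grid$month, months)]
  grid <- dplyr::left_join(grid, per_site, by = "site_id")
  # EVI: summer-peaked sinusoid, greener in forested wild sites
  evi_base <- 0.30 + 0.06 * (grid$stratum == "wild") +
    0.03 * (grid$stratum == "rural")
  grid$EVI <- pmin(0.95, pmax(0.05,
    evi_base + 0.15 * cos(2 * pi * (grid$mnum - 7) / 12) +
      stats::rnorm(nrow(grid), 0, 0.02)))
  # salmon presence: sites near freshwater, autumn run
  grid$Sal <- as.integer(grid$DW < 150 & grid$mnum %in% 9:11)
  # seasonal conflict probability: rises with human density, peaks
  # late summer/autumn
  grid$season <- season_of(grid$mnum)
  season_shift <- c(spring = -0.5, summer = 0.4, autumn = 0.8,
                    winter = -0.7)
  grid$conflict_prob <- stats::plogis(
    -1.5 + 1.2 * as.numeric(scale(log1p(grid$HD))) +
      season_shift[as.character(grid$season)])
  dplyr::select(grid, -"mnum")
}

# Deployment calendar with daily outages; returns one row per site-month.
simulate_effort <- function(truth, sites) {
  months <- study_months(truth$start_month, truth$n_months)
  first <- as.Date(paste0(months, "-01"))
  ndays <- days_in_month(months)
  deploy_day <- sample(18:31, nrow(sites), replace = TRUE) # mid-first-month
  retrieve_day <- sample(14:19, nrow(sites), replace = TRUE)
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    avail <- ndays
    avail[1] <- ndays[1] - deploy_day[i] + 1
    avail[length(avail)] <- min(retrieve_day[i], ndays[length(ndays)])
    active <- stats::rbinom(length(avail), avail, 1 - truth$outage_prob)
    tibble::tibble(
      site_id = sites$site_id[i], stratum = sites$stratum[i],
      lat = sites$lat[i], lon = sites$lon[i],
      month = months, active_days = active,
      start_day = c(deploy_day[i], rep(1, length(months) - 1))
    )
  })
}

#' Simulate site-month detection counts under a truth configuration
#'
#' Draws counts from the zero-inflated negative binomial mixed model the
#' analysis assumes: `y ~ ZI-NB(mu, dispersion, zi_prob)` with
#' `log mu = x'beta + u_site + log(effort)`. Site-months with zero effort
#' get zero counts.
#'
#' @param truth A [truth_config()].
#' @param deployments Site-month effort table (from the generator, or
#'   user-supplied with `site_id`, `stratum`, `month`, `active_days`).
#' @return `deployments` with a `count` column and the site random effects
#'   as the `"u_site"` attribute.
#' @export
simulate_counts <- function(truth, deployments) {
  mnum <- as.integer(substr(deployments$month, 6, 7))
  bs <- c(truth$beta_stratum, wild = 0)
  eta <- truth$beta0 + bs[as.character(deployments$stratum)] +
    truth$season_amp * cos(2 * pi * (mnum - truth$season_peak) / 12)
  sites <- unique(deployments$site_id)
  u <- stats::rnorm(length(sites), 0, truth$sigma_site)
  names(u) <- sites
  mu <- exp(eta + u[deployments$site_id]) * deployments$active_days
  n <- length(mu)
  size <- if (truth$family == "nb2") truth$dispersion else mu / truth$dispersion
  y <- ifelse(stats::runif(n) < truth$zi_prob, 0L,
              stats::rnbinom(n, size = pmax(size, 1e-8), mu = mu))
  y[deployments$active_days == 0] <- 0L
  out <- dplyr::mutate(deployments, count = as.integer(y))
  attr(out, "u_site") <- u
  out
}

#' Simulate detection-record timestamps for given counts
#'
#' Turns site-month event counts into raw detection records: each event is
#' nocturnal with its stratum's probability, lands on a uniformly chosen
#' active day of the month, and gets a uniform time inside the matching
#' solar window (between sunrise and sunset for day events; before sunrise
#' or after sunset, same civil date, for night events). Records at a site
#' are kept at least the independence gap apart so the event bookkeeping
#' round-trips exactly.
#'
#' @param counted Site-month tibble with `count` (from [simulate_counts()])
#'   plus `lat`, `lon`, `start_day`.
#' @param truth The [truth_config()].
#' @return Tibble of detection records: `site_id`, `timestamp` (POSIXct
#'   UTC), `species`, `diel_true`.
#' @export
simulate_timestamps <- function(counted, truth) {
  rows <- counted[counted$count > 0, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(tibble::tibble(site_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          species = character(), diel_true = character()))
  }
  gap_sec <- truth$gap * 60
  recs <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    ndays <- days_in_month(r$month)
    lo <- if (!is.null(r$start_day)) r$start_day else 1L
    days <- sample(seq(lo, ndays), r$count, replace = TRUE)
    night <- stats::runif(r$count) <
      truth$nocturnal_probs[[as.character(r$stratum)]]
    t <- vapply(seq_len(r$count), function(j) {
      draw_event_time(r$month, days[j], night[j], r$lat, r$lon,
                      truth$utc_offset)
    }, numeric(1))
    tibble::tibble(site_id = r$site_id, month = r$month, day = days,
                   lat = r$lat, lon = r$lon, t = t, night = night)
  })
  # enforce the independence gap within each site by redrawing clashing
  # records inside the same solar window (collisions are rare at
  # study-scale counts, so this converges almost immediately)
  recs <- recs |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(d, key) {
      for (pass in 1:200) {
        d <- d[order(d$t), ]
        bad <- which(diff(d$t) < gap_sec) + 1L
        if (length(bad) == 0) break
        d$t[bad] <- vapply(bad, function(j) {
          draw_event_time(d$month[j], d$day[j], d$night[j], d$lat[j],
                          d$lon[j], truth$utc_offset)
        }, numeric(1))
      }
      d
    }) |>
    dplyr::ungroup()
  tibble::tibble(
    site_id = recs$site_id,
    timestamp = as.POSIXct(recs$t, origin = "1970-01-01", tz = "UTC"),
    species = "black bear",
    diel_true = ifelse(recs$night, "night", "day")
  ) |>
    dplyr::arrange(.data$site_id, .data$timestamp)
}

# one uniform instant (seconds since epoch, UTC) on a local civil date,
# inside the day window or its complement
draw_event_time <- function(month, day, night, lat, lon, utc_offset) {
  date <- as.Date(sprintf("%s-%02d", month, day))
  st <- sun_times(lat, lon, date, utc_offset)
  # local midnight in UTC seconds
  mid <- as.numeric(as.POSIXct(paste0(date, " 00:00:00"), tz = "UTC")) -
    utc_offset * 3600
  rise <- as.numeric(st$sunrise)
  set <- as.numeric(st$sunset)
  if (!night) {
    stats::runif(1, rise, set)
  } else {
    # night within the same civil date: [midnight, sunrise) u [sunset, +24h)
    pre <- rise - mid
    post <- mid + 86400 - set
    u <- stats::runif(1, 0, pre + post)
    if (u < pre) mid + u else set + (u - pre)
  }
}

#' Generate a complete synthetic study
#'
#' Produces a `StudyBundle`: site layout, deployment/effort calendar,
#' covariate table, true site-month counts, raw detection records whose
#' independent-event structure reproduces those counts exactly, a gridded
#' human-density layer and conflict-report points for the buffer-extraction
#' stage, and the truth parameters for recovery tests. Fully reproducible
#' from the seed in the configuration.
#'
#' @param truth A [truth_config()].
#' @return List of class `btk_bundle` with elements `sites`, `deployments`,
#'   `covariates`, `site_months` (with true counts), `records`, `hd_grid`,
#'   `conflict_points`, `truth`.
#' @export
generate_study <- function(truth = truth_config()) {
  stopifnot(inherits(truth, "btk_truth"))
  with_preserved_seed(truth$seed, {
    sites <- simulate_sites(truth)
    covariates <- simulate_covariates(truth, sites)
    deployments <- simulate_effort(truth, sites)
    site_months <- simulate_counts(truth, deployments)
    records <- simulate_timestamps(site_months, truth)

    # gridded human-density layer over the site bounding box (25 m cells)
    pad <- 300
    x0 <- floor(min(sites$x) - pad); y0 <- floor(min(sites$y) - pad)
    nx <- ceiling((max(sites$x) + pad - x0) / 25)
    ny <- ceiling((max(sites$y) + pad - y0) / 25)
    cx <- x0 + (seq_len(nx) - 0.5) * 25
    cy <- y0 + (ny - seq_len(ny) + 0.5) * 25 # top row first
    dd <- sqrt(outer(cy^2, cx^2, `+`))
    hd_grid <- grid_layer(2000 * exp(-dd / 900), origin = c(x0, y0),
                          cell_size = 25)

    # conflict-report points concentrated where human density is high
    n_con <- sum(covariates$Con[!duplicated(covariates$site_id)])
    src <- sample(nrow(sites), max(n_con, 1), replace = TRUE,
                  prob = exp(sqrt(sites$x^2 + sites$y^2) / -900))
    conflict_points <- tibble::tibble(
      x = sites$x[src] + stats::rnorm(length(src), 0, 250),
      y = sites$y[src] + stats::rnorm(length(src), 0, 250),
      date = as.Date(paste0(truth$start_month, "-01")) +
        sample.int(365, length(src), replace = TRUE)
    )

    structure(list(
      sites = sites, deployments = deployments, covariates = covariates,
      site_months = site_months, records = records,
      hd_grid = hd_grid, conflict_points = conflict_points,
      truth = truth
    ), class = "btk_bundle")
  })
}

#' @export
print.btk_bundle <- function(x, ...) {
  cat(sprintf(
    "<btk_bundle> %d sites x %d months (%d site-month rows), %d detection records\n",
    nrow(x$sites), x$truth$n_months, nrow(x$site_months), nrow(x$records)))
  cat(sprintf("  zero site-months: %.1f%%; seed %d\n",
              100 * mean(x$site_months$count == 0), x$truth$seed))
  invisible(x)
}

#' Assemble the modelling table from a study bundle
#'
#' Joins the true site-month counts with the covariates and standardizes
#' the continuous covariates, yielding the table [fit_zinb()] consumes.
#'
#' @param bundle A `btk_bundle`.
#' @param standardize_covariates Standardize continuous covariates
#'   (default TRUE).
#' @return Site-month tibble with `count`, `effort`, covariates, `season`,
#'   `stratum`.
#' @export
bundle_model_table <- function(bundle, standardize_covariates = TRUE) {
  tab <- bundle$site_months |>
    dplyr::transmute(.data$site_id, .data$month,
                     stratum = .data$stratum,
                     count = .data$count, effort = .data$active_days) |>
    dplyr::left_join(
      dplyr::select(bundle$covariates, -"stratum"),
      by = c("site_id", "month")
    )
  if (standardize_covariates) {
    tab <- standardize(tab, cols = c("HD", "RD", "TD", "Ele", "DUrb",
                                     "DAg", "DW", "EVI", "Con",
                                     "conflict_prob"))
  }
  tab
}
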