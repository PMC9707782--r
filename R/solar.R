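#' Sunrise and sunset for a site and date
#'
#' Computes sunrise and sunset instants from the NOAA low-precision solar
#' position algorithm (Meeus-style series for the solar longitude, equation
#' of time and declination), using the conventional -0.833 degree solar
#' altitude for rise/set so that atmospheric refraction and the solar disc
#' radius are accounted for. Detections are later labelled diurnal or
#' nocturnal by comparing their timestamps against these instants.
#'
#' Times are returned as POSIXct in UTC; `utc_offset` only shifts the civil
#' date for which the event is computed (the study uses a fixed offset, no
#' daylight-saving logic). Accuracy is within about two minutes of reference
#' ephemeris calculators for mid-latitudes.
#'
#' @param latitude,longitude Site coordinates in decimal degrees
#'   (longitude positive east). `abs(latitude)` must be below 66.5 so that
#'   the sun rises and sets every day; polar day/night is outside the study
#'   envelope and raises an error.
#' @param date A `Date` (or something coercible) giving the civil date.
#' @param utc_offset Hours to add to UTC for local civil time (default -8,
#'   the study region's standard time).
#' @return A tibble with one row per date: `date`, `sunrise`, `sunset`
#'   (POSIXct, UTC), and `day_length_hours`.
#' @examples
#' sun_times(48.37, -123.73, as.Date("2018-09-15"))
#' @export
sun_times <- function(latitude, longitude, date, utc_offset = -8) {
  date <- as.Date(date)
  n <- max(length(latitude), length(longitude), length(date))
  latitude <- rep_len(latitude, n)
  longitude <- rep_len(longitude, n)
  date <- rep_len(date, n)
  if (any(!is.finite(latitude)) || any(abs(latitude) >= 66.5)) {
    stop("sun_times() supports |latitude| < 66.5 degrees only ",
         "(polar day/night is outside the study envelope)", call. = FALSE)
  }

  # First pass at local solar noon, then one refinement pass at the
  # provisional rise/set times (the declination and equation of time drift
  # enough within a day to matter at the minute level).
  noon_guess <- 720 - 4 * longitude - utc_offset * 60 # minutes UTC, approx
  jd <- julian_day(date) + noon_guess / 1440
  s <- solar_geometry(jd)
  ha <- hour_angle_deg(latitude, s$declination)
  solar_noon <- 720 - 4 * longitude - s$eqtime # minutes past UTC midnight
  rise1 <- solar_noon - 4 * ha
  set1 <- solar_noon + 4 * ha

  rise <- refine_riseset(date, latitude, longitude, rise1)
  set <- refine_riseset(date, latitude, longitude, set1)

  midnight <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  tibble::tibble(
    date = date,
    sunrise = midnight + rise * 60,
    sunset = midnight + set * 60,
    day_length_hours = (set - rise) / 60
  )
}

# One refinement evaluation of the rise/set time (minutes past UTC midnight)
refine_riseset <- function(date, latitude, longitude, t_minutes) {
  jd <- julian_day(date) + t_minutes / 1440
  s <- solar_geometry(jd)
  ha <- hour_angle_deg(latitude, s$declination)
  solar_noon <- 720 - 4 * longitude - s$eqtime
  ifelse(t_minutes < solar_noon, solar_noon - 4 * ha, solar_noon + 4 * ha)
}

julian_day <- function(date) {
  # Days since the Julian epoch; as.Date epoch 1970-01-01 is JD 2440587.5
  as.numeric(date) + 2440587.5
}

# Solar declination (radians) and equation of time (minutes) at a Julian day
solar_geometry <- function(jd) {
  t <- (jd - 2451545) / 36525 # Julian centuries from J2000.0
  deg2rad <- pi / 180

  l0 <- (280.46646 + t * (36000.76983 + t * 0.0003032)) %% 360
  m <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  mr <- m * deg2rad
  eq_center <- sin(mr) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * mr) * (0.019993 - 0.000101 * t) +
    sin(3 * mr) * 0.000289
  true_long <- l0 + eq_center
  omega <- (125.04 - 1934.136 * t) * deg2rad
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)

  obliq0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  obliq <- obliq0 + 0.00256 * cos(omega)
  obr <- obliq * deg2rad

  decl <- asin(sin(obr) * sin(app_long * deg2rad))

  y <- tan(obr / 2)^2
  l0r <- l0 * deg2rad
  eqtime <- 4 / deg2rad * (
    y * sin(2 * l0r) - 2 * ecc * sin(mr) +
      4 * ecc * y * sin(mr) * cos(2 * l0r) -
      0.5 * y^2 * sin(4 * l0r) - 1.25 * ecc^2 * sin(2 * mr)
  )
  list(declination = decl, eqtime = eqtime)
}

# Sunrise hour angle in degrees at solar altitude -0.833
hour_angle_deg <- function(latitude, declination) {
  deg2rad <- pi / 180
  latr <- latitude * deg2rad
  cos_ha <- cos(90.833 * deg2rad) / (cos(latr) * cos(declination)) -
    tan(latr) * tan(declination)
  if (any(cos_ha <= -1 | cos_ha >= 1)) {
    stop("sun does not rise or set on this date at this latitude ",
         "(polar day/night)", call. = FALSE)
  }
  acos(cos_ha) / deg2rad
}
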