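# Sunrise/sunset/day-length from the NOAA low-accuracy solar position
# method: Julian century -> solar mean anomaly & ecliptic longitude ->
# declination and equation of time -> hour angle at zenith 90.833 deg
# (0.833 deg refraction + solar-disc correction).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Julian day number of a calendar date at 00:00 UT (Gregorian).
julian_day <- function(date) {
  d <- as.POSIXlt(as.Date(date))
  y <- d$year + 1900L; m <- d$mon + 1L; dd <- d$mday
  if (m <= 2L) { y <- y - 1L; m <- m + 12L }
  a <- floor(y / 100)
  b <- 2 - a + floor(a / 4)
  floor(365.25 * (y + 4716)) + floor(30.6001 * (m + 1)) + dd + b - 1524.5
}

# Solar declination (deg) and equation of time (minutes) at Julian century T.
solar_position <- function(T) {
  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  Mr <- deg2rad(M)
  C <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) +
    sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- deg2rad(125.04 - 1934.136 * T)
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega)
  epsr <- deg2rad(eps)
  decl <- rad2deg(asin(sin(epsr) * sin(deg2rad(app_long))))
  y <- tan(epsr / 2)^2
  L0r <- deg2rad(L0)
  eot <- 4 * rad2deg(
    y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y * y * sin(4 * L0r) - 1.25 * e * e * sin(2 * Mr))
  list(declination = decl, eot = eot)
}

# cos(hour angle) at the standard sunrise/sunset zenith of 90.833 deg.
cos_hour_angle <- function(lat, decl) {
  latr <- deg2rad(lat); dr <- deg2rad(decl)
  cos(deg2rad(90.833)) / (cos(latr) * cos(dr)) - tan(latr) * tan(dr)
}

#' Sunrise, sunset and day length for a date and site
#'
#' NOAA solar-calculator method with the conventional zenith of 90.833
#' degrees (atmospheric refraction of 0.833 degrees plus the solar disc's
#' half-diameter). Declination and equation of time are evaluated at solar
#' noon and refined once at the provisional event time; results are rounded
#' to the nearest minute in the stated UTC offset, matching the NOAA web
#' calculator's display. Polar day/night dates are not supported.
#'
#' @param date calendar date (`Date` or string).
#' @param latitude,longitude site in decimal degrees (north/east positive);
#'   `|latitude|` must stay below the polar circle (66.5).
#' @param utc_offset hours ahead of UTC for the reported clock times (1 for
#'   Central European standard time, 2 for its DST variant).
#' @return A `solar_event`: list with `date`, `latitude`, `longitude`,
#'   `utc_offset`, `sunrise_local`/`sunset_local` ("HH:MM"),
#'   `sunrise_min`/`sunset_min` (minutes after local midnight) and
#'   `day_length` (minutes).
#' @export
sunrise_sunset <- function(date, latitude, longitude, utc_offset = 1) {
  if (abs(latitude) >= 66.5)
    stop("unsupported: polar-circle latitudes (|lat| >= 66.5) are not handled")
  date <- as.Date(date)
  jd0 <- julian_day(date)

  event_utc_min <- function(rise) {
    # pass 1: solar noon estimate
    T <- (jd0 + 0.5 - 2451545) / 36525
    sp <- solar_position(T)
    noon <- 720 - 4 * longitude - sp$eot
    cH <- cos_hour_angle(latitude, sp$declination)
    if (abs(cH) > 1) stop("unsupported: sun does not rise/set on this date here")
    ha <- rad2deg(acos(cH))
    t_min <- if (rise) noon - 4 * ha else noon + 4 * ha
    # pass 2: re-evaluate at the provisional event instant
    T <- (jd0 + t_min / 1440 - 2451545) / 36525
    sp <- solar_position(T)
    noon <- 720 - 4 * longitude - sp$eot
    cH <- cos_hour_angle(latitude, sp$declination)
    if (abs(cH) > 1) stop("unsupported: sun does not rise/set on this date here")
    ha <- rad2deg(acos(cH))
    if (rise) noon - 4 * ha else noon + 4 * ha
  }

  rise_min <- round(event_utc_min(TRUE) + 60 * utc_offset)
  set_min <- round(event_utc_min(FALSE) + 60 * utc_offset)
  hhmm <- function(m) sprintf("%02d:%02d", (m %/% 60) %% 24, m %% 60)
  structure(list(date = date, latitude = latitude, longitude = longitude,
                 utc_offset = utc_offset,
                 sunrise_local = hhmm(rise_min), sunset_local = hhmm(set_min),
                 sunrise_min = rise_min, sunset_min = set_min,
                 day_length = set_min - rise_min),
            class = "solar_event")
}

#' @export
print.solar_event <- function(x, ...) {
  cat(sprintf("%s @ (%.2f, %.2f) UTC%+d: sunrise %s, sunset %s, day %d min\n",
              format(x$date), x$latitude, x$longitude, x$utc_offset,
              x$sunrise_local, x$sunset_local, x$day_length))
  invisible(x)
}

#' Day length over a date range
#'
#' @param dates vector of dates (contiguity is the caller's concern).
#' @param latitude,longitude,utc_offset as in [sunrise_sunset()].
#' @return data.frame with `date`, `sunrise`, `sunset`, `day_length_min`.
#' @export
day_length_series <- function(dates, latitude, longitude, utc_offset = 1) {
  dates <- as.Date(dates)
  ev <- lapply(dates, sunrise_sunset, latitude = latitude,
               longitude = longitude, utc_offset = utc_offset)
  data.frame(date = dates,
             sunrise = vapply(ev, `[[`, "", "sunrise_local"),
             sunset = vapply(ev, `[[`, "", "sunset_local"),
             day_length_min = vapply(ev, `[[`, 0, "day_length"))
}
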