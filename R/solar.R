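#' Sunset and sunrise times for a site (NOAA solar position method)
#'
#' Computes local sunset on `night_date` and sunrise on the following morning,
#' defining the observation window of one bat-night. Times are local standard
#' clock time for the site's fixed UTC offset; no daylight-saving inference is
#' performed. The algorithm is the NOAA solar calculator formulation
#' (Meeus-based low-precision series), accurate to well under a minute at the
#' latitudes supported here.
#'
#' @param site a site object from [site()] or one entry of [read_sites()].
#' @param night_date `Date` vector: the calendar date of the sunset that opens
#'   each night.
#' @return a data.frame with columns `site_id`, `night_date`, `sunset`,
#'   `sunrise` (POSIXct, local clock time).
#' @details Supported latitudes are |lat| < 60 degrees; polar day/night (no
#'   sunrise or sunset) is an error. The sunrise returned is the one of
#'   `night_date + 1`, so `sunset < sunrise` always holds and the night spans
#'   6-16 hours at supported latitudes.
#' @export
night_table <- function(site, night_date) {
  stopifnot(inherits(site, "bn_site"))
  night_date <- as.Date(night_date)
  if (abs(site$latitude) >= 60) {
    stop("latitude ", site$latitude, " outside supported range (|lat| < 60)")
  }
  ss <- vapply(as.numeric(night_date), function(d) {
    solar_event(as.Date(d, origin = "1970-01-01"), site$latitude,
                site$longitude, site$utc_offset_hours, rising = FALSE)
  }, numeric(1))
  sr <- vapply(as.numeric(night_date) + 1, function(d) {
    solar_event(as.Date(d, origin = "1970-01-01"), site$latitude,
                site$longitude, site$utc_offset_hours, rising = TRUE)
  }, numeric(1))
  sunset <- local_midnight(night_date) + ss * 3600
  sunrise <- local_midnight(night_date + 1) + sr * 3600
  span_h <- as.numeric(difftime(sunrise, sunset, units = "hours"))
  if (any(span_h < 6 | span_h > 16)) {
    stop("computed night length outside 6-16 h; site/date out of supported range")
  }
  data.frame(site_id = site$site_id, night_date = night_date,
             sunset = sunset, sunrise = sunrise, stringsAsFactors = FALSE)
}

#' @rdname night_table
#' @param date calendar date (length 1) for a single sunset/sunrise pair.
#' @export
compute_sun_times <- function(site, date) {
  night_table(site, date)
}

# POSIXct midnight of a calendar date, on the internal fixed-offset clock.
# All datetimes in the package are local standard time carried in the "UTC"
# timezone slot (a fixed-offset clock: no DST rules are ever applied).
local_midnight <- function(date) {
  as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
}

# Hour-of-day (local) of one sunrise/sunset. NOAA spreadsheet algorithm:
# iterate the event time because the solar coordinates move within the day.
solar_event <- function(date, lat, lon, utc_offset, rising) {
  jd <- as.numeric(date) + 2440587.5 # Julian day at 00:00 UTC of `date`
  t_frac <- if (rising) 0.25 else 0.75
  for (i in 1:3) {
    jc <- (jd + t_frac - utc_offset / 24 - 2451545) / 36525
    gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
    gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
    eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
    seoc <- sin(rad(gmas)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
      sin(rad(2 * gmas)) * (0.019993 - 0.000101 * jc) +
      sin(rad(3 * gmas)) * 0.000289
    stl <- gmls + seoc
    sal <- stl - 0.00569 - 0.00478 * sin(rad(125.04 - 1934.136 * jc))
    moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
    oc <- moe + 0.00256 * cos(rad(125.04 - 1934.136 * jc))
    decl <- deg(asin(sin(rad(oc)) * sin(rad(sal))))
    vary <- tan(rad(oc / 2))^2
    eot <- 4 * deg(vary * sin(2 * rad(gmls)) -
                     2 * eeo * sin(rad(gmas)) +
                     4 * eeo * vary * sin(rad(gmas)) * cos(2 * rad(gmls)) -
                     0.5 * vary^2 * sin(4 * rad(gmls)) -
                     1.25 * eeo^2 * sin(2 * rad(gmas)))
    # zenith 90.833 deg: geometric horizon + standard refraction + solar radius
    cosha <- cos(rad(90.833)) / (cos(rad(lat)) * cos(rad(decl))) -
      tan(rad(lat)) * tan(rad(decl))
    if (cosha > 1 || cosha < -1) {
      stop("polar day/night at latitude ", lat, " on ", format(date),
           "; outside supported range")
    }
    ha <- deg(acos(cosha))
    solarnoon <- (720 - 4 * lon - eot + utc_offset * 60) / 1440
    t_frac <- if (rising) solarnoon - ha * 4 / 1440 else solarnoon + ha * 4 / 1440
  }
  t_frac * 24
}

rad <- function(x) x * pi / 180
deg <- function(x) x * 180 / pi
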