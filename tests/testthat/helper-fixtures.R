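# Shared fixtures: a study-latitude site, its night table, and builders for
# coded-event and detection tables. All fixtures are constructed in code.

fx_site <- function() site("SIM", 24.2, -110.3, -7)

fx_night <- function(date = as.Date("2016-04-15")) night_table(fx_site(), date)

# coded events at given minute offsets from sunset, alternating from EXIT
fx_events <- function(offsets_min, night = fx_night(), tag = "b1") {
  n <- length(offsets_min)
  data.frame(tag_id = tag, night_date = night$night_date, site_id = night$site_id,
             timestamp = night$sunset + offsets_min * 60,
             direction = rep(c("EXIT", "ENTRY"), length.out = n),
             roost_id = night$site_id, ordinal = seq_len(n),
             pre_sunset = offsets_min < 0, stringsAsFactors = FALSE)
}

# raw detections CSV written to a tempfile; rows are c(tag, iso_ts, site, roost)
fx_detections_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("tag_id,timestamp,site_id,roost_id",
               vapply(rows, paste, "", collapse = ",")), path)
  path
}

fx_deployments <- function(tags, tagged_at = "2016-03-01 12:00:00", sex = "F",
                           repro = NA_character_) {
  data.frame(tag_id = tags,
             tagged_at = as.POSIXct(tagged_at, tz = "UTC"),
             site_id = "SIM", sex = sex, repro_condition = repro,
             stringsAsFactors = FALSE)
}

local_time <- function(x) as.POSIXct(x, tz = "UTC")
local_midnight_utc <- function(d) as.POSIXct(paste(format(d), "00:00:00"), tz = "UTC")

# Independent sunrise/sunset oracle: Spencer (1971) Fourier-series declination
# and equation of time -- a different formulation from the production code.
spencer_sun <- function(lat, lon, utc_offset, date) {
  n <- as.integer(format(date, "%j"))
  g <- 2 * pi / 365 * (n - 1)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.04089 * sin(2 * g))
  latr <- lat * pi / 180
  cosha <- (cos(90.833 * pi / 180) - sin(latr) * sin(decl)) /
    (cos(latr) * cos(decl))
  ha <- acos(cosha) * 180 / pi
  noon <- (720 - 4 * lon - eot + utc_offset * 60) / 60
  c(sunrise = noon - ha / 15, sunset = noon + ha / 15) # local hours
}
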