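#' Define a monitored roost site
#'
#' A site groups one or more roost entrances sharing a location. Where two
#' roosts sit close enough that bats switch between them within a night, set
#' `merge_roosts = TRUE` so event coding treats the pair as a single entrance
#' complex.
#'
#' @param site_id character site identifier.
#' @param latitude,longitude decimal degrees; |lat| <= 90, |lon| <= 180.
#' @param utc_offset_hours signed UTC offset of the local standard clock
#'   (e.g. -7). No daylight-saving rules are applied anywhere in the package.
#' @param roost_ids character vector of roost identifiers belonging to the site.
#' @param merge_roosts if TRUE, passages at any member roost are coded against
#'   a single shared entrance; requires at least 2 roost_ids.
#' @return an object of class `bn_site`.
#' @export
site <- function(site_id, latitude, longitude, utc_offset_hours,
                 roost_ids = site_id, merge_roosts = FALSE) {
  stopifnot(length(site_id) == 1, abs(latitude) <= 90, abs(longitude) <= 180)
  if (merge_roosts && length(roost_ids) < 2) {
    stop("merge_roosts = TRUE requires at least 2 roost_ids")
  }
  structure(list(site_id = as.character(site_id), latitude = latitude,
                 longitude = longitude, utc_offset_hours = utc_offset_hours,
                 roost_ids = as.character(roost_ids),
                 merge_roosts = isTRUE(merge_roosts)),
            class = "bn_site")
}

#' @export
print.bn_site <- function(x, ...) {
  cat(sprintf("<site %s: %.4f, %.4f (UTC%+g); roosts: %s%s>\n", x$site_id,
              x$latitude, x$longitude, x$utc_offset_hours,
              paste(x$roost_ids, collapse = ", "),
              if (x$merge_roosts) "; merged complex" else ""))
  invisible(x)
}

#' Read a site registry from YAML
#'
#' The YAML file maps site ids to entries with `latitude`, `longitude`,
#' `utc_offset_hours`, `roost_ids`, and optional `merge_roosts`.
#'
#' @param path path to the YAML file.
#' @return a named list of `bn_site` objects (class `bn_site_registry`).
#' @export
read_sites <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- lapply(names(raw), function(id) {
    s <- raw[[id]]
    site(id, s$latitude, s$longitude, s$utc_offset_hours,
         roost_ids = unlist(s$roost_ids),
         merge_roosts = isTRUE(s$merge_roosts))
  })
  names(reg) <- names(raw)
  structure(reg, class = "bn_site_registry")
}

# site lookup by roost id: returns site_id per roost, NA if unknown
roost_site_map <- function(sites) {
  if (inherits(sites, "bn_site")) sites <- list(sites)
  roosts <- unlist(lapply(sites, `[[`, "roost_ids"))
  sids <- rep(vapply(sites, `[[`, "", "site_id"),
              vapply(sites, function(s) length(s$roost_ids), 0L))
  stats::setNames(sids, roosts)
}

# Strict ISO-8601 parser for local civil datetimes ("T" or space separator,
# optional :SS). Returns POSIXct on the package's fixed-offset clock ("UTC"
# tz slot, see local_midnight). Invalid entries are an error naming the line.
parse_timestamp <- function(x, what = "timestamp") {
  x <- sub("T", " ", x, fixed = TRUE)
  x <- ifelse(grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}$", x), paste0(x, ":00"), x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}:\\d{2}$", x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  out[ok] <- as.POSIXct(x[ok], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  # as.POSIXct with format silently rolls nothing: impossible dates give NA
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("unparseable ", what, " at line ", bad[1] + 1L, ": '", x[bad[1]], "'")
  }
  out
}

#' Read a PIT-tag detection stream
#'
#' Reads comma-separated detections with header columns
#' `tag_id,timestamp,site_id,roost_id[,antenna_id]`. Timestamps must be
#' ISO-8601 local civil time. Exact duplicate rows are dropped (with a logged
#' count); near-duplicate antenna re-reads are handled later by
#' [deduplicate_bursts()].
#'
#' @param path path to the CSV file.
#' @param sites a `bn_site_registry` (or single `bn_site`) used to validate
#'   that every `roost_id` belongs to its claimed `site_id`.
#' @return a data.frame of detections sorted by `(tag_id, timestamp)`, with
#'   attribute `n_duplicates_dropped`.
#' @export
read_detections <- function(path, sites) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("tag_id", "timestamp", "site_id", "roost_id")
  if (!all(need %in% names(df))) {
    stop("detections file must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(empty_detections())
  }
  dup <- duplicated(df)
  ndup <- sum(dup)
  if (ndup > 0) {
    message(ndup, " duplicate ", if (ndup == 1) "row" else "rows", " dropped")
    df <- df[!dup, , drop = FALSE]
  }
  ts <- parse_timestamp(df$timestamp)
  map <- roost_site_map(sites)
  unknown_site <- !df$site_id %in% vapply(unclass_registry(sites), `[[`, "", "site_id")
  if (any(unknown_site)) {
    stop("unknown site_id '", df$site_id[which(unknown_site)[1]], "' in detections")
  }
  bad_roost <- is.na(map[df$roost_id]) | map[df$roost_id] != df$site_id
  if (any(bad_roost)) {
    i <- which(bad_roost)[1]
    stop("roost_id '", df$roost_id[i], "' does not belong to site '",
         df$site_id[i], "'")
  }
  out <- data.frame(tag_id = df$tag_id, timestamp = ts, site_id = df$site_id,
                    roost_id = df$roost_id,
                    antenna_id = if ("antenna_id" %in% names(df)) df$antenna_id else NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tag_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates_dropped") <- ndup
  out
}

unclass_registry <- function(sites) {
  if (inherits(sites, "bn_site")) list(sites) else unclass(sites)
}

empty_detections <- function() {
  structure(data.frame(tag_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                       site_id = character(), roost_id = character(),
                       antenna_id = character(), stringsAsFactors = FALSE),
            n_duplicates_dropped = 0L)
}

#' Write detections / coded events / metrics as CSV
#'
#' Writers matching the package's canonical CSV schemas; datetimes are written
#' as ISO-8601 with a "T" separator so a write-then-read round trip is the
#' identity.
#'
#' @param x the table to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(x, path) {
  x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tag-deployment table
#'
#' CSV with columns `tag_id,tagged_at,site_id,sex,repro_condition` and optional
#' `age_class,mass_g,forearm_mm`. One row per tag; reproductive condition may
#' be set only for females.
#'
#' @param path path to the CSV file.
#' @return a data.frame keyed by `tag_id`.
#' @export
read_deployments <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("tag_id", "tagged_at", "site_id", "sex")
  if (!all(need %in% names(df))) {
    stop("deployments file must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$tag_id)) {
    stop("duplicate tag_id in deployments: '",
         df$tag_id[duplicated(df$tag_id)][1], "'")
  }
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (!"repro_condition" %in% names(df)) df$repro_condition <- NA_character_
  df$repro_condition[df$repro_condition %in% c("", "NA")] <- NA_character_
  valid_rc <- c("nonreproductive", "pregnant", "lactating", "postlactating")
  bad <- !is.na(df$repro_condition) & !df$repro_condition %in% valid_rc
  if (any(bad)) stop("invalid repro_condition '", df$repro_condition[bad][1], "'")
  male_rc <- df$sex == "M" & !is.na(df$repro_condition)
  if (any(male_rc)) {
    stop("repro_condition set for male tag '", df$tag_id[male_rc][1], "'")
  }
  df$tagged_at <- parse_timestamp(df$tagged_at, "tagged_at")
  for (col in c("mass_g", "forearm_mm")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read daily environmental covariates
#'
#' CSV with columns `date,tmean_c,precip_mm`. Missing calendar days inside the
#' covered span are accepted and reported; rows lacking covariates are dropped
#' later, at analysis-table assembly.
#'
#' @param path path to the CSV file.
#' @return a data.frame keyed by `date`, with attribute `n_gap_days`.
#' @export
read_env <- function(path) {
  df <- utils::read.csv(path)
  need <- c("date", "tmean_c", "precip_mm")
  if (!all(need %in% names(df))) {
    stop("env file must have columns ", paste(need, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable date in env file")
  if (any(df$precip_mm < 0, na.rm = TRUE)) stop("precip_mm must be >= 0")
  gaps <- 0L
  if (nrow(df) > 1) {
    full <- seq(min(df$date), max(df$date), by = "day")
    gaps <- sum(!full %in% df$date)
    if (gaps > 0) message(gaps, " day(s) missing from env table")
  }
  attr(df, "n_gap_days") <- gaps
  df
}
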