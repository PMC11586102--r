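#' Per-bat-night activity metrics
#'
#' Computes the four activity metrics from coded exit/entry events, one row
#' per bat-night:
#'
#' * `emergence_min_after_sunset` — minutes from local sunset to the first
#'   exit (negative when the bat emerged within the pre-sunset tolerance band);
#'   the absolute clock time is kept in `emergence_clock`.
#' * `n_returns` — number of entries after the first exit.
#' * `hours_inside` — summed durations of consecutive entry-to-exit intervals
#'   (time in the roost between foraging bouts; the span before the first exit
#'   and after an unpaired final entry contribute nothing).
#' * `hours_active` — summed durations of exit-to-entry intervals (time
#'   outside the roost). A night ending on an exit leaves its final outside
#'   interval unobserved: it contributes nothing and the night is flagged
#'   `censored_open_end` rather than truncated at sunrise.
#'
#' For uncensored nights the two durations partition the span from first to
#' last event: `hours_inside + hours_active == last - first` (checked to 1 s;
#' a violation is an error naming the bat-night).
#'
#' @param events coded events from [code_directions()] / [code_events()].
#' @param nights night table with sunset/sunrise for every (site, night_date)
#'   present; taken from the `nights` attribute of `events` when NULL.
#' @return data.frame with one row per bat-night: `tag_id, night_date, site_id,
#'   emergence_min_after_sunset, emergence_clock, n_returns, hours_inside,
#'   hours_active, n_events, censored_open_end, pre_sunset_emergence`.
#' @export
compute_activity_metrics <- function(events, nights = NULL) {
  if (is.null(nights)) nights <- attr(events, "nights")
  if (is.null(nights)) stop("no night table supplied")
  if (nrow(events) == 0) return(empty_metrics())
  ev <- events[order(events$tag_id, events$night_date, events$ordinal), , drop = FALSE]
  gkey <- paste(ev$tag_id, format(ev$night_date))
  grp <- cumsum(!duplicated(gkey))
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  t <- as.numeric(ev$timestamp)
  # within-night consecutive gaps; odd-ordinal gaps are exit->entry (active),
  # even-ordinal gaps entry->exit (inside)
  gap <- c(diff(t), 0)
  gap[last] <- 0
  active_s <- rowsum(gap * (ev$ordinal %% 2 == 1), grp)[, 1]
  inside_s <- rowsum(gap * (ev$ordinal %% 2 == 0), grp)[, 1]
  n_events <- tabulate(grp)
  n_returns <- rowsum(as.numeric(ev$direction == "ENTRY"), grp)[, 1]
  ni <- match(paste(ev$site_id[first], format(ev$night_date[first])),
              paste(nights$site_id, format(nights$night_date)))
  if (anyNA(ni)) {
    stop("night table lacks (", ev$site_id[first][which(is.na(ni))[1]], ", ",
         format(ev$night_date[first][which(is.na(ni))[1]]), ")")
  }
  sunset <- nights$sunset[ni]
  out <- data.frame(
    tag_id = ev$tag_id[first],
    night_date = ev$night_date[first],
    site_id = ev$site_id[first],
    emergence_min_after_sunset = (t[first] - as.numeric(sunset)) / 60,
    emergence_clock = ev$timestamp[first],
    n_returns = as.integer(n_returns),
    hours_inside = inside_s / 3600,
    hours_active = active_s / 3600,
    n_events = n_events,
    censored_open_end = n_events %% 2 == 1,
    pre_sunset_emergence = ev$pre_sunset[first],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # conservation check on uncensored nights
  span_h <- (t[last] - t[first]) / 3600
  bad <- !out$censored_open_end &
    abs(out$hours_inside + out$hours_active - span_h) > 1 / 3600
  if (any(bad)) {
    stop("duration conservation violated for bat-night ",
         out$tag_id[bad][1], " / ", format(out$night_date[bad][1]))
  }
  night_len <- as.numeric(difftime(nights$sunrise[ni], nights$sunset[ni], units = "hours"))
  too_long <- out$hours_inside + out$hours_active > night_len + 1
  if (any(too_long)) {
    stop("durations exceed night length for bat-night ",
         out$tag_id[too_long][1], " / ", format(out$night_date[too_long][1]))
  }
  out
}

empty_metrics <- function() {
  data.frame(tag_id = character(), night_date = as.Date(character()),
             site_id = character(), emergence_min_after_sunset = numeric(),
             emergence_clock = as.POSIXct(character(), tz = "UTC"),
             n_returns = integer(), hours_inside = numeric(),
             hours_active = numeric(), n_events = integer(),
             censored_open_end = logical(), pre_sunset_emergence = logical(),
             stringsAsFactors = FALSE)
}

# ---- single bat-night accessors -------------------------------------------
# These operate on the coded events of ONE bat-night (any number of rows with
# a common tag_id/night_date) and exist mainly for worked examples and tests;
# compute_activity_metrics() is the vectorised production path.

#' Activity metrics of a single bat-night
#'
#' `emergence_time()` returns minutes after sunset (and the clock time as an
#' attribute), `count_returns()` the number of entries, `hours_inside()` the
#' summed entry-to-exit durations, and `hours_active()` the summed
#' exit-to-entry durations, each computed on the coded events of one
#' bat-night.
#'
#' @param bat_night coded events of a single bat-night (>= 1 row).
#' @param sunset the night's sunset (POSIXct); required by `emergence_time()`.
#' @return a single number (minutes or hours).
#' @export
emergence_time <- function(bat_night, sunset) {
  stopifnot(nrow(bat_night) >= 1)
  bn <- bat_night[order(bat_night$ordinal), , drop = FALSE]
  structure(as.numeric(difftime(bn$timestamp[1], sunset, units = "mins")),
            clock = bn$timestamp[1])
}

#' @rdname emergence_time
#' @export
count_returns <- function(bat_night) {
  sum(bat_night$direction == "ENTRY")
}

#' @rdname emergence_time
#' @export
hours_inside <- function(bat_night) {
  pair_hours(bat_night, from = "ENTRY")
}

#' @rdname emergence_time
#' @export
hours_active <- function(bat_night) {
  pair_hours(bat_night, from = "EXIT")
}

pair_hours <- function(bat_night, from) {
  bn <- bat_night[order(bat_night$ordinal), , drop = FALSE]
  t <- as.numeric(bn$timestamp)
  if (length(t) < 2) return(0)
  gaps <- diff(t)
  sum(gaps[bn$direction[-length(t)] == from]) / 3600
}
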