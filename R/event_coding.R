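#' Drop detections from the post-tagging acclimation window
#'
#' Bats handled and tagged may behave abnormally for a few nights, so all
#' detections on the first `exclusion_days` calendar days after (and including)
#' the tagging day are removed. A detection is kept when its calendar date is
#' at least `exclusion_days` days after the tagging date.
#'
#' @param detections detection data.frame (see [read_detections()]).
#' @param deployments deployment table (see [read_deployments()]).
#' @param exclusion_days integer number of days to exclude (default 3);
#'   0 leaves the input unchanged.
#' @param unknown_tags `"drop"` (default) drops detections of tags with no
#'   deployment with a warning; `"error"` aborts.
#' @return filtered detections; attribute `n_excluded` carries the per-tag
#'   removal counts.
#' @export
filter_post_tagging <- function(detections, deployments, exclusion_days = 3,
                                unknown_tags = c("drop", "error")) {
  unknown_tags <- match.arg(unknown_tags)
  if (nrow(detections) == 0) return(detections)
  idx <- match(detections$tag_id, deployments$tag_id)
  if (anyNA(idx)) {
    miss <- unique(detections$tag_id[is.na(idx)])
    if (unknown_tags == "error") {
      stop("detections of unknown tag(s): ", paste(miss, collapse = ", "))
    }
    warning(length(miss), " unknown tag(s) dropped: ",
            paste(utils::head(miss, 5), collapse = ", "))
    detections <- detections[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  tag_date <- as.Date(deployments$tagged_at[idx], tz = "UTC")
  keep <- as.Date(detections$timestamp, tz = "UTC") >= tag_date + exclusion_days
  removed <- detections$tag_id[!keep]
  fully_gone <- setdiff(unique(detections$tag_id), unique(detections$tag_id[keep]))
  if (length(fully_gone)) {
    warning("all detections of ", length(fully_gone),
            " tag(s) fall inside the exclusion window")
  }
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- if (length(removed)) table(removed) else table(character())
  out
}

#' Restrict detections to the condition-assignment window
#'
#' Reproductive condition is recorded at tagging and only holds for a limited
#' span, so the reproductive-condition analysis keeps only the `window_days`
#' calendar days that follow the post-tagging exclusion window. Pass
#' `window_days = Inf` to keep everything (the sex/season analysis uses all
#' detections).
#'
#' @inheritParams filter_post_tagging
#' @param window_days days retained after the exclusion window (default 14);
#'   `Inf` is the identity.
#' @return filtered detections.
#' @export
select_condition_window <- function(detections, deployments, window_days = 14,
                                    exclusion_days = 3) {
  if (nrow(detections) == 0 || is.infinite(window_days)) return(detections)
  idx <- match(detections$tag_id, deployments$tag_id)
  if (anyNA(idx)) stop("detections of unknown tag(s); run filter_post_tagging first")
  tag_date <- as.Date(deployments$tagged_at[idx], tz = "UTC")
  keep <- as.Date(detections$timestamp, tz = "UTC") <
    tag_date + exclusion_days + window_days
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_window_dropped") <- sum(!keep)
  out
}

#' Collapse antenna read bursts into passages
#'
#' An RFID cord antenna re-reads a tag many times while the bat moves through
#' the entrance. Maximal runs of same-tag reads whose successive gaps are at
#' most `burst_gap_s` seconds collapse to one passage, stamped with the run's
#' first timestamp and carrying the number of raw reads. With
#' `burst_gap_s <= 0` no collapsing is done (every read is its own passage).
#'
#' @param detections detection data.frame, sorted per tag (as produced by
#'   [read_detections()]).
#' @param burst_gap_s maximum within-burst gap in seconds (default 60).
#' @return a passage data.frame: `tag_id, timestamp, site_id, roost_id,
#'   n_raw_reads`.
#' @export
deduplicate_bursts <- function(detections, burst_gap_s = 60) {
  d <- detections[order(detections$tag_id, detections$timestamp), , drop = FALSE]
  n <- nrow(d)
  if (n == 0) {
    return(data.frame(tag_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                      site_id = character(), roost_id = character(),
                      n_raw_reads = integer(), stringsAsFactors = FALSE))
  }
  if (burst_gap_s <= 0) {
    new_run <- rep(TRUE, n)
  } else {
    gap <- c(Inf, diff(as.numeric(d$timestamp)))
    same_tag <- c(FALSE, d$tag_id[-1] == d$tag_id[-n])
    new_run <- !(same_tag & gap <= burst_gap_s)
  }
  run <- cumsum(new_run)
  first <- !duplicated(run)
  out <- data.frame(tag_id = d$tag_id[first], timestamp = d$timestamp[first],
                    site_id = d$site_id[first], roost_id = d$roost_id[first],
                    n_raw_reads = tabulate(run), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Treat the roosts of a complex as a single entrance
#'
#' When roosts sit close enough that individuals switch between them within a
#' night, direction coding must see them as one entrance: a passage out of one
#' roost followed by a passage into the other is an exit then an entry, and the
#' between-roost transfer counts as time outside. The original roost is kept in
#' `roost_id_original` for reporting.
#'
#' @param passages passage data.frame.
#' @param site a `bn_site`; identity unless `site$merge_roosts` is TRUE.
#' @return passages with `roost_id` rewritten to the site id where merged.
#' @export
merge_roost_complex <- function(passages, site) {
  stopifnot(inherits(site, "bn_site"))
  if (!site$merge_roosts) return(passages)
  sel <- passages$site_id == site$site_id
  passages$roost_id_original <- passages$roost_id
  passages$roost_id[sel] <- site$site_id
  passages
}

#' Assign passages to bat-nights
#'
#' A night runs from `sunset - sunset_tolerance_min` minutes to the next
#' sunrise; a passage joins the night whose window contains it. Passages
#' outside every window are daytime reads: dropped and counted. Bats
#' occasionally emerge slightly before civil sunset, hence the tolerance band;
#' passages in it get `pre_sunset = TRUE`.
#'
#' @param passages passage data.frame.
#' @param nights night table from [night_table()] covering every date spanned.
#' @param sunset_tolerance_min minutes before sunset still counted into the
#'   night (default 30).
#' @return passages with added `night_date` and `pre_sunset` columns; attribute
#'   `n_daytime_dropped`.
#' @export
assign_nights <- function(passages, nights, sunset_tolerance_min = 30) {
  if (nrow(passages) == 0) {
    passages$night_date <- as.Date(character())
    passages$pre_sunset <- logical()
    attr(passages, "n_daytime_dropped") <- 0L
    return(passages)
  }
  tol <- sunset_tolerance_min * 60
  key <- function(s, d) paste(s, format(d))
  nk <- key(nights$site_id, nights$night_date)
  if (anyDuplicated(nk)) stop("duplicate (site, night_date) rows in nights")
  # overlap check per site: window open must come after the previous close
  for (sid in unique(nights$site_id)) {
    ns <- nights[nights$site_id == sid, , drop = FALSE]
    ns <- ns[order(ns$night_date), , drop = FALSE]
    if (nrow(ns) > 1 &&
        any(utils::head(ns$sunrise, -1) > utils::tail(ns$sunset, -1) - tol)) {
      stop("overlapping night windows at site ", sid)
    }
  }
  d0 <- as.Date(passages$timestamp, tz = "UTC")
  assign_for <- function(cand_date) {
    i <- match(key(passages$site_id, cand_date), nk)
    ok <- !is.na(i) &
      passages$timestamp >= nights$sunset[i] - tol &
      passages$timestamp <= nights$sunrise[i]
    list(ok = ok, i = i)
  }
  same <- assign_for(d0)        # night opened by this date's sunset
  prev <- assign_for(d0 - 1)    # after-midnight reads belong to yesterday's night
  i <- ifelse(same$ok, same$i, ifelse(prev$ok, prev$i, NA_integer_))
  dropped <- sum(is.na(i))
  if (dropped > 0) message(dropped, " daytime passage(s) dropped")
  keep <- !is.na(i)
  out <- passages[keep, , drop = FALSE]
  i <- i[keep]
  out$night_date <- nights$night_date[i]
  out$pre_sunset <- out$timestamp < nights$sunset[i]
  rownames(out) <- NULL
  attr(out, "n_daytime_dropped") <- dropped
  out
}

#' Code passage directions within each bat-night
#'
#' A single cord antenna cannot sense direction, so direction is inferred by
#' strict alternation: the first passage of a bat-night is the emergence (an
#' EXIT), the next a return (ENTRY), and so on. Odd-length sequences end on an
#' EXIT and are flagged as open-ended (censored): the final outside interval
#' is unobserved. A missed passage silently flips subsequent directions; this
#' known limitation is quantified with the synthetic module rather than
#' corrected.
#'
#' @param passages night-assigned passages from [assign_nights()].
#' @return a coded-event data.frame: `tag_id, night_date, site_id, timestamp,
#'   direction, roost_id, ordinal, pre_sunset`, sorted by
#'   `(tag_id, night_date, ordinal)`.
#' @export
code_directions <- function(passages) {
  cols <- c("tag_id", "night_date", "site_id", "timestamp", "roost_id", "pre_sunset")
  if (nrow(passages) == 0) {
    out <- passages[, intersect(cols, names(passages)), drop = FALSE]
    out$direction <- character()
    out$ordinal <- integer()
    return(out)
  }
  p <- passages[order(passages$tag_id, passages$night_date, passages$timestamp), ,
                drop = FALSE]
  grp <- cumsum(!duplicated(paste(p$tag_id, format(p$night_date))))
  ordinal <- stats::ave(seq_len(nrow(p)), grp, FUN = seq_along)
  out <- data.frame(tag_id = p$tag_id, night_date = p$night_date,
                    site_id = p$site_id, timestamp = p$timestamp,
                    direction = ifelse(ordinal %% 2 == 1, "EXIT", "ENTRY"),
                    roost_id = p$roost_id, ordinal = as.integer(ordinal),
                    pre_sunset = p$pre_sunset, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Clean and code a detection stream end to end
#'
#' Convenience chain: post-tagging exclusion, optional condition window, burst
#' deduplication, roost-complex merging, night assignment, direction coding.
#' Returns the coded events with a `cleaning_report` attribute holding the
#' per-stage drop counts.
#'
#' @inheritParams filter_post_tagging
#' @inheritParams select_condition_window
#' @inheritParams deduplicate_bursts
#' @inheritParams assign_nights
#' @param sites `bn_site_registry` or single `bn_site`.
#' @param nights night table covering all dates; computed from the sites when
#'   NULL.
#' @return coded events (see [code_directions()]).
#' @export
code_events <- function(detections, deployments, sites, nights = NULL,
                        exclusion_days = 3, window_days = Inf,
                        burst_gap_s = 60, sunset_tolerance_min = 30,
                        unknown_tags = "drop") {
  reg <- unclass_registry(sites)
  det <- filter_post_tagging(detections, deployments, exclusion_days, unknown_tags)
  n_excluded <- sum(attr(det, "n_excluded"))
  det <- select_condition_window(det, deployments, window_days, exclusion_days)
  n_window <- attr(det, "n_window_dropped")
  pas <- deduplicate_bursts(det, burst_gap_s)
  for (s in reg) pas <- merge_roost_complex(pas, s)
  if (is.null(nights)) {
    nights <- do.call(rbind, lapply(reg, function(s) {
      dts <- as.Date(pas$timestamp[pas$site_id == s$site_id], tz = "UTC")
      if (!length(dts)) return(NULL)
      span <- seq(min(dts) - 1, max(dts), by = "day")
      night_table(s, span)
    }))
  }
  pas <- assign_nights(pas, nights, sunset_tolerance_min)
  ev <- code_directions(pas)
  attr(ev, "nights") <- nights
  attr(ev, "cleaning_report") <- list(
    n_input = nrow(detections),
    n_post_tagging_excluded = n_excluded,
    n_outside_condition_window = if (is.null(n_window)) 0L else n_window,
    n_passages = nrow(pas) + attr(pas, "n_daytime_dropped"),
    n_daytime_dropped = attr(pas, "n_daytime_dropped"),
    n_coded_events = nrow(ev))
  ev
}
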