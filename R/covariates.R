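#' Food-availability season of a month
#'
#' Columnar-cactus phenology in the study region partitions the year into four
#' food-availability seasons: November-January (low nectar), February-April
#' (high nectar), May-July (high nectar and fruit), August-October (high
#' fruit).
#'
#' @param month integer month number(s), 1-12.
#' @return factor with levels `low, nectar, nectar_fruit, fruit` (reference
#'   level `fruit` is set at analysis-table assembly, not here).
#' @export
season_for_month <- function(month) {
  if (any(is.na(month)) || any(month < 1 | month > 12 | month != round(month))) {
    stop("month must be an integer in 1..12")
  }
  labels <- c("low", "nectar", "nectar_fruit", "fruit")
  # months: Jan Feb Mar Apr May Jun Jul Aug Sep Oct Nov Dec
  map <- c("low", "nectar", "nectar", "nectar", "nectar_fruit", "nectar_fruit",
           "nectar_fruit", "fruit", "fruit", "fruit", "low", "low")
  factor(map[month], levels = labels)
}

#' Assemble the per-bat-night analysis table
#'
#' Joins metrics to sex/reproductive condition (from the deployment table),
#' food-availability season and calendar year (from the night date), and,
#' for the sex/environment analysis, daily temperature and precipitation.
#'
#' Modes mirror the two analyses:
#' * `"repro_condition"` — females only, condition in
#'   {nonreproductive, pregnant, lactating}; postlactating females and males
#'   are excluded.
#' * `"sex_environment"` — all bats; rows whose night date is missing from the
#'   environmental table are dropped (complete-case) with a logged count.
#'
#' @param metrics bat-night metrics from [compute_activity_metrics()].
#' @param deployments deployment table.
#' @param env daily environmental covariates (required for
#'   `mode = "sex_environment"`).
#' @param mode `"repro_condition"` or `"sex_environment"`.
#' @return data.frame of analysis rows; `season` is a factor with reference
#'   level `fruit`, `sex` a factor with reference level `F`, `bat_id` and
#'   `year` factors for use as grouping variables.
#' @export
build_analysis_table <- function(metrics, deployments, env = NULL,
                                 mode = c("repro_condition", "sex_environment")) {
  mode <- match.arg(mode)
  idx <- match(metrics$tag_id, deployments$tag_id)
  if (anyNA(idx)) {
    stop("metrics contain tag(s) absent from deployments: ",
         metrics$tag_id[is.na(idx)][1])
  }
  tab <- metrics
  tab$sex <- factor(deployments$sex[idx], levels = c("F", "M"))
  tab$repro_condition <- deployments$repro_condition[idx]
  mo <- as.integer(format(tab$night_date, "%m"))
  tab$season <- season_for_month(mo)
  tab$season <- stats::relevel(tab$season, ref = "fruit")
  tab$year <- factor(format(tab$night_date, "%Y"))
  tab$bat_id <- factor(tab$tag_id)
  if (mode == "repro_condition") {
    keep <- tab$sex == "F" &
      !is.na(tab$repro_condition) &
      tab$repro_condition %in% c("nonreproductive", "pregnant", "lactating")
    tab <- tab[keep, , drop = FALSE]
    # intercept = pregnant, matching the convention of the reported coefficients
    tab$repro_condition <- factor(tab$repro_condition,
                                  levels = c("pregnant", "lactating", "nonreproductive"))
  } else {
    if (is.null(env)) stop("mode 'sex_environment' requires an env table")
    ei <- match(tab$night_date, env$date)
    n_drop <- sum(is.na(ei))
    if (n_drop > 0) {
      message(n_drop, " bat-night(s) dropped: no environmental covariates")
    }
    tab$tmean_c <- env$tmean_c[ei]
    tab$precip_mm <- env$precip_mm[ei]
    tab <- tab[!is.na(ei), , drop = FALSE]
    tab$repro_condition <- NULL
  }
  rownames(tab) <- NULL
  tab
}
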