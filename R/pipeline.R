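#' Run the activity-budget pipeline from a config
#'
#' Orchestrates end-to-end runs. A config (YAML path or list) selects the
#' stages: `"simulate"` writes a synthetic colony's detection stream and truth
#' tables; `"derive"` cleans and codes a detection stream and computes the
#' per-bat-night metrics and analysis table; `"fit"` runs the configured
#' statistical analysis; `"all"` chains them. All referenced input paths are
#' checked before any computation. Every run writes `manifest.json` naming the
#' config hash and seed that produced each artifact, plus a plain-text run
#' log.
#'
#' Config fields (all optional except `out_dir`):
#' * `mode`: simulate | derive | fit | all (default all)
#' * `seed`: integer RNG seed
#' * `out_dir`: artifact directory (created if needed)
#' * `sim`: overrides for [sim_config()] scalar fields
#' * `inputs`: paths `detections`, `deployments`, `sites`, optional `env`
#'   (ignored when simulating; the simulated files are used)
#' * `params`: `exclusion_days`, `window_days`, `burst_gap_s`,
#'   `sunset_tolerance_min`
#' * `analysis`: `mode` (repro_condition | sex_environment), `metrics`
#'   (responses to fit; default all four)
#'
#' @param config path to a YAML file or an equivalent named list.
#' @return the output directory, invisibly; artifacts are written there
#'   (`coded_events.csv`, `metrics.csv`, `analysis_table.csv`, `fits.json`,
#'   `contrasts.csv`, `aic_table.csv`, `cleaning_report.json`, ...).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  mode <- config$mode %||% "all"
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  hash <- config_hash(config)
  logf <- file.path(out_dir, "run_log.txt")
  cat(sprintf("batnight %s | config %s | seed %d | R %s | %s\n",
              as.character(utils::packageVersion("batnight")), hash, seed,
              paste(R.version$major, R.version$minor, sep = "."),
              format(Sys.time())), file = logf)
  note <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE, sep = "")

  params <- config$params %||% list()
  exclusion_days <- params$exclusion_days %||% 3
  window_days <- parse_window(params$window_days %||% Inf)
  burst_gap_s <- params$burst_gap_s %||% 60
  sunset_tol <- params$sunset_tolerance_min %||% 30

  do_sim <- mode %in% c("simulate", "all") && is.null(config$inputs)
  do_derive <- mode %in% c("derive", "all")
  do_fit <- mode %in% c("fit", "all")

  # fail fast on missing inputs before any computation
  if (!do_sim) {
    ins <- config$inputs %||% list()
    need <- c("detections", "deployments", "sites")
    for (k in need) {
      if (is.null(ins[[k]])) stop("config$inputs$", k, " is required when not simulating")
      if (!file.exists(ins[[k]])) stop("stage derive: input file not found: ", ins[[k]])
    }
    if (!is.null(ins$env) && !file.exists(ins$env)) {
      stop("stage derive: input file not found: ", ins$env)
    }
  }

  set.seed(seed)
  nights <- NULL
  env <- NULL
  sim_groups <- NULL
  if (do_sim) {
    sc_args <- config$sim %||% list()
    sc_args <- sc_args[names(sc_args) %in% names(formals(sim_config))]
    sc_args$seed <- seed
    sc <- do.call(sim_config, sc_args)
    truth <- simulate_truth(sc)
    det <- apply_detection_process(truth$truth_events, sc)
    write_detections(det, file.path(out_dir, "detections.csv"))
    dep_out <- truth$deployments
    dep_out$tagged_at <- format(dep_out$tagged_at, "%Y-%m-%dT%H:%M:%S")
    utils::write.csv(dep_out, file.path(out_dir, "deployments.csv"),
                     row.names = FALSE, quote = FALSE)
    write_sites(sc$site, file.path(out_dir, "sites.yaml"))
    tm <- truth$truth_metrics
    tm$emergence_clock <- format(tm$emergence_clock, "%Y-%m-%dT%H:%M:%S")
    utils::write.csv(tm, file.path(out_dir, "truth_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    write_detections(truth$truth_events,
                     file.path(out_dir, "truth_events.csv"))
    nights <- truth$nights
    sim_groups <- truth$deployments[, c("tag_id", "group")]
    env <- simulate_env(nights$night_date)
    utils::write.csv(env, file.path(out_dir, "env.csv"),
                     row.names = FALSE, quote = FALSE)
    note("simulate: %d bats, %d truth events, %d detections",
         nrow(truth$deployments), nrow(truth$truth_events), nrow(det))
    detections <- det
    deployments <- truth$deployments
    sites <- sc$site
  } else {
    sites <- read_sites(config$inputs$sites)
    detections <- read_detections(config$inputs$detections, sites)
    deployments <- read_deployments(config$inputs$deployments)
    if (!is.null(config$inputs$env)) env <- read_env(config$inputs$env)
  }

  tab <- NULL
  analysis <- config$analysis %||% list()
  an_mode <- analysis$mode %||% "repro_condition"
  if (do_derive || do_fit) {
    ev <- code_events(detections, deployments, sites, nights = nights,
                      exclusion_days = exclusion_days, window_days = window_days,
                      burst_gap_s = burst_gap_s,
                      sunset_tolerance_min = sunset_tol)
    metrics <- compute_activity_metrics(ev)
    write_coded_events(ev, file.path(out_dir, "coded_events.csv"))
    write_metrics(metrics, file.path(out_dir, "metrics.csv"))
    jsonlite::write_json(attr(ev, "cleaning_report"),
                         file.path(out_dir, "cleaning_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    tab <- build_analysis_table(metrics, deployments, env = env, mode = an_mode)
    if (!is.null(sim_groups)) {
      tab$group <- sim_groups$group[match(tab$tag_id, sim_groups$tag_id)]
    }
    utils::write.csv(fmt_times(tab), file.path(out_dir, "analysis_table.csv"),
                     row.names = FALSE, quote = FALSE)
    note("derive: %d coded events, %d bat-nights, %d analysis rows",
         nrow(ev), nrow(metrics), nrow(tab))
  }

  if (do_fit) {
    fit_out <- pipeline_fit(tab, an_mode, metrics = analysis$metrics, out_dir = out_dir)
    note("fit: %s analysis, %d model fits", an_mode, fit_out$n_fits)
  }

  manifest <- list(config_hash = hash, seed = seed,
                   files = setdiff(list.files(out_dir),
                                   c("manifest.json", "run_log.txt")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Fit the configured statistical analysis on an analysis table
#'
#' For `mode = "repro_condition"`: per metric, a single-fixed-effect GLM
#' (Poisson for returns; gamma inverse for the duration metrics and emergence,
#' with non-positive rows dropped and logged), a likelihood-ratio test against
#' the intercept-only null, Tukey-adjusted pairwise contrasts among
#' conditions, and response-scale effect sizes. For `mode = "sex_environment"`:
#' per metric, the 16-model candidate set (negative binomial for returns,
#' gamma log for durations, Gaussian for emergence) with crossed random
#' intercepts for bat and year, ranked by AIC, plus the effect report of the
#' best-supported model.
#'
#' @param tab analysis table from [build_analysis_table()].
#' @param mode `"repro_condition"` or `"sex_environment"`.
#' @param metrics character vector of responses to fit; default all four.
#' @param out_dir directory for `fits.json`, `contrasts.csv` / `aic_table.csv`,
#'   `lrt.csv`; NULL skips writing.
#' @return list with per-metric results (`fits`, `lrt`, `contrasts` or
#'   `aic_table`, `effects`) and `n_fits`.
#' @export
pipeline_fit <- function(tab, mode = c("repro_condition", "sex_environment"),
                         metrics = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  all_metrics <- c("n_returns", "emergence_min_after_sunset",
                   "hours_inside", "hours_active")
  metrics <- metrics %||% all_metrics
  res <- list()
  n_fits <- 0L
  if (mode == "repro_condition") {
    lrt_rows <- list()
    ctr_rows <- list()
    fit_summ <- list()
    for (m in metrics) {
      fam <- if (m == "n_returns") "poisson" else "gamma"
      dat <- tab
      if (fam == "gamma") dat <- drop_nonpositive(dat, m)
      spec1 <- model_spec(m, fam, fixed = "repro_condition")
      spec0 <- model_spec(m, fam)
      f1 <- fit_activity_glm(dat, spec1)
      f0 <- fit_activity_glm(dat, spec0)
      lr <- lrt(f1, f0)
      ct <- pairwise_contrasts(f1, "repro_condition", "tukey")
      ef <- effect_report(f1)
      n_fits <- n_fits + 2L
      res[[m]] <- list(fit = f1, null = f0, lrt = lr, contrasts = ct, effects = ef)
      lrt_rows[[m]] <- data.frame(metric = m, chi2 = lr$chi2, df = lr$df,
                                  p_value = lr$p_value)
      ct$metric <- m
      ctr_rows[[m]] <- ct
      fit_summ[[m]] <- list(spec = unclass(f1$spec)[c("response", "family", "link", "fixed")],
                            coefficients = f1$coefficients, loglik = f1$loglik,
                            aic = f1$aic, n_obs = f1$n_obs,
                            effects = ef)
    }
    if (!is.null(out_dir)) {
      utils::write.csv(do.call(rbind, lrt_rows), file.path(out_dir, "lrt.csv"),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, ctr_rows),
                       file.path(out_dir, "contrasts.csv"), row.names = FALSE)
      jsonlite::write_json(fit_summ, file.path(out_dir, "fits.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  } else {
    aic_rows <- list()
    fit_summ <- list()
    for (m in metrics) {
      fam <- switch(m, n_returns = "negative_binomial",
                    emergence_min_after_sunset = "gaussian", "gamma")
      link <- if (fam == "gamma") "log" else NULL
      dat <- tab
      if (fam == "gamma") dat <- drop_nonpositive(dat, m)
      specs <- build_candidate_set(m, fam, link)
      # terms whose factor is constant in this data cannot be estimated;
      # drop the affected candidate models (happens in short demo runs that
      # span one season or one sex)
      usable <- vapply(specs, function(s) {
        vars <- unique(unlist(strsplit(s$fixed, ":", fixed = TRUE)))
        all(vapply(vars, function(v) {
          if (is.factor(dat[[v]])) nlevels(droplevels(dat[[v]])) >= 2
          else length(unique(dat[[v]])) >= 2
        }, logical(1)))
      }, logical(1))
      if (!all(usable)) {
        message(sum(!usable), " candidate model(s) skipped for ", m,
                ": constant factor term in this data")
        specs <- specs[usable]
      }
      fits <- lapply(specs, function(s) fit_activity_glmm(dat, s))
      n_fits <- n_fits + length(fits)
      aic_tab <- select_by_aic(fits)
      best <- fits[[match(aic_tab$model[1], names(specs))]]
      ef <- effect_report(best)
      res[[m]] <- list(fits = fits, aic_table = aic_tab, best = best, effects = ef)
      aic_tab$metric <- m
      aic_rows[[m]] <- aic_tab
      fit_summ[[m]] <- list(best_model = aic_tab$model[1],
                            coefficients = best$coefficients,
                            aic = best$aic, n_obs = best$n_obs, effects = ef)
    }
    if (!is.null(out_dir)) {
      utils::write.csv(do.call(rbind, aic_rows),
                       file.path(out_dir, "aic_table.csv"), row.names = FALSE)
      jsonlite::write_json(fit_summ, file.path(out_dir, "fits.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  res$n_fits <- n_fits
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_window <- function(x) {
  if (is.character(x) && x %in% c("Inf", ".inf", "inf", "all")) return(Inf)
  as.numeric(x)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_sites <- function(sites, path) {
  reg <- unclass_registry(sites)
  out <- lapply(reg, function(s) {
    list(latitude = s$latitude, longitude = s$longitude,
         utc_offset_hours = s$utc_offset_hours,
         roost_ids = as.list(s$roost_ids), merge_roosts = s$merge_roosts)
  })
  names(out) <- vapply(reg, `[[`, "", "site_id")
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_detections
#' @export
write_coded_events <- function(x, path) {
  x <- x[, c("tag_id", "night_date", "timestamp", "direction", "roost_id", "ordinal")]
  x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
write_metrics <- function(x, path) {
  utils::write.csv(fmt_times(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_times <- function(x) {
  for (col in names(x)) {
    if (inherits(x[[col]], "POSIXct")) {
      x[[col]] <- format(x[[col]], "%Y-%m-%dT%H:%M:%S")
    }
  }
  x
}
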