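#' Specify an activity-metric model
#'
#' A model specification names the response metric, the error family and link,
#' the fixed-effect terms, and (for mixed models) the random intercepts.
#' Family/link pairs are restricted to the combinations the analyses use:
#' Poisson(log) and negative binomial(log) for counts of returns,
#' gamma(inverse) or gamma(log) for positive durations, Gaussian(identity)
#' for emergence time.
#'
#' @param response name of the response column (an activity metric).
#' @param family one of `"poisson"`, `"negative_binomial"`, `"gamma"`,
#'   `"gaussian"`.
#' @param link link function; defaults to the family's conventional link
#'   (log, log, inverse, identity respectively).
#' @param fixed character vector of fixed-effect terms (e.g.
#'   `c("sex", "season", "sex:season", "tmean_c")`); empty for the null model.
#' @param random character vector of grouping factors for crossed random
#'   intercepts (e.g. `c("bat_id", "year")`); NULL for a plain GLM.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, family, link = NULL, fixed = character(),
                       random = NULL) {
  family <- match.arg(family, c("poisson", "negative_binomial", "gamma", "gaussian"))
  default_link <- c(poisson = "log", negative_binomial = "log",
                    gamma = "inverse", gaussian = "identity")[family]
  if (is.null(link)) link <- unname(default_link)
  allowed <- list(poisson = "log", negative_binomial = "log",
                  gamma = c("inverse", "log"), gaussian = "identity")
  if (!link %in% allowed[[family]]) {
    stop("family '", family, "' supports link(s): ",
         paste(allowed[[family]], collapse = ", "))
  }
  structure(list(response = response, family = family, link = link,
                 fixed = as.character(fixed), random = random),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(spec_formula(x)), " [", x$family, "(", x$link, ")",
      if (length(x$random)) paste0(" + (1|", paste(x$random, collapse = ") + (1|"), ")"),
      "]\n", sep = "")
  invisible(x)
}

spec_formula <- function(spec, random = FALSE) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  if (random && length(spec$random)) {
    rhs <- paste(rhs, paste0("(1 | ", spec$random, ")", collapse = " + "), sep = " + ")
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

r_family <- function(spec) {
  switch(spec$family,
         poisson = stats::poisson(link = spec$link),
         gamma = stats::Gamma(link = spec$link),
         gaussian = stats::gaussian(),
         negative_binomial = NULL) # handled by the fitting engine
}

check_response <- function(y, spec) {
  if (anyNA(y)) stop("response '", spec$response, "' contains NA")
  if (spec$family %in% c("poisson", "negative_binomial")) {
    if (any(y < 0) || any(y != round(y))) {
      stop("family '", spec$family, "' needs non-negative integer responses")
    }
  }
  if (spec$family == "gamma" && any(y <= 0)) {
    stop("gamma response '", spec$response, "' contains ", sum(y <= 0),
         " non-positive value(s); filter them first ",
         "(e.g. drop_nonpositive()) - the gamma density is undefined at 0")
  }
}

#' Drop rows with non-positive response values
#'
#' Gamma models require strictly positive responses; nights with no
#' return-exit pair have zero hours inside, and zero active hours can occur on
#' censored nights. This helper removes such rows and logs the count.
#'
#' @param data analysis table.
#' @param response response column name.
#' @return filtered data; attribute `n_dropped_nonpositive`.
#' @export
drop_nonpositive <- function(data, response) {
  bad <- data[[response]] <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) with non-positive ", response, " dropped")
  }
  out <- data[!bad, , drop = FALSE]
  attr(out, "n_dropped_nonpositive") <- sum(bad)
  out
}

new_activity_fit <- function(model, spec, engine, data, converged,
                             dispersion = NA_real_, singular = FALSE,
                             fallback = NA_character_, vcov_fixed = NULL) {
  ll <- stats::logLik(model)
  beta <- fixed_coefs(model)
  beta <- beta[!is.na(beta)] # aliased terms in rank-deficient fits
  V <- if (is.null(vcov_fixed)) fixed_vcov(model) else vcov_fixed
  keep <- intersect(names(beta), rownames(V))
  beta <- beta[keep]
  V <- V[keep, keep, drop = FALSE]
  se <- sqrt(diag(V))
  coefs <- data.frame(term = names(beta), estimate = as.numeric(beta), se = se,
                      ci_low = as.numeric(beta) - 1.959964 * se,
                      ci_high = as.numeric(beta) + 1.959964 * se,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = model, spec = spec, engine = engine,
                 coefficients = coefs, vcov = V,
                 loglik = as.numeric(ll), df = attr(ll, "df"),
                 aic = 2 * attr(ll, "df") - 2 * as.numeric(ll),
                 n_obs = stats::nobs(model), dispersion = dispersion,
                 converged = converged, singular = singular,
                 fallback = fallback, data = data),
            class = "activity_fit")
}

fixed_coefs <- function(model) {
  if (inherits(model, "glmmTMB")) glmmTMB::fixef(model)$cond else stats::coef(model)
}

fixed_vcov <- function(model) {
  if (inherits(model, "glmmTMB")) stats::vcov(model)$cond else stats::vcov(model)
}

#' Fit a GLM to one activity metric
#'
#' Maximum-likelihood fit of the specified family/link; negative binomial via
#' [MASS::glm.nb()] (NB2, mean/dispersion parameterisation), all others via
#' [stats::glm()]. Coefficients carry Wald 95% CIs on the link scale.
#' Non-convergence is flagged on the returned object, never silent.
#'
#' @param data analysis table (one row per bat-night).
#' @param spec a [model_spec()] without random terms.
#' @return an object of class `activity_fit`.
#' @export
fit_activity_glm <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(spec$random)) {
    stop("spec has random terms; use fit_activity_glmm()")
  }
  check_response(data[[spec$response]], spec)
  f <- spec_formula(spec)
  if (spec$family == "negative_binomial") {
    model <- MASS::glm.nb(f, data = data)
    disp <- model$theta
  } else {
    model <- stats::glm(f, family = r_family(spec), data = data)
    disp <- if (spec$family == "gaussian") summary(model)$dispersion
            else summary(model)$dispersion
  }
  if (!isTRUE(model$converged)) warning("GLM did not converge")
  new_activity_fit(model, spec, engine = "glm", data = data,
                   converged = isTRUE(model$converged), dispersion = disp)
}

#' Fit a GLMM with crossed random intercepts
#'
#' Fits the specification with random intercepts for each grouping factor in
#' `spec$random` (typically bat identity and year, crossed) by Laplace
#' approximation via glmmTMB. If the fit errors or fails to converge, a
#' documented fallback fits the fixed-effects GLM with cluster-robust
#' standard errors (clustered on the first grouping factor) and records the
#' fallback in the fit metadata. A singular fit (a variance component at zero)
#' is flagged, not an error.
#'
#' @param data analysis table.
#' @param spec a [model_spec()] with random terms.
#' @return an `activity_fit`; `$engine` is `"glmmTMB"`, or `"glm_cluster"`
#'   when the fallback was used (see `$fallback`).
#' @export
fit_activity_glmm <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"), length(spec$random) >= 1)
  for (g in spec$random) {
    if (!g %in% names(data)) stop("grouping column '", g, "' not in data")
    data[[g]] <- droplevels(factor(data[[g]]))
  }
  # a grouping factor with one level carries no information; drop it
  singleton <- vapply(spec$random, function(g) nlevels(data[[g]]) < 2, logical(1))
  if (any(singleton)) {
    message("random term(s) dropped (single level): ",
            paste(spec$random[singleton], collapse = ", "))
    spec$random <- spec$random[!singleton]
    if (!length(spec$random)) {
      return(fit_activity_glm(data, model_spec(spec$response, spec$family,
                                               spec$link, spec$fixed)))
    }
  }
  check_response(data[[spec$response]], spec)
  f <- spec_formula(spec, random = TRUE)
  fam <- if (spec$family == "negative_binomial") {
    glmmTMB::nbinom2(link = spec$link)
  } else {
    r_family(spec)
  }
  model <- tryCatch(
    glmmTMB::glmmTMB(f, family = fam, data = data,
                     control = glmmTMB::glmmTMBControl(
                       optCtrl = list(iter.max = 1000, eval.max = 1000))),
    error = function(e) e)
  ok <- !inherits(model, "error") &&
    isTRUE(model$fit$convergence == 0) &&
    isTRUE(model$sdr$pdHess) &&
    !anyNA(suppressWarnings(sqrt(diag(fixed_vcov(model)))))
  if (!ok) {
    reason <- if (inherits(model, "error")) {
      conditionMessage(model)
    } else if (isTRUE(model$fit$convergence != 0)) {
      "non-convergence"
    } else {
      "unreliable covariance (non-PD Hessian or NaN standard errors)"
    }
    glm_spec <- model_spec(spec$response, spec$family, spec$link, spec$fixed)
    fb <- fit_activity_glm(data, glm_spec)
    cl <- data[[spec$random[1]]]
    Vcl <- sandwich::vcovCL(fb$model, cluster = cl)
    out <- new_activity_fit(fb$model, spec, engine = "glm_cluster", data = data,
                            converged = fb$converged, dispersion = fb$dispersion,
                            fallback = paste0("glmmTMB failed (", reason,
                                              "); GLM with cluster-robust SEs on ",
                                              spec$random[1]),
                            vcov_fixed = Vcl)
    return(out)
  }
  vc <- glmmTMB::VarCorr(model)$cond
  vars <- vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1))
  singular <- any(vars < 1e-8)
  disp <- tryCatch(glmmTMB::sigma(model), error = function(e) NA_real_)
  new_activity_fit(model, spec, engine = "glmmTMB", data = data,
                   converged = TRUE, dispersion = disp, singular = singular)
}

#' @export
print.activity_fit <- function(x, digits = 4, ...) {
  cat("Activity-metric fit: ")
  print(x$spec)
  cat("engine: ", x$engine,
      if (!is.na(x$fallback)) paste0(" (fallback: ", x$fallback, ")"), "\n",
      "n = ", x$n_obs, ", logLik = ", format(x$loglik, digits = digits),
      ", AIC = ", format(x$aic, digits = digits),
      if (x$singular) ", SINGULAR random effect", "\n", sep = "")
  print(x$coefficients, digits = digits)
  invisible(x)
}

#' @export
summary.activity_fit <- function(object, ...) {
  print(object, ...)
}

#' @export
coef.activity_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.activity_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs, class = "logLik")
}

#' Likelihood-ratio test of nested fits
#'
#' Compares a fitted model against a nested null on the same rows:
#' chi-squared statistic `2 * (logLik_alt - logLik_null)` with degrees of
#' freedom equal to the difference in estimated parameters.
#'
#' @param fit_alt,fit_null `activity_fit` objects; `fit_null`'s fixed terms
#'   must be a subset of `fit_alt`'s and both must use the same rows.
#' @return list with `chi2`, `df`, `p_value` (class `lrt_result`).
#' @export
lrt <- function(fit_alt, fit_null) {
  stopifnot(inherits(fit_alt, "activity_fit"), inherits(fit_null, "activity_fit"))
  if (fit_alt$n_obs != fit_null$n_obs ||
      fit_alt$spec$response != fit_null$spec$response) {
    stop("fits are not on the same data")
  }
  if (!all(fit_null$spec$fixed %in% fit_alt$spec$fixed)) {
    stop("null model is not nested in the alternative")
  }
  chi2 <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  df <- fit_alt$df - fit_null$df
  if (df < 0) stop("alternative has fewer parameters than the null")
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p_value = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.4g, df = %d, p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

# Link-scale estimated marginal means of a factor: model matrix rows for each
# level, other numeric covariates held at their mean, other factors at their
# reference level. Exact for single-factor models; documented approximation
# otherwise.
emm_matrix <- function(fit, factor_name) {
  data <- fit$data
  if (!factor_name %in% names(data)) stop("'", factor_name, "' not in model data")
  fe <- spec_formula(fit$spec)
  tt <- stats::delete.response(stats::terms(fe, data = data))
  if (!factor_name %in% all.vars(tt)) {
    stop("'", factor_name, "' is not a term of the model")
  }
  fac <- factor(data[[factor_name]])
  levs <- levels(droplevels(fac))
  if (length(levs) < 2) stop("factor has fewer than 2 levels in the fit")
  grid <- data.frame(row.names = seq_along(levs))
  for (v in all.vars(tt)) {
    col <- data[[v]]
    if (v == factor_name) {
      grid[[v]] <- factor(levs, levels = levels(fac))
    } else if (is.numeric(col)) {
      grid[[v]] <- mean(col)
    } else {
      f <- factor(col)
      grid[[v]] <- factor(rep(levels(f)[1], length(levs)), levels = levels(f))
    }
  }
  L <- stats::model.matrix(tt, grid)
  rownames(L) <- levs
  L
}

#' Pairwise contrasts of a factor with Tukey-style adjustment
#'
#' All level pairs of `factor_name`, estimated on the link scale from the
#' fit's coefficients and back-transformed to the response scale: ratios of
#' predicted means for log- and inverse-link models, plain differences for
#' Gaussian. The family-wise adjustment is the multivariate-normal max-|z|
#' method over the contrast set (the large-sample analogue of the Tukey
#' adjustment used by estimated-marginal-means software): each adjusted p is
#' the probability that the maximum absolute standardised contrast exceeds the
#' observed one under the joint normal with the contrasts' estimated
#' correlation, and adjusted CIs use the matching critical value.
#'
#' @param fit an `activity_fit`.
#' @param factor_name name of a factor term in the model.
#' @param adjustment `"tukey"` (default) or `"none"`.
#' @return data.frame of class `contrast_result`: one row per level pair with
#'   response-scale `estimate`, `ci_low`, `ci_high`, `z`, `p_value`,
#'   `p_adjusted`, and the `scale` of the estimate.
#' @export
pairwise_contrasts <- function(fit, factor_name, adjustment = c("tukey", "none")) {
  adjustment <- match.arg(adjustment)
  L <- emm_matrix(fit, factor_name)
  levs <- rownames(L)
  beta <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  V <- fit$vcov
  eta <- as.numeric(L %*% beta)
  pairs <- utils::combn(seq_along(levs), 2)
  D <- t(apply(pairs, 2, function(ij) L[ij[1], ] - L[ij[2], ]))
  est_link <- as.numeric(D %*% beta)
  se_link <- sqrt(rowSums((D %*% V) * D))
  z <- est_link / se_link
  # correlation of the contrast estimates, for the max-|z| adjustment
  C <- D %*% V %*% t(D)
  R <- stats::cov2cor(C)
  p_raw <- 2 * stats::pnorm(-abs(z))
  if (adjustment == "tukey" && length(z) > 1) {
    k <- length(z)
    p_adj <- vapply(abs(z), function(zz) {
      1 - mvtnorm::pmvnorm(lower = rep(-zz, k), upper = rep(zz, k), corr = R,
                           algorithm = mvtnorm::GenzBretz(abseps = 1e-6))[1]
    }, numeric(1))
    p_adj <- pmin(1, pmax(p_adj, p_raw))
    crit <- stats::uniroot(function(q) {
      mvtnorm::pmvnorm(lower = rep(-q, k), upper = rep(q, k), corr = R,
                       algorithm = mvtnorm::GenzBretz(abseps = 1e-6))[1] - 0.95
    }, c(1, 6))$root
  } else {
    p_adj <- p_raw
    crit <- stats::qnorm(0.975)
  }
  link <- fit$spec$link
  if (link == "identity") {
    scale <- "difference"
    estimate <- est_link
    lo <- est_link - crit * se_link
    hi <- est_link + crit * se_link
  } else if (link == "log") {
    scale <- "ratio"
    estimate <- exp(est_link)
    lo <- exp(est_link - crit * se_link)
    hi <- exp(est_link + crit * se_link)
  } else { # inverse link: mu = 1/eta, ratio mu_i/mu_j = eta_j/eta_i
    scale <- "ratio"
    if (any(eta <= 0)) stop("inverse-link means non-positive; contrasts undefined")
    lr <- log(eta[pairs[2, ]]) - log(eta[pairs[1, ]])
    G <- t(vapply(seq_len(ncol(pairs)), function(k) {
      L[pairs[2, k], ] / eta[pairs[2, k]] - L[pairs[1, k], ] / eta[pairs[1, k]]
    }, numeric(ncol(L))))
    se_lr <- sqrt(rowSums((G %*% V) * G))
    estimate <- exp(lr)
    lo <- exp(lr - crit * se_lr)
    hi <- exp(lr + crit * se_lr)
  }
  out <- data.frame(
    contrast = paste(levs[pairs[1, ]],
                     if (scale == "ratio") "/" else "-",
                     levs[pairs[2, ]]),
    estimate = estimate, ci_low = pmin(lo, hi), ci_high = pmax(lo, hi),
    z = z, p_value = p_raw, p_adjusted = p_adj,
    adjustment = adjustment, scale = scale,
    stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' The a priori candidate model set for the sex/environment analysis
#'
#' A deterministic 16-model menu over the fixed-effect menu
#' {sex, season, temperature, precipitation} with an optional sex-by-season
#' interaction, every model carrying crossed random intercepts for bat
#' identity and year: the null; the four single-term models; the six additive
#' pairs; the full additive model; and the four interactive variants
#' (sex*season alone and with temperature, precipitation, or both). The
#' original candidate list is not published in full, so this menu is the
#' package's documented reconstruction.
#'
#' @param response activity-metric column name.
#' @param family,link passed to [model_spec()].
#' @param random grouping factors, default crossed `bat_id` and `year`.
#' @return named list of 16 `model_spec`s.
#' @export
build_candidate_set <- function(response, family, link = NULL,
                                random = c("bat_id", "year")) {
  sx <- "sex"; se <- "season"; tm <- "tmean_c"; pr <- "precip_mm"
  inter <- c(sx, se, "sex:season")
  sets <- list(
    null = character(),
    sex = sx, season = se, tmean = tm, precip = pr,
    `sex+season` = c(sx, se), `sex+tmean` = c(sx, tm),
    `sex+precip` = c(sx, pr), `season+tmean` = c(se, tm),
    `season+precip` = c(se, pr), `tmean+precip` = c(tm, pr),
    `sex+season+tmean+precip` = c(sx, se, tm, pr),
    `sex*season` = inter,
    `sex*season+tmean` = c(inter, tm),
    `sex*season+precip` = c(inter, pr),
    `sex*season+tmean+precip` = c(inter, tm, pr))
  lapply(sets, function(tt) model_spec(response, family, link, fixed = tt,
                                       random = random))
}

#' Rank fitted models by AIC
#'
#' Sorts fits by AIC and reports each model's AIC difference from the minimum.
#' Models within 2 AIC units of the best are equivalently supported and form
#' the best set; ties are all reported, no single winner is forced.
#'
#' @param fits a (named) list of `activity_fit`s on identical rows.
#' @return data.frame sorted by AIC with columns `model, df, aic, delta_aic,
#'   in_best_set`.
#' @export
select_by_aic <- function(fits) {
  stopifnot(length(fits) >= 1)
  n <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n)) != 1) {
    stop("fits use differing numbers of observations; AICs are not comparable")
  }
  eng <- vapply(fits, `[[`, "", "engine")
  if (length(unique(eng)) != 1) {
    warning("fits mix engines (", paste(unique(eng), collapse = ", "),
            "); AICs may not be comparable")
  }
  nm <- names(fits)
  if (is.null(nm)) {
    nm <- vapply(fits, function(f) deparse(spec_formula(f$spec)), "")
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  tab <- data.frame(model = nm, df = vapply(fits, `[[`, numeric(1), "df"),
                    aic = aic, delta_aic = aic - min(aic),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$in_best_set <- tab$delta_aic < 2
  rownames(tab) <- NULL
  tab
}

#' Response-scale effect sizes with 95% confidence intervals
#'
#' One row per coefficient: the link-scale estimate and, where the link allows
#' a direct reading, the response-scale effect — exponentiated ratios for log
#' links, plain differences (minutes or hours) for the identity link, and for
#' the inverse link the ratio of the predicted mean at reference + term to the
#' reference mean (delta-method CI). Reference levels are the factors' first
#' levels of the fitted data (stated in the table's `reference` attribute).
#'
#' @param fit an `activity_fit`.
#' @return data.frame with columns `term, estimate, se, ci_low, ci_high,
#'   effect, effect_low, effect_high, effect_scale`.
#' @export
effect_report <- function(fit) {
  co <- fit$coefficients
  link <- fit$spec$link
  if (link == "identity") {
    eff <- co$estimate; lo <- co$ci_low; hi <- co$ci_high
    scale <- "difference"
  } else if (link == "log") {
    eff <- exp(co$estimate); lo <- exp(co$ci_low); hi <- exp(co$ci_high)
    scale <- "ratio"
  } else { # inverse
    V <- fit$vcov
    i0 <- match("(Intercept)", co$term)
    if (is.na(i0)) stop("inverse-link effect report needs an intercept")
    eta0 <- co$estimate[i0]
    eff <- lo <- hi <- numeric(nrow(co))
    for (k in seq_len(nrow(co))) {
      if (k == i0) {
        # response-scale reference mean 1/eta0, delta method
        eff[k] <- 1 / eta0
        se_m <- sqrt(V[i0, i0]) / eta0^2
        lo[k] <- eff[k] - 1.959964 * se_m
        hi[k] <- eff[k] + 1.959964 * se_m
      } else {
        etak <- eta0 + co$estimate[k]
        eff[k] <- eta0 / etak # mu_level / mu_reference
        g <- numeric(nrow(co))
        g[i0] <- 1 / eta0 - 1 / etak
        g[k] <- -1 / etak
        se_lr <- sqrt(drop(t(g) %*% V %*% g))
        lo[k] <- eff[k] * exp(-1.959964 * se_lr)
        hi[k] <- eff[k] * exp(1.959964 * se_lr)
      }
    }
    scale <- "ratio"
  }
  refs <- vapply(Filter(is.factor, fit$data), function(f) levels(f)[1], "")
  out <- data.frame(term = co$term, estimate = co$estimate, se = co$se,
                    ci_low = co$ci_low, ci_high = co$ci_high,
                    effect = eff, effect_low = pmin(lo, hi),
                    effect_high = pmax(lo, hi), effect_scale = scale,
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- refs
  out
}
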