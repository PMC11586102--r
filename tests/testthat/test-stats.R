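test_that("model specifications enforce the allowed family/link pairs", {
  expect_equal(model_spec("y", "poisson")$link, "log")
  expect_equal(model_spec("y", "gamma")$link, "inverse")
  expect_equal(model_spec("y", "gamma", "log")$link, "log")
  expect_error(model_spec("y", "poisson", "identity"), "supports link")
  expect_error(model_spec("y", "gaussian", "log"), "supports link")
})

test_that("intercept-only Poisson recovers log of the sample mean exactly", {
  d <- data.frame(y = c(1L, 2L, 3L))
  fit <- fit_activity_glm(d, model_spec("y", "poisson"))
  expect_equal(unname(coef(fit)), log(2), tolerance = 1e-8)
  expect_equal(fit$aic, AIC(fit$model))
})

test_that("a known two-group Poisson rate ratio is recovered", {
  set.seed(2024)
  n <- 5000
  d <- data.frame(g = factor(rep(c("A", "B"), each = n)))
  d$y <- rpois(2 * n, c(1.5, 3.0)[as.integer(d$g)])
  fit <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "g"))
  ratio <- exp(coef(fit)[["gB"]])
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("gaussian-identity fits equal ordinary least squares", {
  set.seed(5)
  d <- data.frame(x = rnorm(40), g = factor(rep(c("a", "b"), 20)))
  d$y <- 1 + 2 * d$x + 0.5 * (d$g == "b") + rnorm(40)
  fit <- fit_activity_glm(d, model_spec("y", "gaussian", fixed = c("x", "g")))
  expect_equal(coef(fit), coef(lm(y ~ x + g, d)), tolerance = 1e-10)
})

test_that("gamma fits refuse non-positive responses with an instructive error", {
  d <- data.frame(y = c(0, 1.2, 3.4))
  expect_error(fit_activity_glm(d, model_spec("y", "gamma")), "non-positive")
  expect_message(d2 <- drop_nonpositive(d, "y"), "1 row")
  expect_equal(attr(d2, "n_dropped_nonpositive"), 1L)
  expect_silent(fit_activity_glm(d2, model_spec("y", "gamma")))
})

test_that("the LRT is degenerate against itself and powerful under a real effect", {
  set.seed(8)
  d <- data.frame(g = factor(rep(c("A", "B"), each = 400)))
  d$y <- rpois(800, c(1, 3)[as.integer(d$g)])
  f1 <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "g"))
  f0 <- fit_activity_glm(d, model_spec("y", "poisson"))
  self <- lrt(f1, f1)
  expect_equal(self$chi2, 0)
  expect_equal(self$p_value, 1)
  strong <- lrt(f1, f0)
  expect_equal(strong$df, 1)
  expect_lt(strong$p_value, 1e-6)
  expect_error(lrt(f0, f1), "not nested")
  d$x <- rnorm(800)
  fx <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "x"))
  expect_error(lrt(f1, fx), "not nested")
})

test_that("pairwise contrasts enumerate level pairs and adjustment is monotone", {
  set.seed(3)
  n <- 300
  d <- data.frame(g = factor(rep(c("a", "b", "c"), each = n)))
  d$y <- rpois(3 * n, exp(c(0.2, 0.5, 1.0))[as.integer(d$g)])
  fit <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "g"))
  ct <- pairwise_contrasts(fit, "g")
  expect_equal(nrow(ct), 3)
  expect_true(all(ct$p_adjusted >= ct$p_value - 1e-12))
  expect_true(all(ct$ci_low <= ct$estimate & ct$estimate <= ct$ci_high))
  expect_error(pairwise_contrasts(fit, "nope"), "not in model data")
})

test_that("contrasts match the estimated-marginal-means implementation", {
  skip_if_not_installed("emmeans")
  set.seed(3)
  n <- 300
  d <- data.frame(g = factor(rep(c("a", "b", "c"), each = n)))
  d$y <- rpois(3 * n, exp(c(0.2, 0.5, 1.0))[as.integer(d$g)])
  fit <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "g"))
  ct <- pairwise_contrasts(fit, "g")
  em <- summary(pairs(emmeans::emmeans(fit$model, "g")), infer = TRUE,
                type = "response")
  expect_equal(ct$estimate, em$ratio, tolerance = 1e-6)
  # emmeans adjusts with multivariate t; ours is its normal large-sample limit
  expect_equal(ct$p_adjusted, em$p.value, tolerance = 0.02)
  expect_equal(ct$ci_low, em$asymp.LCL %||% em$lower.CL, tolerance = 0.01)

  # gamma inverse link: ratios of predicted means
  d$t <- rgamma(3 * n, 2, rate = 2 / c(2, 3, 5)[as.integer(d$g)])
  fg <- fit_activity_glm(d, model_spec("t", "gamma", "inverse", fixed = "g"))
  ctg <- pairwise_contrasts(fg, "g")
  emg <- summary(pairs(emmeans::regrid(emmeans::emmeans(fg$model, "g"), "log")),
                 infer = TRUE, type = "response")
  expect_equal(ctg$estimate, emg$ratio, tolerance = 1e-6)
  expect_equal(ctg$ci_low, emg$lower.CL, tolerance = 0.02)
  expect_equal(ctg$ci_high, emg$upper.CL, tolerance = 0.02)
})

test_that("a two-level contrast equals the back-transformed coefficient", {
  set.seed(4)
  d <- data.frame(g = factor(rep(c("a", "b"), each = 200)))
  d$y <- rpois(400, c(2, 3)[as.integer(d$g)])
  fit <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "g"))
  ct <- pairwise_contrasts(fit, "g")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$estimate, exp(-coef(fit)[["gb"]]), tolerance = 1e-10)
  expect_equal(ct$p_adjusted, ct$p_value)
})

test_that("the candidate set has 16 models including the null, closed over the menu", {
  specs <- build_candidate_set("n_returns", "negative_binomial")
  expect_length(specs, 16)
  expect_true(any(vapply(specs, function(s) length(s$fixed) == 0, logical(1))))
  menu <- c("sex", "season", "tmean_c", "precip_mm", "sex:season")
  for (s in specs) {
    expect_true(all(s$fixed %in% menu))
    expect_equal(s$random, c("bat_id", "year"))
  }
  # deterministic
  expect_identical(names(specs), names(build_candidate_set("x", "gaussian")))
})

test_that("AIC ranking sorts, ties share the best set, and row order is irrelevant", {
  set.seed(9)
  d <- data.frame(g = factor(rep(c("A", "B"), each = 1000)))
  d$y <- rpois(2000, c(1.5, 3.0)[as.integer(d$g)])
  f1 <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "g"))
  f0 <- fit_activity_glm(d, model_spec("y", "poisson"))
  tab <- select_by_aic(list(sex_model = f1, null = f0))
  expect_equal(tab$model[1], "sex_model")
  expect_gt(tab$delta_aic[2], 2)
  expect_true(!is.unsorted(tab$aic))
  # identical fits tie with delta 0, both in the best set
  ties <- select_by_aic(list(a = f1, b = f1))
  expect_equal(ties$delta_aic, c(0, 0))
  expect_true(all(ties$in_best_set))
  # row-order invariance of the input table
  d2 <- d[sample(nrow(d)), ]
  f1b <- fit_activity_glm(d2, model_spec("y", "poisson", fixed = "g"))
  expect_equal(f1b$aic, f1$aic, tolerance = 1e-9)
  # differing data sizes are rejected
  f_small <- fit_activity_glm(d[1:100, ], model_spec("y", "poisson"))
  expect_error(select_by_aic(list(f1, f_small)), "differing numbers")
})

test_that("with no group variance the GLMM collapses to the GLM", {
  set.seed(12)
  nb <- 50; nn <- 10
  d <- data.frame(bat_id = factor(rep(1:nb, each = nn)),
                  year = factor(sample(2015:2017, nb * nn, TRUE)),
                  g = factor(rep(c("A", "B"), each = nb / 2 * nn)))
  d$y <- rpois(nrow(d), c(2, 3)[as.integer(d$g)]) # truth: zero random variance
  fm <- fit_activity_glmm(d, model_spec("y", "poisson", fixed = "g",
                                        random = c("bat_id", "year")))
  fg <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "g"))
  expect_equal(coef(fm), coef(fg), tolerance = 0.01)
  if (fm$engine == "glmmTMB") {
    vc <- glmmTMB::VarCorr(fm$model)$cond
    expect_lt(as.numeric(vc$bat_id), 0.01)
  }
})

test_that("a planted bat-level intercept SD of 0.5 is recovered", {
  set.seed(13)
  nb <- 100; nn <- 20
  d <- data.frame(bat_id = factor(rep(1:nb, each = nn)),
                  year = factor(sample(2015:2018, nb * nn, TRUE)))
  u <- rnorm(nb, 0, 0.5)
  d$y <- rpois(nrow(d), exp(log(2) + u[as.integer(d$bat_id)]))
  fm <- fit_activity_glmm(d, model_spec("y", "poisson", random = c("bat_id", "year")))
  expect_equal(fm$engine, "glmmTMB")
  sd_hat <- sqrt(as.numeric(glmmTMB::VarCorr(fm$model)$cond$bat_id))
  expect_gt(sd_hat, 0.35)
  expect_lt(sd_hat, 0.65)
})

test_that("GLMM and GLM fixed effects agree in sign", {
  set.seed(14)
  nb <- 40; nn <- 10
  d <- data.frame(bat_id = factor(rep(1:nb, each = nn)),
                  year = factor(sample(2015:2017, nb * nn, TRUE)),
                  g = factor(rep(c("A", "B"), each = nb / 2 * nn)))
  u <- rnorm(nb, 0, 0.4)
  d$y <- rpois(nrow(d), exp(log(2) + 0.6 * (d$g == "B") + u[as.integer(d$bat_id)]))
  fm <- fit_activity_glmm(d, model_spec("y", "poisson", fixed = "g",
                                        random = c("bat_id", "year")))
  fg <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "g"))
  expect_equal(sign(coef(fm)[["gB"]]), sign(coef(fg)[["gB"]]))
})

test_that("the GLMM fallback records itself and keeps cluster-robust SEs", {
  # Gaussian response with a constant column defeats glmmTMB? No: force the
  # fallback by making the optimizer fail on a degenerate 2-row-per-group fit
  set.seed(15)
  d <- data.frame(bat_id = factor(rep(1:3, each = 2)),
                  year = factor(rep(2015:2016, 3)),
                  y = rpois(6, 2))
  fm <- suppressWarnings(
    fit_activity_glmm(d, model_spec("y", "poisson", random = c("bat_id", "year"))))
  expect_s3_class(fm, "activity_fit")
  expect_true(fm$engine %in% c("glmmTMB", "glm_cluster"))
  if (fm$engine == "glm_cluster") expect_match(fm$fallback, "glmmTMB")
})

test_that("effect sizes back-transform per link with monotone CI endpoints", {
  # log link: a coefficient of 0.3855 is a ratio of about 1.47
  set.seed(16)
  d <- data.frame(g = factor(rep(c("a", "b"), each = 500)))
  d$y <- rpois(1000, c(2, 2 * exp(0.3855))[as.integer(d$g)])
  fit <- fit_activity_glm(d, model_spec("y", "poisson", fixed = "g"))
  ef <- effect_report(fit)
  expect_equal(ef$effect, exp(ef$estimate), tolerance = 1e-12)
  expect_equal(ef$effect[ef$term == "gb"], 1.47, tolerance = 0.1)
  expect_true(all(ef$effect_low < ef$effect_high))
  expect_equal(exp(0.3855), 1.4704, tolerance = 1e-4)

  # identity link: effects are reported directly as differences
  d$z <- rnorm(1000, c(10, 12)[as.integer(d$g)])
  fz <- fit_activity_glm(d, model_spec("z", "gaussian", fixed = "g"))
  efz <- effect_report(fz)
  expect_equal(efz$effect, efz$estimate)
  expect_equal(efz$effect_scale, rep("difference", 2))

  # inverse link: ratio of predicted means vs the reference level
  d$t <- rgamma(1000, 2, rate = 2 / c(2, 3)[as.integer(d$g)])
  ft <- fit_activity_glm(d, model_spec("t", "gamma", "inverse", fixed = "g"))
  eft <- effect_report(ft)
  mu <- tapply(d$t, d$g, mean)
  expect_equal(eft$effect[eft$term == "gb"], unname(mu["b"] / mu["a"]),
               tolerance = 0.02)
})
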