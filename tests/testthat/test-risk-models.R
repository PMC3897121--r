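test_that("AICc matches the published model-comparison arithmetic", {
  expect_equal(round_half_away(aicc(-202.578, 5, 367), 1), 415.3)
  expect_equal(round_half_away(aicc(-227.479, 2, 367), 0), 459)
  expect_equal(aicc(0, 1, 1e9), 2, tolerance = 1e-6)  # reduces to AIC
  expect_error(aicc(-10, 5, 6), "n > k \\+ 1")
  # strictly above AIC, monotone decreasing in n toward it
  ll <- -100; k <- 4
  a <- vapply(c(10, 50, 500, 5e4), function(n) aicc(ll, k, n), numeric(1))
  expect_true(all(diff(a) < 0))
  expect_true(all(a > -2 * ll + 2 * k))
})

test_that("Akaike weights: symmetry, shift invariance, published value", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  a <- c(aicc(-227.479, 2, 367), aicc(-210.299, 3, 367),
         aicc(-204.703, 4, 367), aicc(-202.578, 5, 367))
  w <- akaike_weights(a)
  expect_equal(round(w[4], 3), 0.748)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(a + 100), w, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    w <- akaike_weights(runif(6, 100, 200))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("relative importance sums weights over models containing a variable", {
  members <- list("length", c("length", "mindepth"),
                  c("length", "mindepth", "range"),
                  c("length", "mindepth", "range", "eoo"))
  w <- c(0.000, 0.005, 0.212, 0.784)  # published weight column
  imp <- relative_importance(w, members)
  expect_equal(unname(imp["length"]), 1.001, tolerance = 0.01)  # in every model
  expect_gte(imp[["eoo"]], 0.78)
  expect_lte(imp[["eoo"]], 0.79)
  # a variable in no model scores 0
  imp2 <- relative_importance(c(0.6, 0.4), list("a", "a"))
  expect_equal(unname(imp2), 1)
  expect_equal(unname(relative_importance(c(1), list(character(0)))),
               numeric(0))
})

test_that("intercept-only logistic fit equals the logit of prevalence", {
  d <- data.frame(y = rep(c(1, 0), c(30, 70)))
  f <- fit_logistic_glm(y ~ 1, d)
  expect_equal(unname(f$coefficients), log(30 / 70), tolerance = 1e-6)
  expect_equal(f$k, 1)
  expect_equal(f$n, 100)
  expect_lt(f$logLik, 0)
})

test_that("one-covariate fit matches a grid-search likelihood oracle", {
  set.seed(21)
  x <- rnorm(20)
  y <- rbinom(20, 1, plogis(-0.3 + 1.1 * x))
  f <- fit_logistic_glm(y ~ x, data.frame(x = x, y = y))
  loglik <- function(b0, b1) sum(y * (b0 + b1 * x) - log(1 + exp(b0 + b1 * x)))
  # coarse grid then refined grid around the coarse optimum
  g <- expand.grid(b0 = seq(-5, 5, 0.1), b1 = seq(-5, 5, 0.1))
  ll <- mapply(loglik, g$b0, g$b1)
  best <- g[which.max(ll), ]
  g2 <- expand.grid(b0 = seq(best$b0 - 0.2, best$b0 + 0.2, 0.001),
                    b1 = seq(best$b1 - 0.2, best$b1 + 0.2, 0.001))
  ll2 <- mapply(loglik, g2$b0, g2$b1)
  best2 <- g2[which.max(ll2), ]
  expect_equal(unname(f$coefficients), c(best2$b0, best2$b1),
               tolerance = 1e-3)
  expect_gte(f$logLik + 1e-9, max(ll2))
  # score equations satisfied: sum((y - p) x_j) ~ 0
  expect_equal(sum(y - f$fitted), 0, tolerance = 1e-8)
  expect_equal(sum((y - f$fitted) * x), 0, tolerance = 1e-8)
  expect_true(all(f$fitted > 0 & f$fitted < 1))
})

test_that("degenerate and separated designs are reported explicitly", {
  expect_error(fit_logistic_glm(y ~ x, data.frame(y = rep(1, 10),
                                                  x = rnorm(10))),
               "separation")
  d <- data.frame(y = rep(c(0, 1), each = 10), x = c(1:10, 21:30))
  expect_warning(fit_logistic_glm(y ~ x, d), "separation")
  d2 <- data.frame(y = rbinom(20, 1, 0.5), x = rnorm(20))
  d2$x2 <- d2$x
  expect_error(fit_logistic_glm(y ~ x + x2, d2), "rank-deficient")
})

test_that("GLMM with variance pinned at zero reproduces the GLM exactly", {
  t <- derive_features(simulate_species(sim_config(n_species = 300),
                                        seed = 9))
  d <- t[!is.na(t$threatened), ]
  d$zlen <- standardize(log10(d$max_length_cm))
  glm_fit <- fit_logistic_glm(threatened ~ zlen, d)
  glmm_fit <- fit_logistic_glmm(threatened ~ zlen, d, fix_zero = TRUE)
  expect_equal(glmm_fit$coefficients, glm_fit$coefficients,
               tolerance = 1e-4)
  expect_equal(unname(glmm_fit$varcomp), rep(0, 3))
  expect_equal(glmm_fit$logLik, glm_fit$logLik)
})

test_that("GLMM on data without group effects stays near the GLM", {
  cfg <- sim_config(n_species = 500,
                    re_sd = c(order = 0, family = 0, genus = 0))
  t <- derive_features(simulate_species(cfg, seed = 14))
  tr <- sim_truth(t)
  d <- data.frame(y = tr$true_threatened,
                  zlen = standardize(log10(t$max_length_cm)),
                  family = t$family)
  glm_fit <- fit_logistic_glm(y ~ zlen, d)
  glmm_fit <- fit_logistic_glmm(y ~ zlen, d, random = "family")
  expect_lt(sum(glmm_fit$varcomp), 0.15)  # ~0, up to finite-sample noise
  expect_equal(unname(glmm_fit$coefficients), unname(glm_fit$coefficients),
               tolerance = 2 * max(glm_fit$se))
  expect_equal(glmm_fit$k, 3)  # 2 fixed effects + 1 variance component
})

test_that("strong family effects favour the GLMM over the GLM (negative dAIC)", {
  cfg <- sim_config(n_species = 800,
                    re_sd = c(order = 0, family = 1.5, genus = 0))
  t <- derive_features(simulate_species(cfg, seed = 30))
  tr <- sim_truth(t)
  d <- data.frame(y = tr$true_threatened,
                  zlen = standardize(log10(t$max_length_cm)),
                  family = t$family)
  glm_fit <- fit_logistic_glm(y ~ zlen, d)
  glmm_fit <- fit_logistic_glmm(y ~ zlen, d, random = "family")
  aic <- function(f) -2 * f$logLik + 2 * f$k
  expect_lt(aic(glmm_fit) - aic(glm_fit), 0)
  expect_gt(glmm_fit$varcomp[["family"]], 0.2)
})

test_that("nested random-effect variances are labelled by taxonomy level", {
  cfg <- sim_config(n_species = 600,
                    re_sd = c(order = 0.3, family = 1, genus = 0.3))
  t <- derive_features(simulate_species(cfg, seed = 8))
  tr <- sim_truth(t)
  d <- data.frame(y = tr$true_threatened,
                  zlen = standardize(log10(t$max_length_cm)),
                  order = t$order, family = t$family, genus = t$genus)
  f <- fit_logistic_glmm(y ~ zlen, d)
  expect_named(f$varcomp, c("order", "family", "genus"))
  expect_true(all(f$varcomp >= 0))
  expect_equal(f$k, 5)  # 2 fixed + 3 variance components
})

test_that("effect size expression evaluates verbatim", {
  expect_equal(effect_size_pct(1.7, 0), 0)
  expect_equal(effect_size_pct(0, 1), 0.26894 - 0.11920, tolerance = 1e-4)
  expect_equal(effect_size_pct(0, -1), -effect_size_pct(0, 1))
})

test_that("variance-decomposition R2 follows the logit-link formula", {
  r <- r2_glmm_components(1, 1)
  expect_equal(r$R2_marginal, 1 / (2 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(r$R2_marginal, 0.18904, tolerance = 1e-4)
  expect_equal(r$R2_conditional, 0.37808, tolerance = 1e-4)
  expect_equal(r2_glmm_components(0, 2)$R2_marginal, 0)
  r0 <- r2_glmm_components(1.3, 0)
  expect_equal(r0$R2_marginal, r0$R2_conditional)
  # marginal R2 grows with the true fixed-effect size, noise held fixed
  r2_at <- function(scale, seed) {
    cfg <- sim_config(n_species = 400,
                      beta = c(intercept = 0, length = scale,
                               min_depth = -scale, depth_range = 0, eoo = 0),
                      re_sd = c(order = 0, family = 0.5, genus = 0))
    t <- simulate_species(cfg, seed = seed)
    tr <- sim_truth(t)
    d <- data.frame(y = tr$true_threatened,
                    zlen = standardize(log10(t$max_length_cm)),
                    zmd = standardize(log10(t$min_depth_m + 1)),
                    family = t$family)
    r2_glmm(fit_logistic_glmm(y ~ zlen + zmd, d, random = "family"))$R2_marginal
  }
  expect_lt(r2_at(0.3, 77), r2_at(2, 77))
})

test_that("compare_models orders deltas and weights consistently", {
  t <- derive_features(simulate_species(sim_config(n_species = 400),
                                        seed = 4))
  d <- prepare_predictors(t)
  d <- d[!is.na(d$threatened), ]
  fits <- list(len = fit_logistic_glm(threatened ~ log_length, d),
               full = fit_logistic_glm(threatened ~ log_length +
                                         log_min_depth, d))
  cmp <- compare_models(fits)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
  expect_equal(sum(cmp$delta_AICc == 0), 1)
  expect_true(all(cmp$delta_AICc >= 0))
  expect_equal(cmp$AICc,
               vapply(fits, function(f) aicc(f$logLik, f$k, f$n),
                      numeric(1)), ignore_attr = TRUE)
})
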