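#' Fit a binomial logistic GLM for threat status
#'
#' Maximum-likelihood logistic regression of the binary threatened
#' indicator (1 = CR/EN/VU, 0 = LC) on standardized traits. Complete
#' separation is reported explicitly rather than silently returning huge
#' coefficients.
#'
#' @param formula model formula, e.g.
#'   `threatened ~ z_length + z_min_depth`.
#' @param data data frame holding the response and predictors; rows with
#'   missing values in the model variables are dropped (complete-case).
#' @return A `risk_fit` object: coefficients with standard errors, log
#'   likelihood, parameter count `k`, `n`, fitted probabilities, empty
#'   variance components, and the underlying [stats::glm] object.
#' @export
fit_logistic_glm <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2)
    stop("response has no variation (all ", unique(y)[1],
         "): complete separation, cannot fit")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial("logit"),
               na.action = stats::na.omit),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep_warn || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    big <- names(which.max(abs(stats::coef(fit)[-1])))
    warning("possible complete separation (covariate '", big,
            "'): coefficients may be unbounded")
  }
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: aliased coefficient(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  ll <- stats::logLik(fit)
  new_risk_fit(
    coefficients = stats::coef(fit),
    se = sqrt(diag(stats::vcov(fit))),
    varcomp = stats::setNames(numeric(0), character(0)),
    logLik = as.numeric(ll), k = attr(ll, "df"), n = stats::nobs(fit),
    converged = fit$converged, singular = FALSE,
    fixed_linpred = stats::predict(fit, type = "link"),
    fitted = stats::fitted(fit), model = fit, formula = formula)
}

#' Fit a binomial logistic GLMM with nested taxonomic random intercepts
#'
#' Approximate maximum-likelihood fit (Laplace approximation to the
#' marginal likelihood, via [lme4::glmer]) of the threatened-vs-LC response
#' with random intercepts for nested taxonomy levels, e.g.
#' `order/family/genus`, to absorb phylogenetic non-independence. The
#' parameter count `k` is the number of fixed effects plus the number of
#' variance components. With `fix_zero = TRUE` (or no random terms) all
#' variance components are pinned at zero, in which case the marginal
#' likelihood is exactly the GLM likelihood and the fit reduces to
#' [fit_logistic_glm()].
#'
#' @inheritParams fit_logistic_glm
#' @param random character vector of grouping columns ordered from
#'   outermost to innermost (default `c("order", "family", "genus")`).
#' @param fix_zero pin all random-effect variances at zero.
#' @return A `risk_fit` with per-level variance components (`varcomp`), an
#'   honest `converged` flag and a `singular` flag (a variance estimated at
#'   the zero boundary is flagged, not an error).
#' @export
fit_logistic_glmm <- function(formula, data,
                              random = c("order", "family", "genus"),
                              fix_zero = FALSE) {
  if (fix_zero || length(random) == 0) {
    out <- fit_logistic_glm(formula, data)
    out$varcomp <- stats::setNames(rep(0, length(random)), random)
    return(out)
  }
  miss <- setdiff(random, names(data))
  if (length(miss) > 0)
    stop("random-effect column(s) not in data: ", paste(miss, collapse = ", "))
  re <- paste0("(1 | ", paste(random, collapse = "/"), ")")
  full <- stats::as.formula(paste(deparse(formula), "+", re))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(full, data = data, family = stats::binomial("logit"),
                na.action = stats::na.omit, nAGQ = 1L),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  vc <- lme4::VarCorr(fit)
  varcomp <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  # lme4 names nested groups innermost-first, e.g. "genus:(family:order)";
  # the level is the first ':'-token. Re-order outermost-first.
  lev <- vapply(strsplit(names(varcomp), ":", fixed = TRUE),
                function(p) gsub("[()]", "", p[1]), character(1))
  names(varcomp) <- lev
  varcomp <- varcomp[intersect(random, lev)]
  conv_fail <- any(grepl("failed to converge|convergence code",
                         msgs, ignore.case = TRUE))
  ll <- stats::logLik(fit)
  beta <- lme4::fixef(fit)
  new_risk_fit(
    coefficients = beta,
    se = sqrt(diag(as.matrix(stats::vcov(fit)))),
    varcomp = varcomp,
    logLik = as.numeric(ll), k = length(beta) + length(varcomp),
    n = stats::nobs(fit),
    converged = !conv_fail, singular = lme4::isSingular(fit),
    fixed_linpred = as.numeric(
      lme4::getME(fit, "X") %*% beta),
    fitted = stats::fitted(fit), model = fit, formula = formula)
}

new_risk_fit <- function(...) structure(list(...), class = "risk_fit")

#' @export
print.risk_fit <- function(x, ...) {
  kind <- if (length(x$varcomp) > 0) "binomial GLMM" else "binomial GLM"
  cat("<risk_fit> ", kind, ", n = ", x$n, ", k = ", x$k,
      ", logLik = ", format(x$logLik, digits = 6), "\n", sep = "")
  print(cbind(estimate = x$coefficients, se = x$se))
  if (length(x$varcomp) > 0) {
    cat("variance components:\n")
    print(x$varcomp)
    if (isTRUE(x$singular)) cat("(singular fit: variance at boundary)\n")
  }
  if (!isTRUE(x$converged)) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1). Requires `n > k + 1`;
#' converges to plain AIC as n grows.
#'
#' @param logLik log likelihood at the optimum.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @return The AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1 (n = ", n,
                       ", k = ", k, ")")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a set of AICc values
#'
#' w_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2)), with Delta relative to
#' the minimum. Invariant to additive shifts; sums to 1.
#'
#' @param aicc_values numeric vector with at least one finite value.
#' @return Numeric vector of weights.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(any(is.finite(aicc_values)))
  d <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-d / 2)
  w / sum(w, na.rm = TRUE)
}

#' Relative variable importance from Akaike weights
#'
#' The importance of a variable is the sum of the Akaike weights of the
#' models that contain it, in `[0, 1]`.
#'
#' @param weights Akaike weights over a common model set.
#' @param members list (one element per model) of character vectors naming
#'   the variables each model contains.
#' @return Named numeric vector of importances over all variables seen.
#' @export
relative_importance <- function(weights, members) {
  stopifnot(length(weights) == length(members))
  vars <- unique(unlist(members))
  vapply(vars, function(v)
    sum(weights[vapply(members, function(m) v %in% m, logical(1))]),
    numeric(1))
}

#' Effect of a one-SD increase on the threat probability scale
#'
#' Computes `1/(1 + exp(b0 + b1)) - 1/(1 + exp(b0 + 2 b1))`, the published
#' probability-scale effect of a one standard deviation increase in a
#' standardized trait. Note the expression uses `1/(1 + exp(x))` (the
#' complement of the standard logistic), so only the magnitude (and the
#' antisymmetry in `b1`) is interpretation-safe; see the methods vignette.
#'
#' @param b0 intercept on the logit scale.
#' @param b1 standardized coefficient on the logit scale.
#' @return The effect expressed as a proportion.
#' @export
effect_size_pct <- function(b0, b1) {
  1 / (1 + exp(b0 + b1)) - 1 / (1 + exp(b0 + 2 * b1))
}

#' Marginal and conditional R2 for binomial GLMMs
#'
#' Variance-decomposition R2 for logit-link mixed models
#' (Nakagawa–Schielzeth): the marginal R2 is the fixed-effect variance over
#' the total (fixed + random + distribution-specific) variance, with
#' pi^2/3 as the logit residual variance; the conditional R2 adds the
#' random-effect variance to the numerator.
#'
#' @param fit a `risk_fit` (its fixed-effect linear predictor supplies the
#'   fixed-effect variance; its `varcomp` the random-effect variance).
#' @return A `variance_decomposition` list: `sigma2_fixed`, `sigma2_random`,
#'   `sigma2_dist`, `R2_marginal`, `R2_conditional`.
#' @export
r2_glmm <- function(fit) {
  stopifnot(inherits(fit, "risk_fit"))
  r2_glmm_components(stats::var(fit$fixed_linpred), sum(fit$varcomp))
}

#' @rdname r2_glmm
#' @param sigma2_fixed variance of the fixed-effect linear predictor.
#' @param sigma2_random sum of random-intercept variance components.
#' @export
r2_glmm_components <- function(sigma2_fixed, sigma2_random = 0) {
  s_dist <- pi^2 / 3
  tot <- sigma2_fixed + sigma2_random + s_dist
  structure(list(sigma2_fixed = sigma2_fixed,
                 sigma2_random = sigma2_random,
                 sigma2_dist = s_dist,
                 R2_marginal = sigma2_fixed / tot,
                 R2_conditional = (sigma2_fixed + sigma2_random) / tot),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("R2(marginal) = ", format(x$R2_marginal, digits = 4),
      ", R2(conditional) = ", format(x$R2_conditional, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' AICc comparison table for a set of fitted models
#'
#' @param fits named list of `risk_fit` objects fitted to the same data.
#' @return A `model_comparison` data frame ordered as supplied (by
#'   increasing complexity, by convention), with k, logLik, AICc, delta
#'   AICc, and Akaike weight.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  n <- unique(vapply(fits, `[[`, numeric(1), "n"))
  if (length(n) > 1)
    warning("models fitted to different n: ", paste(n, collapse = ", "),
            "; AICc comparison is not strictly valid")
  ai <- vapply(fits, function(f) aicc(f$logLik, f$k, f$n), numeric(1))
  out <- data.frame(
    model = if (!is.null(names(fits))) names(fits) else
      paste0("m", seq_along(fits)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AICc = ai, delta_AICc = ai - min(ai),
    weight = akaike_weights(ai),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}
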