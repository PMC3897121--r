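#' Add log10-transformed predictor columns for the predictive models
#'
#' The predictive (non-mixed) threat models use log10-transformed traits.
#' Length and Extent of Occurrence are strictly positive and transformed as
#' log10(x); minimum depth can legitimately be 0 m, so the depth variables
#' are transformed as log10(x + 1).
#'
#' @param t a `species_table` with derived features (see
#'   [derive_features()]).
#' @return The table with `log_length`, `log_min_depth`, `log_depth_range`,
#'   `log_eoo` columns added.
#' @export
prepare_predictors <- function(t) {
  if (!"depth_range" %in% names(t)) t <- derive_features(t)
  t$log_length <- log10(t$max_length_cm)
  t$log_min_depth <- log10(t$min_depth_m + 1)
  t$log_depth_range <- log10(t$depth_range + 1)
  t$log_eoo <- log10(t$eoo_km2)
  t
}

#' Fit an ordered sequence of predictive logistic GLMs
#'
#' Fits binomial logit GLMs of increasing complexity to the
#' threatened-vs-LC response on the common complete-case subset of all
#' variables used by any model (so AICc values are comparable), and reports
#' k, log likelihood, AICc, delta AICc, Akaike weight, in-sample AUC, and
#' Nagelkerke pseudo-R2 per model.
#'
#' @param t a `species_table` with `threatened` and the predictor columns
#'   referenced by the formulas (see [prepare_predictors()]).
#' @param formulas list of model formulas ordered by increasing complexity.
#' @return A `model_comparison` data frame with `auc` and `pseudo_r2`
#'   columns (pseudo-R2 variant recorded in the `pseudo_r2_method`
#'   attribute), plus the fitted models in the `fits` attribute.
#' @export
fit_model_sequence <- function(t, formulas) {
  stopifnot(length(formulas) >= 1)
  vars <- unique(unlist(lapply(formulas, all.vars)))
  miss <- setdiff(vars, names(t))
  if (length(miss) > 0)
    stop("formula references missing column(s): ",
         paste(miss, collapse = ", "))
  cc <- stats::complete.cases(t[, vars, drop = FALSE])
  d <- as.data.frame(t)[cc, , drop = FALSE]
  fits <- lapply(formulas, fit_logistic_glm, data = d)
  names(fits) <- vapply(formulas, function(f)
    paste(deparse(f), collapse = ""), character(1))
  out <- compare_models(fits)
  out$auc <- vapply(fits, function(f) {
    y <- f$model$y
    roc_auc(f$fitted, y)$auc
  }, numeric(1))
  out$pseudo_r2 <- vapply(fits, function(f) {
    null_dev <- f$model$null.deviance
    dev <- f$model$deviance
    n <- f$n
    (1 - exp((dev - null_dev) / n)) / (1 - exp(-null_dev / n))
  }, numeric(1))
  attr(out, "pseudo_r2_method") <- "Nagelkerke"
  attr(out, "fits") <- fits
  attr(out, "n") <- sum(cc)
  out
}

#' ROC curve and AUC
#'
#' The AUC is the Mann–Whitney probability that a random positive outscores
#' a random negative, with ties counted one half (computed from ranks, so
#' it equals the all-pairs enumeration exactly). True/false positive rates
#' and accuracy are evaluated over a 0–1 threshold grid with the `>=`
#' classification rule.
#'
#' @param scores numeric prediction scores (probabilities).
#' @param labels binary labels (0/1 or logical); both classes must be
#'   present.
#' @param thresholds threshold grid, default `seq(0, 1, by = 0.01)`.
#' @return A `roc_result` list: `thresholds`, `tpr`, `fpr`, `accuracy`,
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, thresholds = seq(0, 1, by = 0.01)) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc needs both classes present (n1 = ", n1, ", n0 = ", n0, ")")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tpr <- vapply(thresholds, function(th) sum(scores >= th & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thresholds, function(th) sum(scores >= th & labels == 0L) / n0,
                numeric(1))
  acc <- vapply(thresholds, function(th)
    (sum(scores >= th & labels == 1L) + sum(scores < th & labels == 0L)) /
      (n1 + n0), numeric(1))
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 accuracy = acc, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", format(x$auc, digits = 4), ", ",
      length(x$thresholds), " thresholds\n", sep = "")
  invisible(x)
}

#' Accuracy-maximizing classification threshold
#'
#' Scans the threshold grid of a [roc_auc()] result for the accuracy
#' maximum; ties are broken toward 0.5 (the default classification rule).
#'
#' @param roc a `roc_result`.
#' @return The chosen threshold.
#' @export
choose_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  best <- max(roc$accuracy)
  cands <- roc$thresholds[roc$accuracy >= best - 1e-12]
  cands[which.min(abs(cands - 0.5))]
}

#' Predict which Data Deficient species are likely threatened
#'
#' Applies a fitted threat model to the DD species with the model's
#' predictors present; species at or above the threshold (`>=`, not `>`)
#' are classified as likely threatened. Species lacking a required
#' predictor are excluded and reported.
#'
#' @param fit a `risk_fit` from [fit_logistic_glm()] or the best row of
#'   [fit_model_sequence()].
#' @param dd a `species_table` (or data frame) of DD species with the
#'   predictor columns.
#' @param threshold classification threshold, default 0.5.
#' @return A list: `n_predicted_threatened`, `n_scored`, `probabilities`
#'   (named by species_id), `excluded` species ids.
#' @export
predict_dd <- function(fit, dd, threshold = 0.5) {
  stopifnot(inherits(fit, "risk_fit"))
  vars <- setdiff(all.vars(fit$formula), all.vars(fit$formula[[2]]))
  miss <- setdiff(vars, names(dd))
  if (length(miss) > 0)
    stop("DD table lacks predictor column(s): ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(dd[, vars, drop = FALSE])
  excluded <- dd$species_id[!ok]
  if (!any(ok)) {
    warning("no scorable DD species (all lack predictors)")
    return(list(n_predicted_threatened = 0L, n_scored = 0L,
                probabilities = stats::setNames(numeric(0), character(0)),
                excluded = excluded))
  }
  p <- stats::predict(fit$model, newdata = as.data.frame(dd)[ok, , drop = FALSE],
                      type = "response")
  names(p) <- dd$species_id[ok]
  list(n_predicted_threatened = sum(p >= threshold),
       n_scored = sum(ok), probabilities = p, excluded = excluded)
}

#' Apportion Data Deficient species across Red List categories
#'
#' After the model predicts how many scorable DD species are likely
#' threatened, the remaining scorable DD species are split between NT and
#' LC using the observed NT:LC ratio r. Two readings of "distributed
#' according to the ratio" are supported: `mode = "share"` (the default,
#' which reproduces the published counts) takes `NT_est = round(r *
#' remainder)`; `mode = "odds"` reads r as odds, `NT_est = round(r / (1 +
#' r) * remainder)`. Rounding is nearest (half away from zero) with the
#' remainder assigned to LC, so totals are conserved exactly. DD species
#' that could not be scored stay DD.
#'
#' @param n_dd_total total DD species.
#' @param n_dd_scored DD species with sufficient traits to score.
#' @param n_pred_threatened scorable DD species predicted threatened.
#' @param nt_obs,lc_obs observed NT and LC counts (define r = NT/LC).
#' @param thr_obs observed threatened count (CR + EN + VU).
#' @param mode `"share"` or `"odds"`.
#' @param ratio optionally override r = `nt_obs / lc_obs`.
#' @return A `predicted_category_table` data frame with rows threatened /
#'   NT / LC / DD, columns `known`, `estimated`, `total`, `pct` (of the
#'   grand total, unrounded).
#' @export
apportion <- function(n_dd_total, n_dd_scored, n_pred_threatened,
                      nt_obs, lc_obs, thr_obs,
                      mode = c("share", "odds"), ratio = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_pred_threatened <= n_dd_scored, n_dd_scored <= n_dd_total)
  r <- if (is.null(ratio)) nt_obs / lc_obs else ratio
  if (!is.finite(r) || r <= 0) stop("NT:LC ratio must be positive")
  remainder <- n_dd_scored - n_pred_threatened
  frac <- if (mode == "share") r else r / (1 + r)
  nt_est <- round_half_away(frac * remainder)
  nt_est <- min(nt_est, remainder)  # guard: share > 1 cannot overdraw
  lc_est <- remainder - nt_est
  dd_remaining <- n_dd_total - n_dd_scored
  grand <- thr_obs + nt_obs + lc_obs + n_dd_total
  out <- data.frame(
    category = c("threatened", "NT", "LC", "DD"),
    known = c(thr_obs, nt_obs, lc_obs, 0),
    estimated = c(n_pred_threatened, nt_est, lc_est, dd_remaining),
    stringsAsFactors = FALSE)
  out$total <- out$known + out$estimated
  out$pct <- 100 * out$total / grand
  stopifnot(sum(out$total) == grand)
  attr(out, "ratio") <- r
  attr(out, "mode") <- mode
  class(out) <- c("predicted_category_table", "data.frame")
  out
}
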