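#' Summarize Red List categories by group
#'
#' Produces one row per group plus a grand-total row, with counts per
#' category, the threatened count (CR + EN + VU), and percentages. Two
#' percentage conventions are printed in the source tables: per-category
#' percentages relative to the grand total (the all-taxa table) or relative
#' to the group (the by-habitat table); choose with `category_percent`.
#' The threatened percentage is always relative to the group, and the group
#' size percentage relative to the grand total.
#'
#' @param t a `species_table`.
#' @param group_by name of the grouping column (e.g. `"habitat"`,
#'   `"family"`, or a custom label column).
#' @param category_percent `"grand"` or `"group"` denominator for the
#'   per-category percentages.
#' @return A `category_table` data frame; percentages are unrounded (use
#'   [round_half_away()] to reproduce printed 1 d.p. values).
#' @export
summarize_categories <- function(t, group_by,
                                 category_percent = c("grand", "group")) {
  category_percent <- match.arg(category_percent)
  if (!group_by %in% names(t))
    stop("unknown group field: '", group_by, "'")
  grand <- nrow(t)
  groups <- unique(t[[group_by]])
  one <- function(label, rows) {
    counts <- vapply(REDLIST_CATEGORIES,
                     function(cc) sum(rows$category == cc), integer(1))
    n <- nrow(rows)
    thr <- sum(counts[THREATENED_CATEGORIES])
    denom <- if (category_percent == "grand") grand else n
    data.frame(group = label, n_total = n,
               pct_of_grand = if (grand > 0) 100 * n / grand else 0,
               n_threatened = thr,
               pct_threatened = if (n > 0) 100 * thr / n else 0,
               as.list(counts),
               as.list(stats::setNames(
                 if (denom > 0) 100 * counts / denom else counts * 0,
                 paste0("pct_", REDLIST_CATEGORIES))),
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(groups, function(g)
    one(g, t[t[[group_by]] == g, , drop = FALSE])))
  out <- rbind(out, one("All", t))
  rownames(out) <- NULL
  class(out) <- c("category_table", "data.frame")
  out
}

#' One-tailed binomial test of family-level threat
#'
#' Tests whether a family's threatened fraction among data-sufficient
#' species exceeds (or falls below) a null rate common to all families,
#' using exact binomial tail probabilities (no normal approximation;
#' families are small). Both tails include P(X = k).
#'
#' @param k threatened count, `0 <= k <= n`.
#' @param n data-sufficient species count.
#' @param null_rate null threat proportion in (0, 1). See
#'   [default_null_rate()] for the recommended data-driven default.
#' @param family optional family label carried into the result.
#' @return A one-row data frame with `p_greater` = P(X >= k), `p_lower` =
#'   P(X <= k) under Binomial(n, null_rate), and a significance `band` in
#'   `ns`, `0.05`, `0.01`, `0.001` from the smaller tail.
#' @export
family_binomial_test <- function(k, n, null_rate, family = NA_character_) {
  stopifnot(k >= 0, k <= n, null_rate > 0, null_rate < 1)
  if (n == 0) {
    p_greater <- p_lower <- 1
  } else {
    p_greater <- stats::pbinom(k - 1, n, null_rate, lower.tail = FALSE)
    p_lower <- stats::pbinom(k, n, null_rate)
  }
  p_min <- min(p_greater, p_lower)
  band <- if (p_min < 0.001) "0.001" else if (p_min < 0.01) "0.01" else
    if (p_min < 0.05) "0.05" else "ns"
  data.frame(family = family, n_data_sufficient = n, n_threatened = k,
             null_rate = null_rate, p_greater = p_greater,
             p_lower = p_lower, band = band, stringsAsFactors = FALSE)
}

#' Data-driven null rate for the family threat test
#'
#' The null expectation that extinction risk is equal across families is
#' the overall threatened fraction among data-sufficient (non-DD) species
#' of the supplied table, optionally restricted (e.g. to marine habitats).
#' The published 35.6% null is not derivable from the all-species totals,
#' so it is never hard-coded; supply it explicitly if desired.
#'
#' @param t a `species_table`.
#' @param subset optional logical vector restricting the table first.
#' @return Proportion threatened among data-sufficient species.
#' @export
default_null_rate <- function(t, subset = NULL) {
  if (!is.null(subset)) t <- t[subset, , drop = FALSE]
  ds <- t$category != "DD"
  if (!any(ds)) stop("no data-sufficient species")
  sum(t$category %in% THREATENED_CATEGORIES) / sum(ds)
}

#' Run the family binomial test across all families of a table
#'
#' @inheritParams default_null_rate
#' @param null_rate numeric null proportion, or `"auto"` to compute it from
#'   the table via [default_null_rate()].
#' @return A data frame with one [family_binomial_test()] row per family.
#' @export
family_threat_tests <- function(t, null_rate = "auto") {
  if (identical(null_rate, "auto")) null_rate <- default_null_rate(t)
  fams <- sort(unique(t$family))
  do.call(rbind, lapply(fams, function(f) {
    rows <- t[t$family == f, , drop = FALSE]
    ds <- rows$category != "DD"
    family_binomial_test(sum(rows$category %in% THREATENED_CATEGORIES),
                         sum(ds), null_rate, family = f)
  }))
}

#' Combine subpopulation/regional Red List categories
#'
#' Each regional category is mapped to a numeric score (LC = 0, NT = 1,
#' VU = 2, EN = 3, CR = 4), scores are averaged across regions, the mean is
#' rounded half away from zero, and mapped back to a category. DD regions
#' carry no information and are ignored; an all-DD input returns DD.
#'
#' @param regional character vector of Red List categories.
#' @return A single category string.
#' @export
combine_regional_categories <- function(regional) {
  stopifnot(all(regional %in% REDLIST_CATEGORIES))
  scale <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4)
  vals <- scale[regional[regional != "DD"]]
  if (length(vals) == 0) return("DD")
  names(scale)[round_half_away(mean(vals)) + 1]
}
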