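#' Clean a raw landings panel
#'
#' FAO-style landings exports are string-typed: a cell is a number, the
#' token `"<0.5"` (landings below half a tonne, assigned 0.5 t), or `"."`
#' (data unavailable/unobtainable, assigned zero and counted as missing).
#' Any other token is an error naming the row. The missing count is kept on
#' the result for [missing_fraction()]. Idempotent on already-clean panels.
#'
#' @param raw data frame with columns `country`, `year`, `category`,
#'   `value` (character or numeric).
#' @return A `landings_panel` data frame with numeric `tonnes` replacing
#'   `value`, and attributes `n_missing`, `n_entries`.
#' @export
clean_landings <- function(raw) {
  stopifnot(all(c("country", "year", "category", "value") %in% names(raw)))
  v <- raw$value
  if (is.numeric(v)) {
    tonnes <- v
    n_missing <- 0L
  } else {
    v <- trimws(as.character(v))
    is_missing <- v == "."
    is_half <- v == "<0.5"
    tonnes <- suppressWarnings(as.numeric(v))
    tonnes[is_missing] <- 0
    tonnes[is_half] <- 0.5
    bad <- is.na(tonnes)
    if (any(bad))
      stop("unparseable landings value '", v[which(bad)[1]], "' at row ",
           which(bad)[1])
    n_missing <- sum(is_missing)
  }
  if (any(tonnes < 0)) stop("negative landings at row ",
                            which(tonnes < 0)[1])
  out <- data.frame(country = raw$country,
                    year = as.integer(raw$year),
                    category = raw$category,
                    tonnes = tonnes, stringsAsFactors = FALSE)
  attr(out, "n_missing") <- n_missing
  attr(out, "n_entries") <- nrow(out)
  class(out) <- c("landings_panel", "data.frame")
  out
}

#' Fraction of landings entries reported missing
#'
#' @param p a `landings_panel` from [clean_landings()].
#' @return Percentage of entries that were the `"."` missing code
#'   (unrounded; the printed figure rounds to 0 d.p.).
#' @export
missing_fraction <- function(p) {
  stopifnot(inherits(p, "landings_panel"))
  n <- attr(p, "n_entries")
  if (is.null(n) || n == 0) stop("empty landings panel")
  100 * attr(p, "n_missing") / n
}

#' Per-country share of mean annual landings over a window
#'
#' For each country, landings are summed per year, averaged over the
#' (inclusive) window -- years with no reported entries count as zero --
#' and expressed as a percent share of the summed means, so shares sum
#' to 100.
#'
#' @param p a `landings_panel`.
#' @param years inclusive year window, default `2000:2009`.
#' @return Data frame `country`, `mean_annual_t`, `share_pct` sorted by
#'   decreasing share.
#' @export
decade_share <- function(p, years = 2000:2009) {
  stopifnot(inherits(p, "landings_panel"))
  sub <- p[p$year %in% years, , drop = FALSE]
  if (nrow(sub) == 0) stop("window ", min(years), "-", max(years),
                           " is outside the data")
  tot <- stats::aggregate(tonnes ~ country, data = sub, FUN = sum)
  tot$mean_annual_t <- tot$tonnes / length(years)
  tot$share_pct <- 100 * tot$mean_annual_t / sum(tot$mean_annual_t)
  out <- tot[order(-tot$share_pct), c("country", "mean_annual_t", "share_pct")]
  rownames(out) <- NULL
  out
}

#' Yearly ray/shark log-ratio of taxonomically differentiated landings
#'
#' Per year, the log of total ray landings over total shark landings,
#' after excluding the undifferentiated aggregate ('sharks, rays, skates,
#' etc') and chimaera reporting categories. A positive value means more
#' rays than sharks were landed. The log base is configurable (natural log
#' by default); only the sign and zero-crossing carry interpretation, and
#' those are base-invariant.
#'
#' @param p a `landings_panel`.
#' @param meta category metadata: data frame with `category` and `group`
#'   (one of `shark`, `ray`, `chimaera`, `mixed`).
#' @param exclude_groups groups dropped before the ratio, default
#'   `c("mixed", "chimaera")`.
#' @param log_base base of the logarithm, default `exp(1)`.
#' @return Data frame `year`, `shark_t`, `ray_t`, `log_ratio`; years where
#'   either group total is zero get `NA` (never +/-Inf).
#' @export
ray_shark_log_ratio <- function(p, meta,
                                exclude_groups = c("mixed", "chimaera"),
                                log_base = exp(1)) {
  stopifnot(inherits(p, "landings_panel"),
            all(c("category", "group") %in% names(meta)))
  unknown <- setdiff(unique(p$category), meta$category)
  if (length(unknown) > 0)
    stop("categories without metadata: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  grp <- meta$group[match(p$category, meta$category)]
  keep <- !(grp %in% exclude_groups)
  sub <- p[keep, , drop = FALSE]
  grp <- grp[keep]
  years <- sort(unique(p$year))
  tot <- function(g) vapply(years, function(yr)
    sum(sub$tonnes[sub$year == yr & grp == g]), numeric(1))
  shark_t <- tot("shark"); ray_t <- tot("ray")
  lr <- ifelse(shark_t > 0 & ray_t > 0,
               log(ray_t / shark_t) / log(log_base), NA_real_)
  data.frame(year = years, shark_t = shark_t, ray_t = ray_t,
             log_ratio = lr)
}

#' Over-representation of threatened species by EEZ span
#'
#' Compares the distribution of the number of national jurisdictions
#' (EEZs) spanned between threatened species and all species: per span
#' bin, the log ratio of the proportion of threatened species to the
#' proportion of all species. Positive values mean threatened species are
#' over-represented at that span.
#'
#' @param all_spans integer vector of EEZ counts, one per species (all
#'   species).
#' @param thr_spans EEZ counts for threatened species only.
#' @param breaks optional cut points for binning (passed to [base::cut()]
#'   with `include.lowest = TRUE, right = FALSE`); default one bin per
#'   distinct span value.
#' @param log_base base of the logarithm, default natural log.
#' @return Data frame `bin`, `n_all`, `n_threatened`, `prop_all`,
#'   `prop_threatened`, `log_ratio`; bins empty in either set get `NA`.
#' @export
eez_overrepresentation <- function(all_spans, thr_spans, breaks = NULL,
                                   log_base = exp(1)) {
  stopifnot(all(all_spans >= 1), all(thr_spans >= 1))
  if (is.null(breaks)) {
    lev <- sort(unique(c(all_spans, thr_spans)))
    b_all <- factor(all_spans, levels = lev)
    b_thr <- factor(thr_spans, levels = lev)
  } else {
    b_all <- cut(all_spans, breaks, include.lowest = TRUE, right = FALSE)
    b_thr <- cut(thr_spans, breaks, include.lowest = TRUE, right = FALSE)
  }
  n_all <- table(b_all); n_thr <- table(b_thr)
  p_all <- as.numeric(n_all) / length(all_spans)
  p_thr <- as.numeric(n_thr) / length(thr_spans)
  lr <- ifelse(p_all > 0 & p_thr > 0,
               log(p_thr / p_all) / log(log_base), NA_real_)
  data.frame(bin = names(n_all), n_all = as.integer(n_all),
             n_threatened = as.integer(n_thr),
             prop_all = p_all, prop_threatened = p_thr,
             log_ratio = lr, stringsAsFactors = FALSE)
}

#' Percent biomass decline implied by B/B_MSY
#'
#' If B_MSY is assumed to occur at a fraction f of unexploited biomass,
#' a stock at biomass ratio B/B_MSY has declined by 100 (1 - B/B_MSY * f)
#' percent from the unexploited state. A product above 1 (stock above
#' unexploited biomass) is clipped to 0% decline with a warning.
#'
#' @param b_over_bmsy biomass relative to B_MSY (> 0).
#' @param bmsy_fraction assumed B_MSY as a fraction of unexploited biomass
#'   (in (0, 1]).
#' @return Percent decline (unrounded).
#' @export
decline_from_bmsy <- function(b_over_bmsy, bmsy_fraction) {
  stopifnot(b_over_bmsy > 0, bmsy_fraction > 0, bmsy_fraction <= 1)
  prod <- b_over_bmsy * bmsy_fraction
  if (any(prod > 1)) {
    warning("B above unexploited biomass: decline clipped at 0%")
    prod <- pmin(prod, 1)
  }
  100 * (1 - prod)
}

#' Printed decline interval across B_MSY assumptions
#'
#' Evaluates [decline_from_bmsy()] at the bounding B_MSY fractions and
#' rounds the interval outward to whole percent (floor of the lower bound,
#' ceiling of the upper), the convention of the printed "declined by
#' between X% and Y%" statement.
#'
#' @param b_over_bmsy biomass relative to B_MSY.
#' @param fractions B_MSY fractions of unexploited biomass, default
#'   `c(0.3, 0.5)`.
#' @return Integer vector `c(lower, upper)` percent decline.
#' @export
decline_interval <- function(b_over_bmsy, fractions = c(0.3, 0.5)) {
  d <- vapply(fractions, function(f) decline_from_bmsy(b_over_bmsy, f),
              numeric(1))
  c(lower = floor(min(d)), upper = ceiling(max(d)))
}
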