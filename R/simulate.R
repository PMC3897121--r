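#' Simulation configuration with the stated-world defaults
#'
#' Central configuration for the three generators. Defaults emulate the
#' empirical structure of the global chondrichthyan dataset: 1,041 species;
#' body length log-normal around 80 cm; Extent of Occurrence spanning
#' roughly 354 km2 to 278 million km2 with a latent correlation of 0.58
#' with body length; about 46% of species deepwater; DD rates of 38.4%
#' (shallow) and 57.6% (deepwater), so data deficiency is depth-dependent
#' (non-random masking); threatened species split CR:EN:VU = 25:43:113 and
#' non-threatened NT:LC = 132:241; a landings missing-entry rate of 10.88%.
#' True logistic coefficients are on the standardized log10-trait scale.
#'
#' @param n_species number of species.
#' @param n_orders,families_per_order,genera_per_family taxonomy shape.
#' @param length_meanlog,length_sdlog log-normal body length (cm).
#' @param eoo_meanlog10,eoo_sdlog10 log10-normal Extent of Occurrence
#'   (km2), clipped to `eoo_range`.
#' @param eoo_length_cor latent correlation between log length and log EOO.
#' @param range_length_cor latent correlation between log depth range and
#'   log length.
#' @param eoo_range clip bounds for EOO, km2.
#' @param deep_prob probability a species is deepwater (min depth >= 200 m).
#' @param beta named true logistic coefficients
#'   (`intercept`, `length`, `min_depth`, `depth_range`, `eoo`) on the
#'   standardized scale.
#' @param re_sd named random-intercept SDs for `order`, `family`, `genus`.
#' @param threat_split,safe_split category split proportions for simulated
#'   threatened (CR/EN/VU) and non-threatened (NT/LC) species.
#' @param dd_rate_shallow,dd_rate_deep DD-masking probabilities.
#' @param n_cells,cell_area_km2 incidence grid shape.
#' @param n_countries,years,n_shark_cats,n_ray_cats,n_chimaera_cats,
#'   include_mixed landings panel shape.
#' @param missing_rate,half_rate injection rates for the `"."` and
#'   `"<0.5"` tokens.
#' @param ray_trend yearly log-scale growth of ray landings relative to
#'   sharks (gives the log-ratio series a known sign structure).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 1041,
                       n_orders = 13, families_per_order = 4,
                       genera_per_family = 4,
                       length_meanlog = log(80), length_sdlog = 0.7,
                       eoo_meanlog10 = 6.3, eoo_sdlog10 = 1.1,
                       eoo_length_cor = 0.58, range_length_cor = 0.4,
                       eoo_range = c(354, 2.78e8),
                       deep_prob = 0.46,
                       beta = c(intercept = -0.4, length = 1.2,
                                min_depth = -1.3, depth_range = -0.6,
                                eoo = 0.3),
                       re_sd = c(order = 0.25, family = 0.6, genus = 0.25),
                       threat_split = c(CR = 25, EN = 43, VU = 113),
                       safe_split = c(NT = 132, LC = 241),
                       dd_rate_shallow = 0.384, dd_rate_deep = 0.576,
                       n_cells = 15000, cell_area_km2 = 23322,
                       n_countries = 25, years = 1950:2009,
                       n_shark_cats = 8, n_ray_cats = 8,
                       n_chimaera_cats = 2, include_mixed = TRUE,
                       missing_rate = 0.1088, half_rate = 0.005,
                       ray_trend = 0.02) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 1,
            all(re_sd >= 0),
            all(c("intercept", "length", "min_depth", "depth_range",
                  "eoo") %in% names(beta)),
            dd_rate_shallow >= 0, dd_rate_shallow <= 1,
            dd_rate_deep >= 0, dd_rate_deep <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (n_orders < 1 || families_per_order < 1 || genera_per_family < 1)
    stop("degenerate taxonomy shape: all levels need >= 1 group")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a species trait/status table with known ground truth
#'
#' Traits are drawn per the configuration; the true threat probability
#' follows the logistic model with nested taxonomic random intercepts on
#' standardized log10 traits; threatened species are split across CR/EN/VU
#' (and non-threatened across NT/LC) by the configured proportions; a
#' depth-dependent DD mask then hides the category of some species. The
#' hidden truth (true category, true threat indicator and probability,
#' mask flag) is attached as the `truth` attribute; retrieve it with
#' [sim_truth()]. Output is a pure function of `(cfg, seed)`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A `species_table` with a `truth` attribute.
#' @export
simulate_species <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    n <- cfg$n_species
    n_fam <- cfg$n_orders * cfg$families_per_order
    n_gen <- n_fam * cfg$genera_per_family
    genus_i <- sample.int(n_gen, n, replace = TRUE)
    family_i <- (genus_i - 1) %/% cfg$genera_per_family + 1
    order_i <- (family_i - 1) %/% cfg$families_per_order + 1

    z_len <- stats::rnorm(n)
    z_eoo <- cfg$eoo_length_cor * z_len +
      sqrt(1 - cfg$eoo_length_cor^2) * stats::rnorm(n)
    z_rng <- cfg$range_length_cor * z_len +
      sqrt(1 - cfg$range_length_cor^2) * stats::rnorm(n)

    max_length_cm <- round(exp(cfg$length_meanlog +
                                 cfg$length_sdlog * z_len), 1)
    eoo_km2 <- round(pmin(pmax(10^(cfg$eoo_meanlog10 +
                                     cfg$eoo_sdlog10 * z_eoo),
                               cfg$eoo_range[1]), cfg$eoo_range[2]))
    deep <- stats::rbinom(n, 1, cfg$deep_prob) == 1
    min_depth_m <- ifelse(deep,
                          round(200 + stats::rlnorm(n, log(250), 0.7)),
                          round(stats::rexp(n, rate = 1 / 25)))
    depth_range <- pmax(5, round(exp(log(500) + 0.8 * z_rng)))
    max_depth_m <- min_depth_m + depth_range
    habitat <- suggest_habitat(min_depth_m, max_depth_m)

    eta <- cfg$beta[["intercept"]] +
      cfg$beta[["length"]] * standardize(log10(max_length_cm)) +
      cfg$beta[["min_depth"]] * standardize(log10(min_depth_m + 1)) +
      cfg$beta[["depth_range"]] * standardize(log10(depth_range + 1)) +
      cfg$beta[["eoo"]] * standardize(log10(eoo_km2)) +
      stats::rnorm(cfg$n_orders, 0, cfg$re_sd[["order"]])[order_i] +
      stats::rnorm(n_fam, 0, cfg$re_sd[["family"]])[family_i] +
      stats::rnorm(n_gen, 0, cfg$re_sd[["genus"]])[genus_i]
    p_true <- stats::plogis(eta)
    thr_true <- stats::rbinom(n, 1, p_true)

    true_category <- character(n)
    true_category[thr_true == 1] <-
      sample(names(cfg$threat_split), sum(thr_true), replace = TRUE,
             prob = cfg$threat_split)
    true_category[thr_true == 0] <-
      sample(names(cfg$safe_split), n - sum(thr_true), replace = TRUE,
             prob = cfg$safe_split)

    p_dd <- ifelse(deep, cfg$dd_rate_deep, cfg$dd_rate_shallow)
    masked <- stats::rbinom(n, 1, p_dd) == 1
    category <- ifelse(masked, "DD", true_category)

    tab <- data.frame(
      species_id = sprintf("sp%04d", seq_len(n)),
      order = sprintf("order%02d", order_i),
      family = sprintf("family%03d", family_i),
      genus = sprintf("genus%03d", genus_i),
      species = sprintf("species%04d", seq_len(n)),
      category = category,
      max_length_cm = max_length_cm,
      min_depth_m = min_depth_m,
      max_depth_m = max_depth_m,
      eoo_km2 = eoo_km2,
      habitat = habitat,
      n_eez = 1L + stats::rpois(n, lambda = pmin(40, eoo_km2 / 1e7)),
      stringsAsFactors = FALSE)
    out <- as_species_table(tab, source = paste0("simulate_species(seed=",
                                                 seed, ")"))
    attr(out, "truth") <- data.frame(
      species_id = tab$species_id,
      true_category = true_category,
      true_threatened = as.integer(true_category %in%
                                     THREATENED_CATEGORIES),
      true_p = p_true,
      dd_masked = masked,
      stringsAsFactors = FALSE)
    out
  })
}

#' Ground truth of a simulated species table
#'
#' @param t a table from [simulate_species()].
#' @return The hidden-truth data frame (true category, true threat
#'   indicator and probability, DD mask flag).
#' @export
sim_truth <- function(t) {
  tr <- attr(t, "truth")
  if (is.null(tr)) stop("table carries no simulation truth")
  tr
}

#' Simulate a species-by-cell incidence matrix
#'
#' Each species occupies a contiguous block of equal-area cells whose total
#' area approximates its Extent of Occurrence to within one cell (at least
#' one cell). Pure function of `(t, cfg, seed)`.
#'
#' @param t a `species_table` with `eoo_km2` present for all species.
#' @param cfg a [sim_config()] (grid shape, cell area).
#' @param seed integer seed.
#' @return An `incidence_matrix`.
#' @export
simulate_incidence <- function(t, cfg = sim_config(), seed = 1) {
  if (any(is.na(t$eoo_km2))) stop("all species need eoo_km2 to place ranges")
  n_cells <- cfg$n_cells
  k <- pmax(1L, as.integer(round(t$eoo_km2 / cfg$cell_area_km2)))
  if (any(k > n_cells))
    stop("grid too small: largest range needs ", max(k), " of ",
         n_cells, " cells")
  with_seed(seed, {
    start <- vapply(k, function(ki) sample.int(n_cells - ki + 1L, 1L),
                    integer(1))
    triplets <- data.frame(
      cell_id = sprintf("c%05d", unlist(Map(function(s, ki)
        seq.int(s, s + ki - 1L), start, k))),
      species_id = rep(t$species_id, k),
      stringsAsFactors = FALSE)
    cells <- data.frame(cell_id = sprintf("c%05d", seq_len(n_cells)),
                        area_km2 = cfg$cell_area_km2)
    incidence_matrix(triplets, cells)
  })
}

#' Simulate a raw landings panel
#'
#' A country x year x reporting-category panel with log-normal tonnages,
#' a configurable upward trend in ray landings relative to sharks (so the
#' ray/shark log-ratio series has known sign structure), and `"."` /
#' `"<0.5"` tokens injected at the configured rates. Pure function of
#' `(cfg, seed)`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A list: `panel` (raw data frame with a character `value`
#'   column, ready for [clean_landings()]) and `meta` (category metadata
#'   with `category`, `group`, `is_nei`).
#' @export
simulate_landings <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  cats <- data.frame(
    category = c(sprintf("shark_sp_%02d", seq_len(cfg$n_shark_cats)),
                 sprintf("ray_sp_%02d", seq_len(cfg$n_ray_cats)),
                 if (cfg$n_chimaera_cats > 0)
                   sprintf("chimaera_%02d", seq_len(cfg$n_chimaera_cats)),
                 if (cfg$include_mixed) "sharks, rays, skates, etc"),
    stringsAsFactors = FALSE)
  cats$group <- c(rep("shark", cfg$n_shark_cats),
                  rep("ray", cfg$n_ray_cats),
                  rep("chimaera", cfg$n_chimaera_cats),
                  if (cfg$include_mixed) "mixed")
  cats$is_nei <- cats$group == "mixed"
  with_seed(seed, {
    grid <- expand.grid(country = sprintf("country%02d",
                                          seq_len(cfg$n_countries)),
                        year = cfg$years, category = cats$category,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grp <- cats$group[match(grid$category, cats$category)]
    base <- stats::rlnorm(nrow(grid), log(500), 1)
    trend <- ifelse(grp == "ray",
                    exp(cfg$ray_trend * (grid$year - min(cfg$years))), 1)
    tonnes <- round(base * trend, 1)
    value <- as.character(tonnes)
    u <- stats::runif(nrow(grid))
    value[u < cfg$missing_rate] <- "."
    value[u >= cfg$missing_rate &
            u < cfg$missing_rate + cfg$half_rate] <- "<0.5"
    grid$value <- value
    list(panel = grid, meta = cats)
  })
}
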