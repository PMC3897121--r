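#' Species-by-cell incidence matrix on an equal-area grid
#'
#' Container for boolean occupancy of species over a generic equal-area
#' cell tessellation (the canonical grid uses ~23,322 km2 hexagons, but any
#' equal-area tessellation works). Occupancy is stored sparsely.
#'
#' @param triplets data frame with columns `cell_id`, `species_id` (one row
#'   per occupied cell; a third value column, if present, is ignored beyond
#'   being nonzero).
#' @param cells data frame with columns `cell_id`, `area_km2` (positive),
#'   and optional `lon`, `lat`.
#' @return An `incidence_matrix`: list with sparse logical `occupancy`
#'   (species x cells, dimnames set) and the `cells` metadata.
#' @export
incidence_matrix <- function(triplets, cells) {
  stopifnot(all(c("cell_id", "species_id") %in% names(triplets)),
            all(c("cell_id", "area_km2") %in% names(cells)))
  if (any(cells$area_km2 <= 0)) stop("cell areas must be positive")
  if (any(duplicated(cells$cell_id))) stop("duplicated cell_id in metadata")
  unknown <- setdiff(unique(triplets$cell_id), cells$cell_id)
  if (length(unknown) > 0)
    stop("triplets reference unknown cell(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  sp <- sort(unique(as.character(triplets$species_id)))
  ce <- as.character(cells$cell_id)
  occ <- Matrix::sparseMatrix(
    i = match(as.character(triplets$species_id), sp),
    j = match(as.character(triplets$cell_id), ce),
    x = TRUE, dims = c(length(sp), length(ce)),
    dimnames = list(sp, ce))
  occ <- occ | FALSE  # collapse duplicate triplets to logical
  if (length(sp) > 0 && any(Matrix::rowSums(occ) == 0))
    stop("every species must occupy at least one cell")
  structure(list(occupancy = occ, cells = as.data.frame(cells)),
            class = "incidence_matrix")
}

#' Read an incidence matrix from triplet + cell-metadata CSVs
#'
#' @param triplet_path CSV with `cell_id`, `species_id` columns.
#' @param cells_path CSV with `cell_id`, `area_km2` columns.
#' @return An `incidence_matrix`.
#' @export
read_incidence <- function(triplet_path, cells_path) {
  incidence_matrix(utils::read.csv(triplet_path, colClasses = "character"),
                   utils::read.csv(cells_path))
}

#' Write an incidence matrix as triplet + cell-metadata CSVs
#'
#' @param inc an `incidence_matrix`.
#' @param triplet_path,cells_path output CSV paths.
#' @return `triplet_path`, invisibly.
#' @export
write_incidence <- function(inc, triplet_path, cells_path) {
  tr <- Matrix::summary(methods::as(inc$occupancy, "TsparseMatrix"))
  out <- data.frame(cell_id = colnames(inc$occupancy)[tr$j],
                    species_id = rownames(inc$occupancy)[tr$i],
                    value = 1L)
  out <- out[order(out$cell_id, out$species_id), ]
  utils::write.csv(out, triplet_path, row.names = FALSE)
  utils::write.csv(inc$cells, cells_path, row.names = FALSE)
  invisible(triplet_path)
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("<incidence_matrix> ", nrow(x$occupancy), " species x ",
      ncol(x$occupancy), " cells, ",
      sum(x$occupancy), " occupancies\n", sep = "")
  invisible(x)
}

#' Per-cell species counts by threat status
#'
#' Counts, per cell: all species, threatened (CR/EN/VU), DD, and
#' data-sufficient (non-DD) species, optionally restricted to a species
#' subset (e.g. one habitat class).
#'
#' @param inc an `incidence_matrix`.
#' @param t a `species_table` covering every species in the incidence
#'   matrix (an error lists any missing ids).
#' @param subset optional character vector of species ids, or a predicate
#'   function on the species table returning a logical vector.
#' @return A `cell_scores` data frame: `cell_id`, `area_km2`, `n_species`,
#'   `n_threatened`, `n_dd`, `n_data_sufficient`.
#' @export
cell_counts <- function(inc, t, subset = NULL) {
  stopifnot(inherits(inc, "incidence_matrix"))
  ids <- rownames(inc$occupancy)
  missing_ids <- setdiff(ids, t$species_id)
  if (length(missing_ids) > 0)
    stop("species in incidence but absent from table: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  keep <- ids
  if (!is.null(subset)) {
    if (is.function(subset)) {
      sel <- subset(t)
      stopifnot(is.logical(sel), length(sel) == nrow(t))
      keep <- intersect(ids, t$species_id[sel])
    } else keep <- intersect(ids, as.character(subset))
  }
  cat_of <- t$category[match(keep, t$species_id)]
  occ <- inc$occupancy[keep, , drop = FALSE]
  count_rows <- function(sel)
    if (!any(sel)) rep(0, ncol(occ)) else
      Matrix::colSums(occ[sel, , drop = FALSE])
  out <- data.frame(
    cell_id = colnames(occ),
    area_km2 = inc$cells$area_km2[match(colnames(occ), inc$cells$cell_id)],
    n_species = count_rows(rep(TRUE, length(keep))),
    n_threatened = count_rows(cat_of %in% THREATENED_CATEGORIES),
    n_dd = count_rows(cat_of == "DD"),
    n_data_sufficient = count_rows(cat_of != "DD"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cell_scores", "data.frame")
  out
}

#' Residual-threat scores per cell
#'
#' Ordinary least squares of the threatened count on the data-sufficient
#' count (with intercept); the attached residuals measure greater-than-
#' expected threat after removing the first-order richness effect. They sum
#' to zero and are invariant to cell relabeling.
#'
#' @param scores a `cell_scores` data frame from [cell_counts()].
#' @return The scores with a `residual_threat` column; the fitted
#'   regression is in the `fit` attribute.
#' @export
residual_threat <- function(scores) {
  stopifnot(all(c("n_threatened", "n_data_sufficient") %in% names(scores)))
  if (nrow(scores) < 3) stop("need at least 3 cells")
  if (stats::var(scores$n_data_sufficient) == 0)
    stop("no variation in data-sufficient counts: cannot regress")
  fit <- stats::lm(n_threatened ~ n_data_sufficient, data = scores)
  scores$residual_threat <- stats::resid(fit)
  attr(scores, "fit") <- fit
  scores
}

#' Irreplaceability scores per cell
#'
#' Each species contributes an irreplaceability score s = 1 / (number of
#' cells it occupies): a species confined to one cell scores 1 there. Two
#' cell statistics are in use and both are first-class: `sum_inverse` sums
#' s over the species present in a cell (a cell value of 0.1 means the
#' cell holds one tenth of the species' pooled global ranges);
#' `mean_log10` averages log10(s) over the species present, which controls
#' for richness. Cells holding no subset species get `NA`, not 0, so map
#' quantiles are not diluted.
#'
#' @param inc an `incidence_matrix`.
#' @param subset optional character vector of species ids to score (e.g.
#'   from [endemic_subset()]); default all species.
#' @param variant `"sum_inverse"` or `"mean_log10"`.
#' @return A data frame `cell_id`, `irreplaceability` with the variant
#'   recorded in the `variant` attribute.
#' @export
irreplaceability <- function(inc, subset = NULL,
                             variant = c("sum_inverse", "mean_log10")) {
  variant <- match.arg(variant)
  stopifnot(inherits(inc, "incidence_matrix"))
  occ <- inc$occupancy
  if (!is.null(subset)) {
    subset <- intersect(rownames(occ), as.character(subset))
    if (length(subset) == 0) stop("subset selects no species on the grid")
    occ <- occ[subset, , drop = FALSE]
  }
  s <- 1 / Matrix::rowSums(occ)
  n_in_cell <- Matrix::colSums(occ)
  val <- if (variant == "sum_inverse") {
    as.numeric(Matrix::crossprod(occ, s))
  } else {
    as.numeric(Matrix::crossprod(occ, log10(s))) / n_in_cell
  }
  val[n_in_cell == 0] <- NA_real_
  out <- data.frame(cell_id = colnames(occ), irreplaceability = val,
                    stringsAsFactors = FALSE)
  attr(out, "variant") <- variant
  out
}

#' Select endemic (small-range) species
#'
#' Endemics are species with an Extent of Occurrence strictly below a
#' threshold (the canonical thresholds are 50,000 / 100,000 / 250,000 /
#' 500,000 km2), optionally restricted to threatened species.
#'
#' @param t a `species_table` with `eoo_km2`.
#' @param eoo_threshold threshold in km2.
#' @param threatened_only keep only CR/EN/VU species (default TRUE).
#' @return Character vector of species ids (species with missing EOO are
#'   never selected).
#' @export
endemic_subset <- function(t, eoo_threshold, threatened_only = TRUE) {
  sel <- !is.na(t$eoo_km2) & t$eoo_km2 < eoo_threshold
  if (threatened_only) sel <- sel & t$category %in% THREATENED_CATEGORIES
  t$species_id[sel]
}
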