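#' Read and validate a species trait/status table
#'
#' Reads a CSV with one row per species: taxonomy (`order`, `family`,
#' `genus`, `species`), IUCN Red List `category`, and optional traits
#' (`max_length_cm`, `min_depth_m`, `max_depth_m`, `eoo_km2`, `habitat`,
#' `n_eez`, `endemic_fao_area`). Missing numeric values are empty cells and
#' are preserved as `NA`, never zeroed. Units are fixed: cm total length,
#' metres, km2.
#'
#' Hard errors (regardless of `strict`): a category outside the closed
#' vocabulary `r paste(REDLIST_CATEGORIES, collapse = ", ")`, and duplicated
#' `species_id`. Numeric invariant violations (min depth above max depth,
#' non-positive length or EOO) are errors when `strict = TRUE`, otherwise
#' the offending rows are flagged in a logical `.invalid` column.
#'
#' @param path path to a CSV file with a header row.
#' @param strict reject invalid rows with an error (default) or flag them.
#' @return A `species_table`: a data frame with a `provenance` attribute
#'   recording the source path and row count.
#' @seealso [write_species_table()], [derive_features()]
#' @export
read_species_table <- function(path, strict = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  as_species_table(raw, strict = strict, source = path)
}

#' Build a species table from a data frame
#'
#' Validation backend of [read_species_table()]; useful when the table is
#' constructed in code (e.g. by [simulate_species()]).
#'
#' @param x data frame with at least `species_id`, taxonomy columns,
#'   and `category`.
#' @inheritParams read_species_table
#' @param source provenance label stored on the result.
#' @return A `species_table`.
#' @export
as_species_table <- function(x, strict = TRUE, source = "<in-memory>") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("species_id", "order", "family", "genus", "species",
                "category")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0)
    stop("species table is missing required column(s): ",
         paste(miss, collapse = ", "))

  numeric_cols <- c("max_length_cm", "min_depth_m", "max_depth_m",
                    "eoo_km2", "n_eez")
  for (col in intersect(numeric_cols, names(x))) {
    v <- x[[col]]
    if (is.character(v)) {
      v <- trimws(v)
      v[v == ""] <- NA_character_
      bad <- !is.na(v) & is.na(suppressWarnings(as.numeric(v)))
      if (any(bad))
        stop("non-numeric value in column '", col, "' at row(s): ",
             paste(utils::head(which(bad), 5), collapse = ", "))
      v <- as.numeric(v)
    }
    x[[col]] <- v
  }

  if (nrow(x) > 0) {
    bad_cat <- !(x$category %in% REDLIST_CATEGORIES)
    if (any(bad_cat))
      stop("unknown Red List category '", x$category[which(bad_cat)[1]],
           "' at row ", which(bad_cat)[1],
           " (allowed: ", paste(REDLIST_CATEGORIES, collapse = ", "), ")")
    dup <- duplicated(x$species_id)
    if (any(dup))
      stop("duplicated species_id: ",
           paste(unique(x$species_id[dup]), collapse = ", "))
    tax_empty <- !nzchar(x$order) | !nzchar(x$family) |
      !nzchar(x$genus) | !nzchar(x$species)
    if (any(tax_empty))
      stop("empty taxonomy field(s) at row(s): ",
           paste(utils::head(which(tax_empty), 5), collapse = ", "))
    if ("habitat" %in% names(x)) {
      hab <- x$habitat
      bad_hab <- !is.na(hab) & nzchar(hab) & !(hab %in% HABITAT_CLASSES)
      if (any(bad_hab))
        stop("unknown habitat class '", hab[which(bad_hab)[1]],
             "' at row ", which(bad_hab)[1])
    }

    invalid <- rep(FALSE, nrow(x))
    problem <- rep(NA_character_, nrow(x))
    flag <- function(cond, msg) {
      cond[is.na(cond)] <- FALSE
      problem[cond & !invalid] <<- msg
      invalid <<- invalid | cond
    }
    if (all(c("min_depth_m", "max_depth_m") %in% names(x)))
      flag(x$min_depth_m > x$max_depth_m, "min_depth_m > max_depth_m")
    if ("min_depth_m" %in% names(x))
      flag(x$min_depth_m < 0, "min_depth_m < 0")
    if ("max_length_cm" %in% names(x))
      flag(x$max_length_cm <= 0, "max_length_cm <= 0")
    if ("eoo_km2" %in% names(x))
      flag(x$eoo_km2 <= 0, "eoo_km2 <= 0")

    if (any(invalid)) {
      i <- which(invalid)[1]
      msg <- paste0("invalid row ", i, " (species_id ", x$species_id[i],
                    "): ", problem[i],
                    if (sum(invalid) > 1)
                      paste0(" [and ", sum(invalid) - 1, " more]"))
      if (strict) stop(msg)
      warning(msg, "; rows flagged in '.invalid'")
      x$.invalid <- invalid
    }
  }

  attr(x, "provenance") <- list(source = source, n_rows = nrow(x))
  class(x) <- c("species_table", "data.frame")
  x
}

#' Write a species table to CSV
#'
#' Missing numeric values are written as empty cells so that a write/read
#' round trip reproduces the table exactly.
#'
#' @param t a `species_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(t, path) {
  utils::write.csv(as.data.frame(t), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive modelling features from depth and category fields
#'
#' Adds `depth_range` (max minus min depth, m), `median_depth`
#' (min depth plus half the range, m), and the binary response `threatened`:
#' 1 for CR/EN/VU, 0 for LC, `NA` for NT and DD (both are excluded from the
#' threatened-vs-LC response). Missing depths propagate. Idempotent.
#'
#' @param t a `species_table` with depth columns.
#' @return The table with the derived columns added (recomputed if present).
#' @export
derive_features <- function(t) {
  stopifnot(inherits(t, "species_table"))
  if (!all(c("min_depth_m", "max_depth_m") %in% names(t)))
    stop("derive_features needs min_depth_m and max_depth_m columns")
  t$depth_range <- t$max_depth_m - t$min_depth_m
  t$median_depth <- t$min_depth_m + t$depth_range / 2
  t$threatened <- ifelse(t$category %in% THREATENED_CATEGORIES, 1L,
                         ifelse(t$category == "LC", 0L, NA_integer_))
  t
}

#' Standardize a numeric vector to z-scores
#'
#' Subtracts the mean and divides by the sample standard deviation, computed
#' over non-missing entries; missing values stay missing.
#'
#' @param x numeric vector with at least two non-missing values and
#'   nonzero spread.
#' @return Vector with mean 0 and sample SD 1 over non-missing entries.
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2)
    stop("standardize needs at least 2 non-missing values")
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0)
    stop("cannot standardize: zero variance")
  (x - mean(x[ok])) / s
}

#' Variance inflation factors
#'
#' For each column j of the design matrix, VIF_j = 1 / (1 - R2_j), where
#' R2_j is from the OLS regression of column j on all other columns (with
#' intercept). Used as a collinearity screen before model fitting.
#'
#' @param X numeric matrix or data frame with at least two columns and full
#'   column rank.
#' @return Named numeric vector of VIFs, all >= 1.
#' @export
variance_inflation <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("variance_inflation needs >= 2 columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("design matrix is rank deficient (perfectly collinear columns)")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Suggest a habitat class from depth (synthetic data only)
#'
#' Habitat is an expert-assigned input in real data; this helper exists so
#' the synthetic generator can label species consistently with their depth
#' distribution (deep sea defined as at or below 200 m).
#'
#' @param min_depth_m,max_depth_m depth limits in metres.
#' @return Character vector of habitat classes.
#' @export
suggest_habitat <- function(min_depth_m, max_depth_m) {
  ifelse(min_depth_m >= 200, "deepwater", "coastal_shelf")
}

#' @export
print.species_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<species_table> ", nrow(x), " species (source: ",
      prov$source, ")\n", sep = "")
  tab <- table(factor(x$category, levels = REDLIST_CATEGORIES))
  print(tab)
  invisible(x)
}
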