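#' IUCN Red List category vocabulary (2001, version 3.1)
#'
#' The six categories used throughout the package, ordered from highest to
#' lowest extinction risk, plus Data Deficient. Legacy (pre-2001) categories
#' are rejected at read time.
#'
#' @format Character vectors.
#' @name categories
NULL

#' @rdname categories
#' @export
REDLIST_CATEGORIES <- c("CR", "EN", "VU", "NT", "LC", "DD")

#' @rdname categories
#' @export
THREATENED_CATEGORIES <- c("CR", "EN", "VU")

#' @rdname categories
#' @export
HABITAT_CLASSES <- c("coastal_shelf", "pelagic", "deepwater",
                     "mesopelagic", "freshwater")

#' Round half away from zero
#'
#' Commercial rounding as used in the printed tables: 0.5 always moves away
#' from zero, unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate code under a fixed RNG seed, restoring prior RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
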