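# Fixture builders and independent oracles shared across tests.

# Build a species_table from per-group Red List category counts.
# `groups` is a named list; each element is a named integer vector over
# CR/EN/VU/NT/LC/DD. The group label lands in column `grp`.
table_from_counts <- function(groups) {
  rows <- do.call(rbind, lapply(names(groups), function(g) {
    cts <- groups[[g]]
    data.frame(grp = g, category = rep(names(cts), cts),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  tab <- data.frame(species_id = sprintf("s%04d", seq_len(n)),
                    order = "ord1", family = "fam1", genus = "gen1",
                    species = sprintf("sp%04d", seq_len(n)),
                    category = rows$category, grp = rows$grp,
                    stringsAsFactors = FALSE)
  as_species_table(tab)
}

# The observed all-taxa category counts (by taxon group) of the global
# chondrichthyan assessment.
taxon_counts <- list(
  rays      = c(CR = 14, EN = 28, VU = 65, NT = 62, LC = 114, DD = 256),
  sharks    = c(CR = 11, EN = 15, VU = 48, NT = 67, LC = 115, DD = 209),
  chimaeras = c(CR = 0,  EN = 0,  VU = 0,  NT = 3,  LC = 12,  DD = 22))

# Observed category counts by habitat class.
habitat_counts <- list(
  coastal_shelf = c(CR = 20, EN = 26, VU = 81, NT = 73, LC = 97, DD = 185),
  pelagic       = c(CR = 0,  EN = 3,  VU = 14, NT = 13, LC = 5,  DD = 4),
  deepwater     = c(CR = 2,  EN = 6,  VU = 17, NT = 45, LC = 133, DD = 276),
  mesopelagic   = c(CR = 0,  EN = 0,  VU = 0,  NT = 0,  LC = 4,  DD = 4),
  freshwater    = c(CR = 3,  EN = 8,  VU = 1,  NT = 1,  LC = 2,  DD = 18))

# Exact binomial tails by brute-force pmf enumeration (independent of
# stats::pbinom), for n small enough to enumerate.
enum_binom_tails <- function(k, n, p) {
  pmf <- vapply(0:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
                numeric(1))
  list(p_greater = sum(pmf[(k + 1):(n + 1)]), p_lower = sum(pmf[1:(k + 1)]))
}

# AUC by all-pairs enumeration with ties counted one half.
enum_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Per-cell counts by an explicit loop over all (cell, species) pairs.
brute_cell_counts <- function(inc, tab) {
  occ <- as.matrix(inc$occupancy)
  cells <- colnames(occ)
  out <- data.frame(cell_id = cells, n_species = 0, n_threatened = 0,
                    n_dd = 0, n_data_sufficient = 0,
                    stringsAsFactors = FALSE)
  for (ci in seq_along(cells)) for (si in seq_len(nrow(occ))) {
    if (!occ[si, ci]) next
    cat_s <- tab$category[tab$species_id == rownames(occ)[si]]
    out$n_species[ci] <- out$n_species[ci] + 1
    if (cat_s %in% c("CR", "EN", "VU"))
      out$n_threatened[ci] <- out$n_threatened[ci] + 1
    if (cat_s == "DD") out$n_dd[ci] <- out$n_dd[ci] + 1 else
      out$n_data_sufficient[ci] <- out$n_data_sufficient[ci] + 1
  }
  out
}

# Minimal valid species table rows for hand-built cases.
mini_species <- function(n, category = "LC", ...) {
  extra <- list(...)
  tab <- data.frame(species_id = sprintf("m%03d", seq_len(n)),
                    order = "ord1", family = "fam1", genus = "gen1",
                    species = sprintf("msp%03d", seq_len(n)),
                    category = rep_len(category, n),
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) tab[[nm]] <- extra[[nm]]
  as_species_table(tab)
}
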