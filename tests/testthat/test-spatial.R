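make_toy_incidence <- function(triplets, n_cells = 5, area = 23322) {
  incidence_matrix(triplets,
                   data.frame(cell_id = paste0("c", seq_len(n_cells)),
                              area_km2 = area))
}

test_that("incidence construction validates its inputs", {
  tr <- data.frame(cell_id = c("c1", "c2"), species_id = c("a", "a"))
  inc <- make_toy_incidence(tr)
  expect_s3_class(inc, "incidence_matrix")
  expect_equal(dim(inc$occupancy), c(1, 5))
  expect_error(make_toy_incidence(
    data.frame(cell_id = "c9", species_id = "a")), "unknown cell")
  expect_error(incidence_matrix(tr, data.frame(cell_id = c("c1", "c2"),
                                               area_km2 = c(1, -1))),
               "positive")
})

test_that("incidence round-trips through triplet CSVs", {
  cfg <- sim_config(n_species = 25, n_cells = 300,
                    eoo_meanlog10 = 5.3, eoo_sdlog10 = 0.5,
                    eoo_range = c(354, 2e6))
  t <- simulate_species(cfg, seed = 6)
  inc <- simulate_incidence(t, cfg, seed = 7)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_incidence(inc, p1, p2)
  inc2 <- read_incidence(p1, p2)
  expect_equal(sort(rownames(inc2$occupancy)), sort(rownames(inc$occupancy)))
  common <- rownames(inc$occupancy)
  expect_equal(as.matrix(inc2$occupancy[common, colnames(inc$occupancy)]),
               as.matrix(inc$occupancy))
})

test_that("cell counts match a brute-force loop on random toy grids", {
  for (seed in 1:4) {
    set.seed(seed)
    n_sp <- 20; n_cells <- 30
    tab <- mini_species(n_sp, category = sample(REDLIST_CATEGORIES, n_sp,
                                                replace = TRUE))
    occ <- matrix(runif(n_sp * n_cells) < 0.2, n_sp, n_cells)
    occ[rowSums(occ) == 0, 1] <- TRUE  # every species occupies >= 1 cell
    idx <- which(occ, arr.ind = TRUE)
    inc <- incidence_matrix(
      data.frame(cell_id = paste0("c", idx[, 2]),
                 species_id = tab$species_id[idx[, 1]]),
      data.frame(cell_id = paste0("c", seq_len(n_cells)), area_km2 = 23322))
    got <- cell_counts(inc, tab)
    want <- brute_cell_counts(inc, tab)
    got <- got[match(want$cell_id, got$cell_id), ]
    expect_equal(got$n_species, want$n_species, ignore_attr = TRUE)
    expect_equal(got$n_threatened, want$n_threatened, ignore_attr = TRUE)
    expect_equal(got$n_dd, want$n_dd, ignore_attr = TRUE)
    expect_equal(got$n_data_sufficient, want$n_data_sufficient,
                 ignore_attr = TRUE)
  }
})

test_that("cell counts handle single species, filters and missing ids", {
  tab <- mini_species(2, category = c("LC", "LC"))
  inc <- make_toy_incidence(data.frame(cell_id = c("c2", "c3"),
                                       species_id = c("m001", "m002")))
  got <- cell_counts(inc, tab)
  expect_equal(got$n_species[got$cell_id == "c2"], 1)
  expect_equal(sum(got$n_species), 2)
  # threatened filter on an all-LC table: all zeros
  thr_only <- cell_counts(inc, tab,
                          subset = function(t) t$category %in%
                            THREATENED_CATEGORIES)
  expect_true(all(thr_only$n_species == 0))
  # species present on the grid but missing from the table
  expect_error(cell_counts(inc, tab[1, ]), "absent from table")
})

test_that("residual threat matches the closed-form OLS oracle", {
  sc <- data.frame(cell_id = c("c1", "c2", "c3"),
                   n_threatened = c(2, 4, 9),
                   n_data_sufficient = c(10, 20, 30))
  r <- residual_threat(sc)
  fit <- attr(r, "fit")
  # hand OLS: slope = 0.35, intercept = -2
  expect_equal(unname(coef(fit)), c(-2, 0.35), tolerance = 1e-12)
  expect_equal(r$residual_threat, c(0.5, -1, 0.5), tolerance = 1e-12)
  expect_equal(sum(r$residual_threat), 0, tolerance = 1e-9)
  # perfect linearity -> all residuals zero
  sc2 <- data.frame(n_threatened = c(5, 10, 15, 25),
                    n_data_sufficient = c(10, 20, 30, 50))
  expect_equal(residual_threat(sc2)$residual_threat, rep(0, 4),
               tolerance = 1e-10)
  # invariant to relabeling of cells
  perm <- c(3, 1, 2)
  r2 <- residual_threat(sc[perm, ])
  expect_equal(r2$residual_threat, r$residual_threat[perm],
               ignore_attr = TRUE)
  expect_error(residual_threat(sc[1:2, ]), "3 cells")
  sc3 <- sc; sc3$n_data_sufficient <- 7
  expect_error(residual_threat(sc3), "no variation")
})

test_that("irreplaceability scores follow the reciprocal-range definitions", {
  # species A occupies cells 1..10 of 120; B occupies 1..100
  tr <- rbind(data.frame(cell_id = paste0("c", 1:10), species_id = "A"),
              data.frame(cell_id = paste0("c", 1:100), species_id = "B"))
  cells <- data.frame(cell_id = paste0("c", 1:120), area_km2 = 23322)
  inc <- incidence_matrix(tr, cells)
  si <- irreplaceability(inc, variant = "sum_inverse")
  expect_equal(si$irreplaceability[si$cell_id == "c1"], 0.11)
  expect_equal(si$irreplaceability[si$cell_id == "c50"], 0.01)
  expect_true(is.na(si$irreplaceability[si$cell_id == "c110"]))
  ml <- irreplaceability(inc, variant = "mean_log10")
  expect_equal(ml$irreplaceability[ml$cell_id == "c1"], -1.5)
  # a single-cell species is maximally irreplaceable
  inc1 <- make_toy_incidence(data.frame(cell_id = "c4", species_id = "solo"))
  expect_equal(irreplaceability(inc1)$irreplaceability[4], 1)
  # subset restriction
  sa <- irreplaceability(inc, subset = "A")
  expect_equal(sa$irreplaceability[sa$cell_id == "c1"], 0.1)
  expect_error(irreplaceability(inc, subset = "nope"), "no species")
})

test_that("sum-inverse irreplaceability conserves each species' range weight", {
  cfg <- sim_config(n_species = 40, n_cells = 500,
                    eoo_meanlog10 = 5.5, eoo_range = c(354, 9e6))
  t <- simulate_species(cfg, seed = 9)
  inc <- simulate_incidence(t, cfg, seed = 10)
  si <- irreplaceability(inc, variant = "sum_inverse")
  expect_equal(sum(si$irreplaceability, na.rm = TRUE), nrow(t))
  for (sp in rownames(inc$occupancy)[1:5]) {
    one <- irreplaceability(inc, subset = sp, variant = "sum_inverse")
    expect_equal(sum(one$irreplaceability, na.rm = TRUE), 1)
  }
})

test_that("endemic subsets respect thresholds and nest monotonically", {
  set.seed(20)
  eoo <- c(runif(66, 1e4, 4.9e5), runif(30, 6e5, 1e7))
  tab <- mini_species(96, category = c(rep("EN", 66), rep("LC", 30)),
                      eoo_km2 = eoo)
  sel <- endemic_subset(tab, 5e5)
  expect_length(sel, 66)
  expect_length(endemic_subset(tab, 0), 0)
  subsets <- lapply(c(5e4, 1e5, 2.5e5, 5e5), function(th)
    endemic_subset(tab, th))
  for (i in 1:3) expect_true(all(subsets[[i]] %in% subsets[[i + 1]]))
  # missing EOO is never selected
  tab$eoo_km2[1] <- NA
  expect_false("m001" %in% endemic_subset(tab, 5e5))
})
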