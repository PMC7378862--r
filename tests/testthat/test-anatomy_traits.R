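eta <- 1.002e-9

test_that("derived cell traits follow the defining formulas", {
  cells <- cells_with_areas(cwa = 300, cla = 700)
  d <- derive_cell_traits(cells)
  expect_identical(d$CTA, 1000)
  expect_identical(d$CWD, 0.30)
  expect_equal(d$CWT, 4)

  # a = 20, b = 10: direct arithmetic re-evaluation of the elliptical form
  a <- 20; b <- 10
  cells2 <- toy_cells()[1L, ]
  cells2$lumen_radial_diameter_um <- 2 * a
  cells2$lumen_area_um2 <- pi * a * b
  d2 <- derive_cell_traits(cells2)
  expect_equal(d2$Kh_c, pi * a^3 * b^3 / (4 * eta * (a^2 + b^2)),
               tolerance = 1e-12)
})

test_that("circular lumen reduces to the Hagen-Poiseuille limit", {
  for (r in c(5, 20, 40)) {
    expect_equal(khc_elliptical(r, r, eta), pi * r^4 / (8 * eta),
                 tolerance = 1e-12)
  }
  # through the cell-table path: CLD = 2r, CLA = pi r^2 infers b = a = r
  cells <- toy_cells()[1L, ]
  cells$lumen_radial_diameter_um <- 40
  cells$lumen_area_um2 <- 400 * pi
  d <- derive_cell_traits(cells)
  expect_equal(d$Kh_c, pi * 20^4 / (8 * eta), tolerance = 1e-12)
})

test_that("implausible lumen eccentricity is flagged, not fatal", {
  cells <- toy_cells()
  cells$lumen_area_um2[2L] <- 1e6  # b/a far outside plausibility
  expect_message(d <- derive_cell_traits(cells), "eccentricity")
  expect_equal(nrow(d), 2L)
  expect_equal(nrow(attr(d, "flagged")), 1L)
})

test_that("Mork index splits earlywood and latewood at 1, inclusive", {
  expect_true(classify_mork(3, 12))    # MI = 1, boundary -> latewood
  expect_false(classify_mork(3, 40))   # MI = 0.3
  expect_true(classify_mork(6, 10))    # MI = 2.4
})

test_that("radial file assignment recovers files from coordinates", {
  pre <- toy_cells()
  pre$radial_file_id <- c(7L, 7L, 9L)
  out <- assign_radial_files(pre)
  expect_identical(out$radial_file_id, pre$radial_file_id)  # pass-through

  # 3 files on a regular tangential grid with small jitter
  set.seed(42)
  n <- 20L
  cells <- do.call(rbind, lapply(1:3, function(f) {
    d <- toy_cells()[rep(1L, n), ]
    d$cell_index <- (f - 1L) * n + seq_len(n)
    d$x_um <- f * 50 + rnorm(n, 0, 4)
    d$y_um <- seq_len(n) * 30
    d$true_file <- f
    d
  }))
  cells$radial_file_id <- NULL
  out <- assign_radial_files(cells)
  expect_equal(length(unique(out$radial_file_id)), 3L)
  # perfect recovery: every assigned file contains exactly one generating file
  tab <- table(out$radial_file_id, out$true_file)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # within-file rank follows radial order
  f1 <- out[out$true_file == 1L, ]
  expect_equal(f1$file_rank[order(f1$y_um)], seq_len(n))

  # a single column of cells forms one file
  one <- cells[cells$true_file == 1L, ]
  one$radial_file_id <- NULL
  out1 <- assign_radial_files(one)
  expect_equal(length(unique(out1$radial_file_id)), 1L)

  no_info <- toy_cells()
  no_info$radial_file_id <- NULL
  expect_error(assign_radial_files(no_info), "configuration")
})

test_that("average radial file handles equal, unequal and many files", {
  # two identical files -> average equals either file
  v <- c(500, 400, 300)
  cells <- rbind(cells_with_areas(v, cla = c(700, 600, 500), file_id = 1L),
                 cells_with_areas(v, cla = c(700, 600, 500), file_id = 2L))
  cells$cell_index <- seq_len(nrow(cells))
  d <- derive_cell_traits(cells)
  avg <- average_radial_file(d)
  expect_equal(avg$CN, 3)
  expect_equal(avg$traits$CWA, v)

  # lengths 4 and 6, constant trait -> constant average, CN = 5
  cells <- rbind(cells_with_areas(rep(7, 4), cla = rep(600, 4), file_id = 1L),
                 cells_with_areas(rep(7, 6), cla = rep(600, 6), file_id = 2L))
  cells$cell_index <- seq_len(nrow(cells))
  avg <- average_radial_file(derive_cell_traits(cells))
  expect_equal(avg$CN, 5)
  expect_equal(avg$traits$CWA, rep(7, 6))

  # >= 20 random files: CN x mean(avg CWA) ~ total CWA / n_files within 1%
  set.seed(7)
  cells <- do.call(rbind, lapply(1:25, function(f) {
    n <- sample(8:15, 1L)
    cells_with_areas(runif(n, 200, 900), cla = runif(n, 300, 1200),
                     file_id = f)
  }))
  cells$cell_index <- seq_len(nrow(cells))
  d <- derive_cell_traits(cells)
  avg <- average_radial_file(d)
  expect_equal(avg$CN * mean(avg$traits$CWA), sum(d$CWA) / 25,
               tolerance = 0.01)
})

test_that("ring aggregation identities hold by construction", {
  cells <- cells_with_areas(c(500, 400, 300), cla = c(700, 600, 500))
  d <- derive_cell_traits(cells)
  rr <- aggregate_ring(d)
  expect_equal(rr$RWA, 1200)               # CN = 3, mean CWA = 400
  expect_equal(rr$HCUE * rr$RWA, rr$Kh_r)  # ratio identity
  expect_equal(rr$carbon_proxy / rr$RWA, 0.508)

  # doubling every CWA at fixed CN doubles RWA and halves HCUE
  cells2 <- cells
  cells2$wall_area_um2 <- 2 * cells2$wall_area_um2
  rr2 <- aggregate_ring(derive_cell_traits(cells2))
  expect_equal(rr2$RWA, 2 * rr$RWA)
  expect_equal(rr2$HCUE, rr$HCUE / 2)
})

test_that("ring record is invariant to radial file permutation", {
  set.seed(3)
  cells <- do.call(rbind, lapply(1:4, function(f) {
    n <- sample(5:9, 1L)
    cells_with_areas(runif(n, 200, 900), cla = runif(n, 300, 1200),
                     file_id = f)
  }))
  cells$cell_index <- seq_len(nrow(cells))
  d <- derive_cell_traits(cells)
  perm <- d
  perm$radial_file_id <- c(3L, 1L, 4L, 2L)[perm$radial_file_id]
  expect_equal(aggregate_ring(perm), aggregate_ring(d))
})

test_that("ring table joins ring widths from a Tucson table", {
  sim <- simulate_site(sim_config(years = 2000:2002, n_trees = 2L,
                                  n_files = 2L, outbreaks = NULL),
                       seed = 5, level = "cell")
  rings <- ring_table(sim$cells, rwl = sim$rwl)
  expect_equal(nrow(rings), 6L)
  # joined RW matches the written rwl to its storage precision
  expect_equal(rings$RW[1L],
               sim$rwl[as.character(rings$year[1L]), rings$tree_id[1L]],
               tolerance = 1e-9)
})
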