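years_mat <- function(values, years, trees = "t1") {
  matrix(values, nrow = length(years), ncol = length(trees),
         dimnames = list(years, trees))
}

test_that("deviations are ratios to the fixed 5-year pre-event mean", {
  v <- rep(10, 20)
  v[11] <- 6                        # event start 1960, year 1
  m <- years_mat(v, 1950:1969)
  ev <- data.frame(start_year = 1960L)
  devs <- deviation_series(m, ev)
  expect_equal(devs$deviation[devs$rel_year == 1], 0.6)
  expect_equal(devs$deviation[devs$rel_year == -3], 1.0)
  # reference stays anchored on the pre-event window for later years
  expect_equal(devs$deviation[devs$rel_year == 5], 1.0)

  # series equal to the reference everywhere -> deviations all 1
  devs0 <- deviation_series(years_mat(rep(10, 20), 1950:1969), ev)
  expect_true(all(devs0$deviation == 1))
})

test_that("trees with incomplete reference windows are dropped", {
  m <- years_mat(c(rep(NA, 3), rep(10, 17)), 1950:1969,
                 trees = c("t1"))
  m <- cbind(m, t2 = rep(10, 20))
  ev <- data.frame(start_year = 1956L)
  expect_message(devs <- deviation_series(m, ev), "dropped 1")
  expect_equal(unique(devs$tree_id), "t2")
})

test_that("welch_test handles exact, extreme and degenerate cases", {
  a <- c(1, 2, 3, 4)
  same <- welch_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  far <- welch_test(a, a + 100)
  expect_lt(far$p, 0.001)
  expect_equal(far$stars, "***")

  degen <- welch_test(c(1, 1, 1), c(1, 2, 3))
  expect_false(degen$testable)
  expect_true(is.na(degen$p))
  expect_false(welch_test(1, c(1, 2, 3))$testable)
})

test_that("effect duration counts consecutive significant years from year 1", {
  expect_equal(effect_duration(c(0.01, 0.02, 0.2, 0.01, 0.3, 0.4, 0.5, 0.6)),
               2L)
  expect_equal(effect_duration(rep(0.2, 8)), 0L)
  expect_equal(effect_duration(rep(0.01, 8)), 8L)
  expect_equal(effect_duration(c(0.01, 0.2, 0.01, 0.01), mode = "total"), 3L)
})

test_that("epoch table pools by severity and summarises duration", {
  set.seed(31)
  n_yr <- 40
  m <- sapply(1:6, function(i) exp(rnorm(n_yr, 0, 0.03)))
  rownames(m) <- 1951:1990
  colnames(m) <- paste0("t", 1:6)
  # one strong event: years 1 and 2 reduced
  m["1970", ] <- m["1970", ] * 0.5
  m["1971", ] <- m["1971", ] * 0.6
  ev <- data.frame(start_year = 1970L, severity = "high")
  et <- epoch_table(deviation_series(m, ev))
  expect_equal(nrow(et), 8L)
  expect_lt(et$ratio[et$rel_year == 1], 0.6)
  expect_lt(et$p[et$rel_year == 1], 0.001)
  summ <- attr(et, "summary")
  expect_equal(summ$duration, 2L)
  expect_equal(summ$max_deviation, et$percent[et$rel_year == 1])
})

test_that("flat profiles are flat and tiny sets return raw points", {
  cells <- derive_cell_traits(cells_with_areas(runif(60, 400, 500),
                                               cla = rep(600, 60)))
  cells$relative_position_pct <- seq(0.5, 99.5, length.out = 60)
  cells$value_const <- 7.5
  prof <- intra_ring_profile(cells, "value_const")
  expect_equal(prof$fit, rep(7.5, 101), tolerance = 1e-9)

  small <- cells[1:5, ]
  prof_small <- intra_ring_profile(small, "CWT")
  expect_true(attr(prof_small, "raw_points"))
})

test_that("profiles recover a known linear gradient on the interior", {
  set.seed(12)
  n <- 400
  pos <- runif(n, 0, 100)
  truth <- 40 - 0.3 * pos          # 40 -> 10 um across the ring
  cells <- derive_cell_traits(
    cells_with_areas(runif(n, 400, 500), cla = rep(600, n)))
  cells$relative_position_pct <- pos
  cells$grad <- truth * exp(rnorm(n, 0, 0.03))
  prof <- intra_ring_profile(cells, "grad")
  interior <- prof$position_pct >= 10 & prof$position_pct <= 90
  rel_err <- abs(prof$fit[interior] - (40 - 0.3 * prof$position_pct[interior])) /
    (40 - 0.3 * prof$position_pct[interior])
  expect_lt(max(rel_err), 0.05)
})

test_that("relative positions accumulate radial extents within files", {
  cells <- derive_cell_traits(cells_with_areas(c(500, 400, 300),
                                               cla = c(700, 600, 500)))
  cells$relative_position_pct <- NULL
  cells$file_rank <- NULL
  out <- relative_positions(cells)
  ext <- cells$lumen_radial_diameter_um + 2 * cells$wall_thickness_radial_um
  expect_equal(out$relative_position_pct,
               (cumsum(ext) - ext / 2) / sum(ext) * 100)
})

test_that("superposed profiles difference out the reference", {
  cells <- derive_cell_traits(
    cells_with_areas(runif(80, 400, 500), cla = rep(600, 80)))
  cells$relative_position_pct <- seq(0.5, 99.5, length.out = 80)
  p1 <- intra_ring_profile(cells, "CWT")
  sp <- superpose_profiles(list(p1, p1), list(y1 = p1))
  expect_equal(sp$differences$y1$diff, rep(0, 101))
  expect_equal(sp$reference$fit, p1$fit)

  p_coarse <- intra_ring_profile(cells, "CWT", grid_step = 2)
  expect_error(superpose_profiles(list(p1), list(y1 = p_coarse)),
               "grids")
})

test_that("identical paired RW/RWA deviations give no gap", {
  d <- c(0.5, 0.6, 0.55, 0.65)
  res <- rw_vs_rwa_contrast(d, d)
  expect_equal(res$p, 1)
  expect_equal(res$rw_understatement_pct, 0)
  expect_false(rw_vs_rwa_contrast(d[1:2], d[1:2] * 0.9)$testable)
})
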