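test_that("zero-variance climate equals the seasonal means; seeds reproduce", {
  cfg <- sim_config(years = 1950:1959, t_anom_sd = 0, p_sdlog = 0)
  cl <- simulate_climate(cfg, seed = 1)
  expect_equal(cl$climate$temperature_mean_C,
               rep(cfg$t_monthly_mean, 10))
  expect_equal(cl$climate$precipitation_sum_mm,
               rep(rep(cfg$p_monthly_mean, 12), 10))

  cfg2 <- sim_config(years = 1950:1959)
  expect_identical(simulate_climate(cfg2, seed = 9),
                   simulate_climate(cfg2, seed = 9))
})

test_that("AR coefficient 0 leaves anomalies serially uncorrelated", {
  cfg <- sim_config(years = 1900:1989, t_ar1 = 0)
  cl <- simulate_climate(cfg, seed = 3)
  z <- as.vector(t(cl$t_anomaly))  # chronological monthly order, 1080 months
  ac <- cor(z[-1], z[-length(z)])
  expect_lt(abs(ac), 0.05)
})

test_that("noise-free tracheidograms lie exactly on the baseline profiles", {
  cfg <- sim_config(cell_noise_sd = 0, n_files = 2L)
  rc <- simulate_tracheidogram(20, cfg)
  p <- rc$relative_position_pct / 100
  expect_equal(rc$lumen_radial_diameter_um,
               cfg$cld_early - (cfg$cld_early - cfg$cld_late) *
                 plogis((p - cfg$lw_onset) / cfg$lw_width))
  expect_equal(nrow(rc), 40L)  # round(cn) cells per file, 2 files
  expect_error(simulate_tracheidogram(2, cfg), "cn_target")
})

test_that("wall-thinning pulses weight the latewood; the floor binds", {
  cfg <- sim_config(cell_noise_sd = 0, n_files = 1L)
  base <- simulate_tracheidogram(30, cfg)
  thin <- simulate_tracheidogram(30, cfg,
                                 multipliers = list(cwt = 0.7))
  cwt <- function(d) (d$wall_thickness_radial_um +
                        d$wall_thickness_tangential_um) / 2
  ratio <- cwt(thin) / cwt(base)
  p <- base$relative_position_pct
  expect_lt(mean(ratio[p >= 90]), mean(ratio[p <= 10]))

  floored <- simulate_tracheidogram(30, cfg, multipliers = list(cwt = 0.1))
  expect_true(all(cwt(floored) >= cfg$cwt_floor - 1e-12))
})

test_that("generated datasets pass schema validation; seeds give identical files", {
  cfg <- sim_config(years = 2000:2004, n_trees = 2L, n_files = 2L,
                    outbreaks = NULL)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_site(cfg, seed = 77, level = "cell", out_dir = d1)
  simulate_site(cfg, seed = 77, level = "cell", out_dir = d2)
  for (f in c("cells.csv", "S19.rwl", "climate.csv", "truth.yml")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  cells <- read_cell_table(file.path(d1, "cells.csv"))
  expect_equal(nrow(cells) > 0, TRUE)
  expect_silent(validate_cell_table(cells))
  expect_silent(validate_climate(read_climate(file.path(d1, "climate.csv"))))
  rwl <- read_rwl(file.path(d1, "S19.rwl"))
  expect_equal(ncol(rwl), 2L)
})

test_that("non-host series never receive outbreak multipliers", {
  cfg_nh <- sim_config(species = "nonhost")
  m <- qwanat:::.outbreak_multipliers(cfg_nh)
  expect_true(all(m == 1))
  expect_equal(nrow(qwanat:::.truth_record(cfg_nh)$events), 0L)

  cfg_h <- sim_config()
  mh <- qwanat:::.outbreak_multipliers(cfg_h)
  expect_equal(mh["1945", "cn"], 0.45)
  expect_equal(mh["1915", "cwt"], 0.85)
  # geometric recovery toward 1
  expect_true(all(diff(mh[as.character(1945:1950), "cn"]) > 0))
})

test_that("CN and RW chronologies are strongly coupled by construction", {
  sim <- simulate_ring_metrics(sim_config(), seed = 14)
  cn <- build_chronology(detrend_trees(param_matrix(sim$rings, "CN")))
  rw <- build_chronology(detrend_trees(param_matrix(sim$rings, "RW")))
  expect_gt(pearson_r(cn, rw)$r, 0.9)
})

test_that("with no outbreaks host and non-host are exchangeable", {
  set.seed(301)
  cfg0 <- sim_config(outbreaks = NULL)
  cfg_nh <- sim_config(species = "nonhost", cn_t_beta_nonhost = 0.06)
  ps <- replicate(40, {
    cl <- simulate_climate(cfg0)
    h <- simulate_ring_metrics(cfg0, climate_sim = cl)
    nh <- simulate_ring_metrics(cfg_nh, climate_sim = cl)
    t.test(h$rings$mean_CWT, nh$rings$mean_CWT)$p.value
  })
  # species label carries no signal: significance at roughly chance rate
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("detection scoring matches within tolerance, one-to-one", {
  sc <- score_detection(c(1908, 1946, 1990), c(1908, 1945, 1963), tol = 1)
  expect_equal(sc$tp, 2L)
  expect_equal(sc$fp, 1L)
  expect_equal(sc$fn, 1L)
  expect_equal(sc$recall, 2 / 3)
  expect_equal(sc$precision, 2 / 3)
})
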