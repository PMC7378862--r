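# Seeded synthetic generator for cell-level, ring-level and climate inputs,
# with ground-truth labels (event years, multipliers, climate couplings) so
# that detection, recovery and calibration can be scored against the truth.
#
# The generator emulates the structure of century-long larch/spruce tracheid
# datasets: a smooth earlywood-to-latewood anatomical gradient per ring,
# climate forcing of cell number (May-Aug temperature) and latewood wall
# thickness (late-summer temperature), and host-only outbreak pulses that
# reduce cell number strongly, wall thickness moderately (latewood most) and
# early-ring lumen diameter slightly, with geometric multi-year recovery.

`%||%` <- function(a, b) if (is.null(a)) b else a

.sim_defaults <- function() {
  list(
    site_id = "S19",
    species = "host",
    n_trees = 7L,
    years = 1900:2017,
    n_files = 5L,
    # ring baseline
    cn_mean = 50,
    cn_tree_sd = 0.08,    # lognormal sd of per-tree random effect
    cn_year_cv = 0.10,    # lognormal sd of per-year CN noise
    trend_range = c(1, 1),# optional log-linear ontogenetic trend (off)
    # earlywood -> latewood anatomical profile (um)
    cld_early = 42, cld_late = 8,
    cwt_early = 3.2, cwt_late = 8,
    lw_onset = 0.70, lw_width = 0.08,
    cwt_tan_ratio = 1.0,
    b_over_a = 1.05,      # tangential/radial lumen semi-axis ratio
    cwt_floor = 3,        # biomechanical minimum mean wall thickness (um)
    # noise
    cell_noise_sd = 0.10,   # lognormal sd per cell (CLD, CWT)
    metric_noise_sd = 0.03, # lognormal sd per ring-level metric
    # climate model (monthly means Jan-Dec; AR(1) temperature anomalies)
    t_monthly_mean = c(-2.5, -2, 1, 4.5, 9, 12.5, 15, 14.5, 11, 7, 1.5, -1.5),
    t_ar1 = 0.3, t_anom_sd = 1.3,
    p_monthly_mean = 77, p_sdlog = 0.45,
    # climate coupling (per degree C of the seasonal anomaly)
    cn_t_beta = 0.06,          # host CN ~ May-Aug temperature
    cn_t_beta_nonhost = 0,     # non-host CN insensitive to climate
    lwcwt_t_beta = 0.03,       # latewood CWT ~ Jul-Sep temperature (both)
    # outbreak schedule (host only); 4 high- and 4 low-severity events
    outbreaks = data.frame(
      start_year = c(1908L, 1915L, 1935L, 1945L, 1954L, 1963L, 1972L, 1981L),
      severity = c("high", "low", "low", "high", "low", "high", "high",
                   "low"),
      stringsAsFactors = FALSE),
    # first-year multipliers by severity
    mult = list(
      high = list(cn = 0.45, cwt = 0.70, cld_early = 0.93, cld_late = 1.05),
      low  = list(cn = 0.70, cwt = 0.85, cld_early = 0.97, cld_late = 1.02)),
    # geometric carry-over: fraction of the deficit remaining per year
    decay = list(cn = 0.55, cwt = 0.40, cld = 0.30),
    # latewood weighting of the CWT multiplier: local severity g(p) =
    # g0 + g1 * S(p), S the latewood share at relative position p
    cwt_weight_g0 = 0.8, cwt_weight_g1 = 0.7,
    profile_grid = 48L
  )
}

#' Simulation configuration
#'
#' Returns the full generator configuration, with any named defaults
#' overridden. See the package vignette for what each block emulates; the
#' defaults describe a 7-tree, 118-year larch-like site with eight scheduled
#' outbreaks (four high-, four low-severity).
#'
#' @param ... Named overrides of the default configuration.
#' @return A list of class `"qwa_config"`.
#' @export
sim_config <- function(...) {
  cfg <- utils::modifyList(.sim_defaults(), list(...))
  stopifnot(cfg$n_trees >= 1L, cfg$cn_mean >= 3,
            cfg$cld_early > 0, cfg$cld_late > 0,
            cfg$cwt_early > 0, cfg$cwt_late > 0)
  for (m in cfg$mult) {
    if (any(unlist(m) <= 0)) stop("outbreak multipliers must be positive")
  }
  if (!cfg$species %in% c("host", "nonhost")) {
    stop("species must be 'host' or 'nonhost'")
  }
  class(cfg) <- c("qwa_config", "list")
  cfg
}

# latewood share at relative position p in [0,1]
.lw_share <- function(p, cfg) stats::plogis((p - cfg$lw_onset) / cfg$lw_width)

.profile_cld <- function(p, cfg) {
  cfg$cld_early - (cfg$cld_early - cfg$cld_late) * .lw_share(p, cfg)
}

.profile_cwt <- function(p, cfg) {
  cfg$cwt_early + (cfg$cwt_late - cfg$cwt_early) * .lw_share(p, cfg)
}

# Ramanujan approximation of the ellipse perimeter
.ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Simulate a monthly climate record
#'
#' Monthly temperature = seasonal mean + AR(1) anomaly; monthly precipitation
#' is lognormal around the seasonal mean. The true anomaly series is
#' returned so coupling-recovery tests can score against it.
#'
#' @param config Configuration from [sim_config()].
#' @param seed Optional integer seed.
#' @return List with `climate` (a validated monthly table) and `t_anomaly`
#'   (year-by-month anomaly matrix).
#' @export
simulate_climate <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  yrs <- config$years
  n <- length(yrs) * 12L
  phi <- config$t_ar1
  innov_sd <- config$t_anom_sd * sqrt(1 - phi^2)
  z <- numeric(n)
  e <- stats::rnorm(n, 0, innov_sd)
  z[1L] <- stats::rnorm(1L, 0, config$t_anom_sd)
  for (i in 2:n) z[i] <- phi * z[i - 1L] + e[i]
  anom <- matrix(z, ncol = 12L, byrow = TRUE,
                 dimnames = list(yrs, month.abb))
  pm <- rep(config$p_monthly_mean, length.out = 12L)
  clim <- data.frame(
    year = rep(yrs, each = 12L),
    month = rep(1:12, times = length(yrs)),
    temperature_mean_C = rep(config$t_monthly_mean, times = length(yrs)) + z,
    precipitation_sum_mm = rep(pm, times = length(yrs)) *
      exp(stats::rnorm(n, 0, config$p_sdlog) - config$p_sdlog^2 / 2))
  list(climate = validate_climate(clim), t_anomaly = anom)
}

# per-year outbreak multipliers (host only): matrix years x
# {cn, cwt, cld_early, cld_late}
.outbreak_multipliers <- function(config) {
  yrs <- config$years
  out <- matrix(1, nrow = length(yrs), ncol = 4L,
                dimnames = list(yrs, c("cn", "cwt", "cld_early", "cld_late")))
  if (config$species != "host" || is.null(config$outbreaks) ||
      nrow(config$outbreaks) == 0L) {
    return(out)
  }
  for (e in seq_len(nrow(config$outbreaks))) {
    s <- config$outbreaks$start_year[e]
    m1 <- config$mult[[config$outbreaks$severity[e]]]
    dec <- c(cn = config$decay$cn, cwt = config$decay$cwt,
             cld_early = config$decay$cld, cld_late = config$decay$cld)
    for (par in colnames(out)) {
      deficit <- 1 - m1[[par]]
      k <- 1L
      while (abs(deficit) > 1e-3 && (s + k - 1L) <= max(yrs)) {
        i <- match(s + k - 1L, yrs)
        if (!is.na(i)) out[i, par] <- out[i, par] * (1 - deficit)
        deficit <- deficit * dec[[par]]
        k <- k + 1L
      }
    }
  }
  out
}

# local (position-dependent) outbreak multipliers for one year
.local_mults <- function(p, cfg, m_cwt, m_cld_early, m_cld_late) {
  g <- cfg$cwt_weight_g0 + cfg$cwt_weight_g1 * .lw_share(p, cfg)
  list(cwt = 1 - (1 - m_cwt) * g,
       cld = m_cld_early + (m_cld_late - m_cld_early) * p)
}

# deterministic per-position anatomy for one year; returns profile arrays
.year_profile <- function(cfg, p, m_cwt, m_cld_early, m_cld_late,
                          lw_climate_mult) {
  lm <- .local_mults(p, cfg, m_cwt, m_cld_early, m_cld_late)
  cld <- .profile_cld(p, cfg) * lm$cld
  cwt <- .profile_cwt(p, cfg) *
    (1 + (lw_climate_mult - 1) * .lw_share(p, cfg)) * lm$cwt
  cwt <- pmax(cwt, cfg$cwt_floor)
  a <- cld / 2
  b <- a * cfg$b_over_a
  cla <- pi * a * b
  cwa <- cwt * .ellipse_perimeter(a, b)
  list(p = p, cld = cld, cwt = cwt, cla = cla, cwa = cwa,
       khc = khc_elliptical(a, b), extent = cld + 2 * cwt)
}

#' Simulate ring-level trait series for one site
#'
#' Fast path of the generator: per tree x year ring metrics are computed by
#' integrating the anatomical profile over a fixed relative-position grid
#' (rather than drawing individual cells), then perturbed with lognormal
#' ring-level noise. This preserves the trait structure (CN, mean CWT/CLD,
#' RWA, Kh_r, HCUE, RW and their outbreak/climate responses) at a fraction of
#' the cost of cell-level simulation, and is what the calibration and
#' recovery experiments run on.
#'
#' @param config Configuration from [sim_config()].
#' @param climate_sim Output of [simulate_climate()]; simulated if `NULL`.
#' @param seed Optional integer seed.
#' @return List with `rings` (per tree x year `data.frame`), `climate`,
#'   `t_anomaly`, and `truth` (events, multipliers, couplings).
#' @export
simulate_ring_metrics <- function(config = sim_config(), climate_sim = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  if (is.null(climate_sim)) climate_sim <- simulate_climate(cfg)
  anom <- climate_sim$t_anomaly
  yrs <- cfg$years
  mayaug <- rowMeans(anom[, 5:8, drop = FALSE])
  late <- rowMeans(anom[, 7:9, drop = FALSE])
  cn_beta <- if (cfg$species == "host") cfg$cn_t_beta else cfg$cn_t_beta_nonhost
  mults <- .outbreak_multipliers(cfg)
  treeff <- exp(stats::rnorm(cfg$n_trees, 0, cfg$cn_tree_sd))
  trend <- exp(seq(log(cfg$trend_range[1L]), log(cfg$trend_range[2L]),
                   length.out = length(yrs)))
  K <- cfg$profile_grid
  p <- (seq_len(K) - 0.5) / K
  lw <- .lw_share(p, cfg) >= 0.5
  rows <- vector("list", length(yrs))
  for (i in seq_along(yrs)) {
    pr <- .year_profile(cfg, p, mults[i, "cwt"], mults[i, "cld_early"],
                        mults[i, "cld_late"],
                        lw_climate_mult = exp(cfg$lwcwt_t_beta * late[i]))
    cn <- cfg$cn_mean * treeff * trend[i] * mults[i, "cn"] *
      exp(cn_beta * mayaug[i]) *
      exp(stats::rnorm(cfg$n_trees, 0, cfg$cn_year_cv))
    nz <- function() exp(stats::rnorm(cfg$n_trees, 0, cfg$metric_noise_sd))
    m_cwa <- mean(pr$cwa) * nz()
    m_khc <- mean(pr$khc) * nz()
    m_ext <- mean(pr$extent) * nz()
    rwa <- cn * m_cwa
    khr <- cn * m_khc
    rows[[i]] <- data.frame(
      tree_id = sprintf("%s_t%02d", cfg$site_id, seq_len(cfg$n_trees)),
      year = yrs[i],
      CN = cn,
      RW = cn * m_ext / 1000,
      mean_CLD = mean(pr$cld) * nz(),
      mean_CWT = mean(pr$cwt) * nz(),
      mean_CLA = mean(pr$cla) * nz(),
      mean_CWA = m_cwa,
      mean_Khc = m_khc,
      RWA = rwa,
      Kh_r = khr,
      HCUE = khr / rwa,
      ew_CWT = mean(pr$cwt[!lw]) * nz(),
      lw_CWT = mean(pr$cwt[lw]) * nz(),
      stringsAsFactors = FALSE)
  }
  rings <- do.call(rbind, rows)
  rings <- rings[order(rings$tree_id, rings$year), , drop = FALSE]
  rownames(rings) <- NULL
  list(rings = rings, climate = climate_sim$climate,
       t_anomaly = climate_sim$t_anomaly,
       truth = .truth_record(cfg, seed))
}

.truth_record <- function(cfg, seed = NULL) {
  ob <- cfg$outbreaks
  if (cfg$species == "host" && !is.null(ob) && nrow(ob) > 0L) {
    for (par in c("cn", "cwt", "cld_early", "cld_late")) {
      ob[[paste0("mult_", par)]] <-
        vapply(ob$severity, function(s) cfg$mult[[s]][[par]], numeric(1L))
    }
  } else {
    ob <- ob[0L, , drop = FALSE]
  }
  list(site_id = cfg$site_id, species = cfg$species, events = ob,
       couplings = list(
         cn_t_beta = if (cfg$species == "host") cfg$cn_t_beta else
           cfg$cn_t_beta_nonhost,
         lwcwt_t_beta = cfg$lwcwt_t_beta),
       decay = cfg$decay, seed = seed)
}

#' Simulate the tracheids of one ring
#'
#' Draws an integer cell count per radial file around the (outbreak-adjusted)
#' CN target, places each cell at its relative position, evaluates the
#' baseline earlywood-to-latewood profiles there, applies the outbreak
#' multipliers (lumen-diameter multiplier interpolated from early to late
#' ring; wall-thickness multiplier weighted toward the latewood), the
#' latewood climate multiplier, and the biomechanical wall-thickness floor,
#' adds lognormal per-cell noise, and derives the measured quantities: lumen
#' area from the ellipse relation `CLA = pi a b`, wall area from mean wall
#' thickness times the lumen perimeter (Ramanujan approximation).
#'
#' @param cn_target Baseline mean cells per radial file (before the outbreak
#'   multiplier); must be >= 3.
#' @param config Configuration from [sim_config()].
#' @param multipliers List with `cn`, `cwt`, `cld_early`, `cld_late`
#'   multipliers for this year (already decayed); default all 1.
#' @param lw_climate_mult Latewood wall-thickness climate multiplier.
#' @param tree_id,year Identifiers stamped on the cells.
#' @param seed Optional integer seed.
#' @return Cell `data.frame` in the input schema (with `radial_file_id`,
#'   `relative_position_pct`, and `x_um`/`y_um` centroid coordinates).
#' @export
simulate_tracheidogram <- function(cn_target, config = sim_config(),
                                   multipliers = NULL, lw_climate_mult = 1,
                                   tree_id = "T01", year = 2000L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  if (cn_target < 3) stop("config error: cn_target must be >= 3")
  m <- utils::modifyList(list(cn = 1, cwt = 1, cld_early = 1, cld_late = 1),
                         multipliers %||% list())
  cn_eff <- max(3, cn_target * m$cn)
  noise <- cfg$cell_noise_sd
  spacing <- cfg$b_over_a * (cfg$cld_early + cfg$cld_late) / 2 + 2 * 5
  out <- vector("list", cfg$n_files)
  idx0 <- 0L
  for (f in seq_len(cfg$n_files)) {
    n_f <- if (noise == 0) max(3L, as.integer(round(cn_eff))) else
      max(3L, stats::rpois(1L, cn_eff))
    p <- (seq_len(n_f) - 0.5) / n_f
    lm <- .local_mults(p, cfg, m$cwt, m$cld_early, m$cld_late)
    cld <- .profile_cld(p, cfg) * lm$cld * exp(stats::rnorm(n_f, 0, noise))
    cwt <- .profile_cwt(p, cfg) *
      (1 + (lw_climate_mult - 1) * .lw_share(p, cfg)) * lm$cwt *
      exp(stats::rnorm(n_f, 0, noise))
    cwt <- pmax(cwt, cfg$cwt_floor)
    cwt_rad <- cwt * 2 / (1 + cfg$cwt_tan_ratio)
    cwt_tan <- cwt_rad * cfg$cwt_tan_ratio
    a <- cld / 2
    b <- a * cfg$b_over_a * exp(stats::rnorm(n_f, 0, noise / 2))
    cla <- pi * a * b
    cwa <- cwt * .ellipse_perimeter(a, b)
    extent <- cld + 2 * cwt_rad
    out[[f]] <- data.frame(
      tree_id = tree_id, year = as.integer(year),
      cell_index = idx0 + seq_len(n_f),
      radial_file_id = f,
      relative_position_pct = p * 100,
      x_um = (f - 1L) * spacing +
        if (noise == 0) 0 else stats::rnorm(n_f, 0, spacing / 15),
      y_um = cumsum(extent) - extent / 2,
      lumen_radial_diameter_um = cld,
      lumen_area_um2 = cla,
      wall_thickness_radial_um = cwt_rad,
      wall_thickness_tangential_um = cwt_tan,
      wall_area_um2 = cwa,
      stringsAsFactors = FALSE)
    idx0 <- idx0 + n_f
  }
  do.call(rbind, out)
}

#' Simulate a full site dataset
#'
#' Generates either ring-level trait series (`level = "ring"`, the fast path;
#' see [simulate_ring_metrics()]) or a full cell table (`level = "cell"`,
#' one [simulate_tracheidogram()] ring per tree x year) together with a
#' Tucson ring-width table, the monthly climate record, and the ground-truth
#' record. Ring width is the summed radial cell extent of the average radial
#' file (so RW and CN are strongly coupled by construction). With `out_dir`
#' set, everything is written as delimited text / `.rwl` / YAML.
#'
#' @param config Configuration from [sim_config()].
#' @param seed Optional integer seed; a fixed seed gives byte-identical
#'   outputs.
#' @param level `"ring"` or `"cell"`.
#' @param climate_sim Optional pre-simulated climate (so host and non-host
#'   share one climate realization).
#' @param out_dir Optional output directory.
#' @return List with `rings` (ring level) or `cells` (cell level), `rwl`,
#'   `climate`, `t_anomaly`, `truth`, `config`.
#' @export
simulate_site <- function(config = sim_config(), seed = NULL,
                          level = c("ring", "cell"), climate_sim = NULL,
                          out_dir = NULL) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  if (is.null(climate_sim)) climate_sim <- simulate_climate(cfg)
  res <- list(climate = climate_sim$climate,
              t_anomaly = climate_sim$t_anomaly,
              truth = .truth_record(cfg, seed), config = cfg)
  if (level == "ring") {
    rm <- simulate_ring_metrics(cfg, climate_sim = climate_sim)
    res$rings <- rm$rings
    res$rwl <- .rings_to_rwl(rm$rings)
  } else {
    anom <- climate_sim$t_anomaly
    late <- rowMeans(anom[, 7:9, drop = FALSE])
    mayaug <- rowMeans(anom[, 5:8, drop = FALSE])
    cn_beta <- if (cfg$species == "host") cfg$cn_t_beta else
      cfg$cn_t_beta_nonhost
    mults <- .outbreak_multipliers(cfg)
    treeff <- exp(stats::rnorm(cfg$n_trees, 0, cfg$cn_tree_sd))
    trend <- exp(seq(log(cfg$trend_range[1L]), log(cfg$trend_range[2L]),
                     length.out = length(cfg$years)))
    cells <- list()
    rw_rows <- list()
    for (t in seq_len(cfg$n_trees)) {
      tid <- sprintf("%s_t%02d", cfg$site_id, t)
      for (i in seq_along(cfg$years)) {
        yr <- cfg$years[i]
        cn_t <- cfg$cn_mean * treeff[t] * trend[i] *
          exp(cn_beta * mayaug[i]) *
          exp(stats::rnorm(1L, 0, cfg$cn_year_cv))
        rc <- simulate_tracheidogram(
          cn_t, cfg,
          multipliers = list(cn = mults[i, "cn"], cwt = mults[i, "cwt"],
                             cld_early = mults[i, "cld_early"],
                             cld_late = mults[i, "cld_late"]),
          lw_climate_mult = exp(cfg$lwcwt_t_beta * late[i]),
          tree_id = tid, year = yr)
        cells[[length(cells) + 1L]] <- rc
        ext <- rc$lumen_radial_diameter_um + 2 * rc$wall_thickness_radial_um
        rw_rows[[length(rw_rows) + 1L]] <- data.frame(
          tree_id = tid, year = yr,
          RW = mean(tapply(ext, rc$radial_file_id, sum)) / 1000)
      }
    }
    res$cells <- do.call(rbind, cells)
    rownames(res$cells) <- NULL
    res$rwl <- .rings_to_rwl(do.call(rbind, rw_rows))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$cells)) {
      write_cell_table(res$cells, file.path(out_dir, "cells.csv"))
    }
    if (!is.null(res$rings)) {
      utils::write.csv(res$rings, file.path(out_dir, "rings.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    write_rwl(res$rwl, file.path(out_dir, paste0(cfg$site_id, ".rwl")),
              prec = 0.001)
    write_climate(res$climate, file.path(out_dir, "climate.csv"))
    truth <- res$truth
    truth$events <- as.list(as.data.frame(truth$events))
    yaml::write_yaml(truth, file.path(out_dir, "truth.yml"))
  }
  res
}

.rings_to_rwl <- function(rings) {
  as.data.frame(param_matrix(rings, "RW"), check.names = FALSE)
}

#' Score detected outbreaks against the generator truth
#'
#' Greedy one-to-one matching of detected start years to true event years
#' within `tol` years.
#'
#' @param detected Events `data.frame` from [detect_outbreaks()] or an
#'   integer vector of detected start years.
#' @param true_years Integer vector of true event start years.
#' @param tol Matching tolerance in years (default 1).
#' @return List with `tp`, `fp`, `fn`, `recall`, `precision`.
#' @export
score_detection <- function(detected, true_years, tol = 1L) {
  det <- if (is.data.frame(detected)) detected$start_year else
    as.integer(detected)
  unmatched <- true_years
  tp <- 0L
  for (d in det) {
    hit <- which(abs(unmatched - d) <= tol)
    if (length(hit) > 0L) {
      tp <- tp + 1L
      unmatched <- unmatched[-hit[1L]]
    }
  }
  fp <- length(det) - tp
  fn <- length(unmatched)
  list(tp = tp, fp = fp, fn = fn,
       recall = if (length(true_years) > 0L) tp / length(true_years) else
         NA_real_,
       precision = if (length(det) > 0L) tp / length(det) else NA_real_)
}
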