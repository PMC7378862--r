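# Fixtures built in code: small cell tables and simulated site pairs.

# minimal valid cell table (3 cells, one ring)
toy_cells <- function() {
  data.frame(
    tree_id = "T1", year = 2000L, cell_index = 1:3,
    radial_file_id = 1L,
    lumen_radial_diameter_um = c(40, 30, 12),
    lumen_area_um2 = c(1300, 740, 115),
    wall_thickness_radial_um = c(3, 4, 6),
    wall_thickness_tangential_um = c(3, 4, 6),
    wall_area_um2 = c(850, 820, 640),
    stringsAsFactors = FALSE
  )
}

# one-ring cell table with chosen wall/lumen areas (other dims plausible)
cells_with_areas <- function(cwa, cla, file_id = 1L) {
  n <- length(cwa)
  data.frame(
    tree_id = "T1", year = 2000L, cell_index = seq_len(n),
    radial_file_id = file_id,
    lumen_radial_diameter_um = 2 * sqrt(cla / pi),
    lumen_area_um2 = cla,
    wall_thickness_radial_um = rep(4, n),
    wall_thickness_tangential_um = rep(4, n),
    wall_area_um2 = cwa,
    stringsAsFactors = FALSE
  )
}

# host + non-host ring-level simulation sharing one climate realization
sim_pair <- function(seed, cfg = sim_config(),
                     cfg_nh = sim_config(species = "nonhost")) {
  set.seed(seed)
  cl <- simulate_climate(cfg)
  host <- simulate_ring_metrics(cfg, climate_sim = cl)
  nonhost <- simulate_ring_metrics(cfg_nh, climate_sim = cl)
  list(host = host, nonhost = nonhost, climate = cl)
}

# CWT chronology from a ring-level simulation
cwt_chronology <- function(sim) {
  build_chronology(detrend_trees(param_matrix(sim$rings, "mean_CWT")))
}
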