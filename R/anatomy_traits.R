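# Per-cell derived traits and per-ring aggregates.
#
# Symbols follow quantitative-wood-anatomy usage: CLD radial lumen diameter,
# CWT mean wall thickness, CLA lumen area, CWA wall area, CTA total cell area
# (CLA + CWA), CWD relative anatomical density CWA/CTA, Kh_c theoretical cell
# hydraulic conductivity, CN mean cells per radial file, RWA ring wall area
# (biomass proxy), Kh_r ring conductivity, HCUE hydraulic carbon use
# efficiency Kh_r/RWA.

#' Theoretical hydraulic conductivity of an elliptical conduit
#'
#' Poiseuille flow adjusted to elliptical tubes:
#' \deqn{K_h = \frac{\pi a^3 b^3}{4 \eta (a^2 + b^2)}}
#' with semi-axes \eqn{a, b} in \eqn{\mu m} and dynamic viscosity \eqn{\eta}
#' in MPa s, giving \eqn{\mu m^4 MPa^{-1} s^{-1}}. For a circular
#' conduit (\eqn{a = b = r}) this reduces to the classical Hagen-Poiseuille
#' \eqn{\pi r^4 / (8 \eta)}.
#'
#' @param a Radial lumen semi-axis, um.
#' @param b Tangential lumen semi-axis, um.
#' @param viscosity Dynamic viscosity of water in MPa s
#'   (default 1.002e-9, water at 20 C).
#' @return Conductivity in um^4 MPa^-1 s^-1.
#' @export
khc_elliptical <- function(a, b, viscosity = 1.002e-9) {
  pi * a^3 * b^3 / (4 * viscosity * (a^2 + b^2))
}

#' Derive per-cell anatomical and functional traits
#'
#' Adds to a validated cell table: `CWT` (mean of radial and tangential wall
#' thickness), `CTA = CLA + CWA`, `CWD = CWA/CTA`, the lumen semi-axes
#' (`a = CLD/2` radial; `b = CLA/(pi a)` tangential, inferred from the
#' ellipse-area relation `CLA = pi a b`), the elliptical-Poiseuille
#' conductivity `Kh_c`, and the Mork latewood flag `is_latewood`.
#'
#' Cells whose inferred eccentricity `b/a` falls outside `ecc_band` are
#' flagged and excluded (with a message), not a hard failure; the dropped rows
#' are attached as attribute `"flagged"`.
#'
#' @param cells Cell table with the required measurement columns (see
#'   [read_cell_table()]).
#' @param viscosity Dynamic viscosity of water, MPa s.
#' @param ecc_band Plausibility band for `b/a`.
#' @return The cell table with columns `CLD`, `CWT_rad`, `CWT_tan`, `CWT`,
#'   `CLA`, `CWA`, `CTA`, `CWD`, `lumen_a_um`, `lumen_b_um`, `Kh_c`,
#'   `is_latewood` added.
#' @export
derive_cell_traits <- function(cells, viscosity = 1.002e-9,
                               ecc_band = c(0.05, 20)) {
  validate_cell_table(cells)
  cells$CLD <- cells$lumen_radial_diameter_um
  cells$CWT_rad <- cells$wall_thickness_radial_um
  cells$CWT_tan <- cells$wall_thickness_tangential_um
  cells$CLA <- cells$lumen_area_um2
  cells$CWA <- cells$wall_area_um2
  cells$CWT <- (cells$CWT_rad + cells$CWT_tan) / 2
  cells$CTA <- cells$CLA + cells$CWA
  cells$CWD <- cells$CWA / cells$CTA
  a <- cells$CLD / 2
  b <- cells$CLA / (pi * a)
  cells$lumen_a_um <- a
  cells$lumen_b_um <- b
  bad <- !is.finite(b) | b <= 0 | b / a < ecc_band[1L] | b / a > ecc_band[2L]
  cells$Kh_c <- khc_elliptical(a, b, viscosity)
  cells$is_latewood <- classify_mork(cells$CWT_rad, cells$CLD)
  flagged <- cells[bad, , drop = FALSE]
  if (nrow(flagged) > 0L) {
    message("derive_cell_traits: excluded ", nrow(flagged),
            " cell(s) with implausible lumen eccentricity")
    cells <- cells[!bad, , drop = FALSE]
  }
  attr(cells, "flagged") <- flagged
  cells
}

#' Mork earlywood/latewood classification
#'
#' Mork index `MI = 4 * CWT_rad / CLD`; a cell is latewood when `MI >= 1`
#' (boundary inclusive).
#'
#' @param cwt_rad Radial wall thickness, um.
#' @param cld Radial lumen diameter, um.
#' @return Logical vector, `TRUE` for latewood.
#' @export
classify_mork <- function(cwt_rad, cld) {
  4 * cwt_rad / cld >= 1
}

#' Assign tracheids of one ring to radial files
#'
#' If `radial_file_id` is already present the cells pass through unchanged
#' (except that within-file rank is recomputed). Otherwise cells are grouped
#' by their tangential centroid coordinate `x_um` with one-dimensional gap
#' clustering: cells are sorted by `x_um` and a new file starts wherever the
#' tangential gap exceeds `gap`. By default `gap` is half the median
#' tangential cell width (lumen plus walls), so a single tight column of
#' cells yields one file while neighbouring files, about one cell width
#' apart, are separated. This is a simplified stand-in for full tracheid-row
#' tracking and assumes approximately straight files.
#'
#' @param cells Cells of one ring (one `tree_id`/`year`).
#' @param gap Tangential distance (um) above which two cells belong to
#'   different files; `NULL` to estimate.
#' @return Cells with `radial_file_id` and `file_rank` (radial order within
#'   file, by `y_um` when available, else by `cell_index`).
#' @export
assign_radial_files <- function(cells, gap = NULL) {
  if (nrow(cells) == 0L) stop("empty ring: no cells to assign")
  if (is.null(cells$radial_file_id) || all(is.na(cells$radial_file_id))) {
    if (is.null(cells$x_um)) {
      stop("configuration error: neither radial_file_id nor x_um/y_um ",
           "coordinates present")
    }
    o <- order(cells$x_um)
    x <- cells$x_um[o]
    d <- diff(x)
    if (is.null(gap)) {
      # half the median tangential cell width: within a file, centroids
      # scatter by less than half a cell; neighbouring files sit about one
      # cell width apart
      b <- cells$lumen_area_um2 / (pi * cells$lumen_radial_diameter_um / 2)
      w <- 2 * b + 2 * cells$wall_thickness_tangential_um
      gap <- stats::median(w) / 2
    }
    fid <- cumsum(c(1, as.numeric(d > gap)))
    cells$radial_file_id[o] <- fid
  }
  ord_key <- if (!is.null(cells$y_um)) cells$y_um else cells$cell_index
  cells$file_rank <- stats::ave(ord_key, cells$radial_file_id,
                                FUN = function(v) rank(v, ties.method = "first"))
  cells
}

# trait columns carried through average-file construction
.avg_file_traits <- c("CLD", "CWT", "CWT_rad", "CLA", "CWA", "CTA", "CWD",
                      "Kh_c")

#' Construct the average radial file of one ring
#'
#' Each radial file's trait sequence is placed on a relative rank axis
#' (cell `i` of an `n`-cell file at position `(i - 0.5)/n`), linearly
#' interpolated onto a common grid of length `L` (the longest file), and
#' averaged across files position by position. `CN` is the mean number of
#' cells per file (real-valued). Totals over the average file are rescaled by
#' `CN/L` by the downstream aggregation so that ring wall area equals
#' `CN x mean(CWA)` exactly.
#'
#' @param cells Cells of one ring carrying derived traits
#'   (see [derive_cell_traits()]) and `radial_file_id`; cells without file ids
#'   are treated as a single file ordered by `cell_index`.
#' @return A list with `CN` (mean cells per file), `L` (grid length),
#'   `position` (relative rank grid in (0,1)), and `traits` (a `data.frame`
#'   of per-position mean trait values, plus `extent_um`, the radial cell
#'   extent `CLD + 2 CWT_rad`).
#' @export
average_radial_file <- function(cells) {
  if (nrow(cells) == 0L) stop("empty ring: cannot build average radial file")
  if (is.null(cells$radial_file_id) || all(is.na(cells$radial_file_id))) {
    cells$radial_file_id <- 1L
  }
  if (is.null(cells$file_rank)) {
    cells <- assign_radial_files(cells)
  }
  cells$extent_um <- cells$CLD + 2 * cells$CWT_rad
  traits <- intersect(c(.avg_file_traits, "extent_um"), names(cells))
  files <- split(cells, cells$radial_file_id)
  lens <- vapply(files, nrow, integer(1L))
  L <- max(lens)
  CN <- mean(lens)
  q <- (seq_len(L) - 0.5) / L
  acc <- matrix(0, nrow = L, ncol = length(traits),
                dimnames = list(NULL, traits))
  for (f in files) {
    f <- f[order(f$file_rank), , drop = FALSE]
    n <- nrow(f)
    p <- (seq_len(n) - 0.5) / n
    for (tr in traits) {
      acc[, tr] <- acc[, tr] + if (n == 1L) {
        rep(f[[tr]], L)
      } else {
        stats::approx(p, f[[tr]], xout = q, rule = 2)$y
      }
    }
  }
  list(CN = CN, L = L, position = q,
       traits = as.data.frame(acc / length(files)))
}

#' Aggregate one ring into ring-level traits
#'
#' Ring-level functional traits from the average radial file:
#' `RWA = CN x mean(CWA)` (equivalently the sum of average-file wall areas
#' rescaled by `CN/L`), a proxy for tree-ring biomass;
#' `Kh_r = CN x mean(Kh_c)` with the same rescaling; `HCUE = Kh_r / RWA`;
#' `carbon_proxy = carbon_fraction x RWA` (structural carbon, conifer cell
#' walls being 50.8 percent carbon). Ring means of the cell traits and
#' Mork-split earlywood/latewood mean wall thickness are included.
#'
#' @param cells Cells of one ring with derived traits.
#' @param rw Ring width in mm from ring-width measurements; if `NA` it is
#'   derived from the average file as `CN x mean(CLD + 2 CWT_rad)` (um to mm).
#' @param carbon_fraction Carbon fraction of the cell wall (default 0.508).
#' @return One-row `data.frame` (a ring record).
#' @export
aggregate_ring <- function(cells, rw = NA_real_, carbon_fraction = 0.508) {
  if (nrow(cells) == 0L) stop("empty ring: no cells to aggregate")
  avg <- average_radial_file(cells)
  RWA <- avg$CN * mean(avg$traits$CWA)
  Kh_r <- avg$CN * mean(avg$traits$Kh_c)
  if (is.na(rw)) {
    rw <- avg$CN * mean(avg$traits$extent_um) / 1000
  }
  lw <- cells$is_latewood
  data.frame(
    tree_id = cells$tree_id[1L],
    year = cells$year[1L],
    RW = rw,
    CN = avg$CN,
    mean_CLD = mean(cells$CLD),
    mean_CWT = mean(cells$CWT),
    mean_CLA = mean(cells$CLA),
    mean_CWA = mean(cells$CWA),
    mean_CTA = mean(cells$CTA),
    mean_CWD = mean(cells$CWD),
    mean_Khc = mean(cells$Kh_c),
    RWA = RWA,
    Kh_r = Kh_r,
    HCUE = Kh_r / RWA,
    carbon_proxy = carbon_fraction * RWA,
    ew_CWT = if (any(!lw)) mean(cells$CWT[!lw]) else NA_real_,
    lw_CWT = if (any(lw)) mean(cells$CWT[lw]) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Build the ring-level trait table for a whole cell dataset
#'
#' Splits the cell table by `(tree_id, year)`, derives cell traits if they are
#' not yet present, and aggregates each ring. Ring widths are joined from a
#' Tucson ring-width table when supplied (series names matched to `tree_id`);
#' rings without a match fall back to the anatomy-derived width.
#'
#' @param cells Cell table (raw or with derived traits).
#' @param rwl Optional ring-width `data.frame` from [read_rwl()], mm.
#' @param viscosity Dynamic viscosity passed to [derive_cell_traits()].
#' @return `data.frame` with one row per `(tree_id, year)`.
#' @export
ring_table <- function(cells, rwl = NULL, viscosity = 1.002e-9) {
  if (is.null(cells$Kh_c)) {
    cells <- derive_cell_traits(cells, viscosity = viscosity)
  }
  rings <- split(cells, list(cells$tree_id, cells$year), drop = TRUE)
  out <- do.call(rbind, lapply(rings, function(rc) {
    rw <- NA_real_
    if (!is.null(rwl)) {
      tid <- as.character(rc$tree_id[1L])
      yr <- as.character(rc$year[1L])
      if (tid %in% names(rwl) && yr %in% rownames(rwl)) {
        rw <- rwl[yr, tid]
      }
    }
    aggregate_ring(rc, rw = rw)
  }))
  out <- out[order(out$tree_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}
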