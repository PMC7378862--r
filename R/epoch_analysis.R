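# Superposed-epoch quantification of outbreak impacts: deviation ratios from
# a fixed 5-year pre-event reference, Welch tests, effect durations,
# intra-ring loess profiles, and the ring-width vs ring-wall-area contrast.

#' Per-tree deviation ratios around outbreak events
#'
#' For every tree x event pair, the reference is the mean of the
#' `ref_window` years preceding the event start (fixed for all relative
#' years). The deviation at relative year `k` (k = 1 is the start year) is
#' `value(start + k - 1) / reference`. Pre-event years are returned as
#' relative years `-ref_window ... -1` so group tests can compare event years
#' against the reference period. Trees missing any reference year, or a
#' given event year, are dropped for that event with a message.
#'
#' @param values Year-by-tree matrix of raw annual values (year row names),
#'   e.g. from [param_matrix()].
#' @param events Events `data.frame` with `start_year` and optionally
#'   `severity` (see [detect_outbreaks()], [classify_severity()]).
#' @param horizon Number of event years to follow (default 8: the start year
#'   plus the successive seven).
#' @param ref_window Reference window length (default 5).
#' @return Long `data.frame`: `tree_id`, `start_year`, `severity`,
#'   `rel_year`, `value`, `ref`, `deviation`.
#' @export
deviation_series <- function(values, events, horizon = 8L, ref_window = 5L) {
  if (nrow(events) == 0L) {
    warning("deviation_series: no events")
    return(data.frame(tree_id = character(0), start_year = integer(0),
                      severity = character(0), rel_year = integer(0),
                      value = numeric(0), ref = numeric(0),
                      deviation = numeric(0)))
  }
  sev <- if (!is.null(events$severity)) events$severity else
    rep("all", nrow(events))
  sev[is.na(sev)] <- "all"
  yrs <- as.integer(rownames(values))
  trees <- colnames(values)
  rel <- c(seq(-ref_window, -1L), seq_len(horizon))
  rows <- list()
  dropped <- 0L
  for (e in seq_len(nrow(events))) {
    s <- events$start_year[e]
    ref_idx <- match(seq(s - ref_window, s - 1L), yrs)
    for (tr in trees) {
      refv <- values[ref_idx, tr]
      if (anyNA(ref_idx) || anyNA(refv)) {
        dropped <- dropped + 1L
        next
      }
      ref <- mean(refv)
      cal <- s + ifelse(rel < 0L, rel, rel - 1L)
      v <- values[match(cal, yrs), tr]
      keep <- !is.na(v)
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = tr, start_year = s, severity = sev[e],
        rel_year = rel[keep], value = v[keep], ref = ref,
        deviation = v[keep] / ref, stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0L) {
    message("deviation_series: dropped ", dropped,
            " tree x event pair(s) with incomplete reference window")
  }
  if (length(rows) == 0L) {
    warning("deviation_series: no valid tree x event pairs")
    return(data.frame(tree_id = character(0), start_year = integer(0),
                      severity = character(0), rel_year = integer(0),
                      value = numeric(0), ref = numeric(0),
                      deviation = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Superposed-epoch deviation table
#'
#' Pools tree x event deviations within each severity class and, for each
#' relative year `k = 1 ... horizon`, reports the mean deviation ratio, the
#' percent deviation `(ratio - 1) x 100`, a Welch t-test of the year-`k`
#' deviations against the pooled pre-event (reference-window) deviations of
#' the same class, and the sample size.
#'
#' @param devs Deviation table from [deviation_series()].
#' @param alpha Significance level used for the duration count.
#' @param duration_mode `"consecutive"` (years significant from year 1 until
#'   the first non-significant year) or `"total"` (all significant years).
#' @return `data.frame` with one row per (severity, rel_year):
#'   `severity`, `rel_year`, `ratio`, `percent`, `p`, `stars`, `n`; attribute
#'   `"summary"` holds per-severity `duration` and `max_deviation` (percent
#'   deviation in the year of strongest reduction).
#' @export
epoch_table <- function(devs, alpha = 0.05,
                        duration_mode = c("consecutive", "total")) {
  duration_mode <- match.arg(duration_mode)
  if (nrow(devs) == 0L) {
    warning("epoch_table: empty deviation table")
    return(data.frame())
  }
  out <- list()
  summ <- list()
  for (g in split(devs, devs$severity)) {
    pre <- g$deviation[g$rel_year < 0L]
    ks <- sort(unique(g$rel_year[g$rel_year > 0L]))
    rows <- lapply(ks, function(k) {
      dk <- g$deviation[g$rel_year == k]
      wt <- welch_test(dk, pre)
      data.frame(severity = g$severity[1L], rel_year = k,
                 ratio = mean(dk), percent = (mean(dk) - 1) * 100,
                 p = wt$p, stars = wt$stars, n = length(dk),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    out[[length(out) + 1L]] <- tab
    summ[[length(summ) + 1L]] <- data.frame(
      severity = tab$severity[1L],
      duration = effect_duration(tab$p, alpha = alpha, mode = duration_mode),
      max_deviation = tab$percent[which.min(tab$ratio)],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "summary") <- do.call(rbind, summ)
  out
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom, with
#' significance stars at 0.05/0.01/0.001. Groups with fewer than 2 values or
#' zero variance are reported as not testable (`NA`), never as a silent
#' p of 0 or 1.
#'
#' @param a,b Numeric samples.
#' @return List with `t`, `df`, `p`, `stars`, `testable`.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L ||
      stats::var(a) == 0 || stats::var(b) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, stars = NA_character_,
                testable = FALSE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, stars = significance_stars(tt$p.value),
       testable = TRUE)
}

#' Significance stars at the 0.05/0.01/0.001 thresholds
#'
#' @param p P-value(s).
#' @return Character vector: `"***"`, `"**"`, `"*"` or `""`.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Effect duration from a sequence of epoch p-values
#'
#' Number of years a parameter stayed significantly different from the
#' reference: by default the maximal run of consecutive significant years
#' starting at relative year 1 (a non-significant year terminates the count);
#' `mode = "total"` counts all significant years in the horizon.
#'
#' @param p P-values for relative years 1 ... horizon, in order.
#' @param alpha Significance level.
#' @param mode `"consecutive"` or `"total"`.
#' @return Integer duration.
#' @export
effect_duration <- function(p, alpha = 0.05,
                            mode = c("consecutive", "total")) {
  mode <- match.arg(mode)
  sig <- !is.na(p) & p < alpha
  if (mode == "total") return(sum(sig))
  d <- 0L
  for (s in sig) {
    if (!s) break
    d <- d + 1L
  }
  d
}

#' Intra-ring profile of a cell parameter by relative position
#'
#' Locally weighted regression (loess: tricube weights, locally linear) of a
#' cell-level parameter on the cell's relative position in the ring (percent
#' distance from the ring border at the start of the ring), pooled over all
#' rings in the set, evaluated with pointwise standard errors on a fixed
#' percent grid. Cells lacking `relative_position_pct` get it from cumulative
#' radial extents within their radial file (`CLD + 2 CWT_rad` per cell).
#'
#' @param cells Cell table with derived traits for the rings to pool.
#' @param parameter Cell-level column to profile (e.g. `"CWT"`, `"CLD"`,
#'   `"CWA"`).
#' @param grid_step Grid spacing in percent (default 1).
#' @param span Loess span (default 0.3).
#' @return A `data.frame` (`position_pct`, `fit`, `se`) of class
#'   `"qwa_profile"`, with attributes `parameter` and `n_cells`. With fewer
#'   than 10 cells no fit is attempted: the raw points are returned with
#'   attribute `raw_points = TRUE`.
#' @export
intra_ring_profile <- function(cells, parameter, grid_step = 1, span = 0.3) {
  if (!parameter %in% names(cells)) {
    stop("parameter not found in cell table: ", parameter)
  }
  cells <- relative_positions(cells)
  pos <- cells$relative_position_pct
  val <- cells[[parameter]]
  ok <- !is.na(pos) & !is.na(val)
  pos <- pos[ok]
  val <- val[ok]
  if (length(val) < 10L) {
    out <- data.frame(position_pct = pos, fit = val, se = NA_real_)
    attr(out, "raw_points") <- TRUE
    attr(out, "parameter") <- parameter
    attr(out, "n_cells") <- length(val)
    class(out) <- c("qwa_profile", "data.frame")
    return(out)
  }
  grid <- seq(0, 100, by = grid_step)
  fit <- stats::loess(val ~ pos, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, newdata = data.frame(pos = grid), se = TRUE)
  out <- data.frame(position_pct = grid, fit = as.vector(pr$fit),
                    se = as.vector(pr$se.fit))
  attr(out, "raw_points") <- FALSE
  attr(out, "parameter") <- parameter
  attr(out, "n_cells") <- length(val)
  class(out) <- c("qwa_profile", "data.frame")
  out
}

#' Fill in relative intra-ring positions from cumulative radial extents
#'
#' Position of a cell = (cumulative radial extent of the preceding cells in
#' its radial file + half its own extent) / total file extent x 100, with the
#' per-cell radial extent `CLD + 2 CWT_rad`. Cells that already carry
#' `relative_position_pct` are left untouched.
#'
#' @param cells Cell table with derived traits (and `radial_file_id` /
#'   `file_rank`, assigned if absent).
#' @return Cells with `relative_position_pct` filled.
#' @export
relative_positions <- function(cells) {
  if (!is.null(cells$relative_position_pct) &&
      !anyNA(cells$relative_position_pct)) {
    return(cells)
  }
  if (is.null(cells$CLD)) stop("derive cell traits before computing positions")
  cells$.ring <- paste(cells$tree_id, cells$year, sep = "\r")
  parts <- split(seq_len(nrow(cells)), cells$.ring)
  pos <- rep(NA_real_, nrow(cells))
  for (idx in parts) {
    rc <- cells[idx, , drop = FALSE]
    if (is.null(rc$radial_file_id) || all(is.na(rc$radial_file_id))) {
      rc <- assign_radial_files(rc)
    }
    if (is.null(rc$file_rank)) rc <- assign_radial_files(rc)
    ext <- rc$CLD + 2 * rc$CWT_rad
    for (f in split(seq_len(nrow(rc)), rc$radial_file_id)) {
      o <- f[order(rc$file_rank[f])]
      e <- ext[o]
      pos[idx[o]] <- (cumsum(e) - e / 2) / sum(e) * 100
    }
  }
  fill <- is.na(cells$relative_position_pct)
  if (is.null(cells$relative_position_pct)) {
    cells$relative_position_pct <- pos
  } else {
    cells$relative_position_pct[fill] <- pos[fill]
  }
  cells$.ring <- NULL
  cells
}

#' Superpose intra-ring profiles on a common reference
#'
#' The reference is the pointwise mean of the pre-event profiles (typically
#' the five years before the outbreak); each post-event profile is reported
#' as its pointwise difference from the reference with propagated standard
#' errors (`sqrt(se_k^2 + se_ref^2)`, the reference SE being the SE of the
#' mean of the pre-event fits).
#'
#' @param pre List of pre-event profiles from [intra_ring_profile()] (all on
#'   the same grid).
#' @param post Named list of post-event profiles on the same grid.
#' @return List with `reference` (grid, fit, se) and `differences` (named
#'   list of `data.frame`s: grid, diff, se).
#' @export
superpose_profiles <- function(pre, post) {
  if (inherits(pre, "qwa_profile")) pre <- list(pre)
  if (inherits(post, "qwa_profile")) post <- list(year1 = post)
  grids <- lapply(c(pre, post), function(p) p$position_pct)
  if (!all(vapply(grids, identical, logical(1L), y = grids[[1L]]))) {
    stop("superpose_profiles: profiles are not on identical grids")
  }
  fit_mat <- vapply(pre, function(p) p$fit, numeric(length(grids[[1L]])))
  se_mat <- vapply(pre, function(p) p$se, numeric(length(grids[[1L]])))
  n_pre <- length(pre)
  ref_fit <- rowMeans(as.matrix(fit_mat))
  ref_se <- sqrt(rowSums(as.matrix(se_mat)^2)) / n_pre
  reference <- data.frame(position_pct = grids[[1L]], fit = ref_fit,
                          se = ref_se)
  differences <- lapply(post, function(p) {
    data.frame(position_pct = p$position_pct, diff = p$fit - ref_fit,
               se = sqrt(p$se^2 + ref_se^2))
  })
  list(reference = reference, differences = differences)
}

#' Contrast ring-width vs ring-wall-area first-year deviations
#'
#' Paired comparison of per tree x event year-1 deviations of ring width
#' (RW) and ring wall area (RWA): the per-pair differences are tested against
#' zero (the paired analogue of the Welch convention), and the mean losses of
#' both estimates are reported along with how much the RW-based loss
#' understates the RWA-based loss.
#'
#' @param rw_dev,rwa_dev Paired numeric vectors of year-1 deviation ratios
#'   (same tree x event order).
#' @return List: `t`, `df`, `p`, `testable`, `mean_rw_loss_pct`,
#'   `mean_rwa_loss_pct` (100 x (1 - mean deviation)), and
#'   `rw_understatement_pct` (percent by which the RW-based loss is lower
#'   than the RWA-based loss).
#' @export
rw_vs_rwa_contrast <- function(rw_dev, rwa_dev) {
  ok <- !is.na(rw_dev) & !is.na(rwa_dev)
  rw_dev <- rw_dev[ok]
  rwa_dev <- rwa_dev[ok]
  if (length(rw_dev) != length(rwa_dev)) {
    stop("rw_vs_rwa_contrast: deviations must be paired")
  }
  d <- rwa_dev - rw_dev
  rw_loss <- (1 - mean(rw_dev)) * 100
  rwa_loss <- (1 - mean(rwa_dev)) * 100
  und <- if (rwa_loss != 0) (rwa_loss - rw_loss) / rwa_loss * 100 else NA_real_
  if (length(d) < 3L || stats::var(d) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = if (all(d == 0)) 1 else NA_real_,
                testable = FALSE, mean_rw_loss_pct = rw_loss,
                mean_rwa_loss_pct = rwa_loss, rw_understatement_pct = und))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       testable = TRUE, mean_rw_loss_pct = rw_loss,
       mean_rwa_loss_pct = rwa_loss, rw_understatement_pct = und)
}
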