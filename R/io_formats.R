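# Reading/writing external representations: delimited cell tables (ROXAS-like
# exports), Tucson .rwl ring-width files, and monthly climate tables.

.cell_required_cols <- c(
  "tree_id", "year", "cell_index",
  "lumen_radial_diameter_um", "lumen_area_um2",
  "wall_thickness_radial_um", "wall_thickness_tangential_um",
  "wall_area_um2"
)
.cell_optional_cols <- c("radial_file_id", "relative_position_pct",
                         "x_um", "y_um")
.cell_dim_cols <- c(
  "lumen_radial_diameter_um", "lumen_area_um2",
  "wall_thickness_radial_um", "wall_thickness_tangential_um",
  "wall_area_um2"
)

#' Read a delimited cell-measurement table
#'
#' Reads one row per measured tracheid. Column names are matched
#' case-insensitively against the canonical schema; additional header spellings
#' (e.g. from different anatomical-measurement software versions) can be mapped
#' through `aliases`.
#'
#' Required columns: `tree_id`, `year`, `cell_index`,
#' `lumen_radial_diameter_um`, `lumen_area_um2`, `wall_thickness_radial_um`,
#' `wall_thickness_tangential_um`, `wall_area_um2`. Optional:
#' `radial_file_id`, `relative_position_pct`, `x_um`, `y_um` (tangential /
#' radial centroid coordinates).
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter (default comma).
#' @param aliases Named character vector mapping non-canonical header names to
#'   canonical schema names, e.g. `c(LD = "lumen_radial_diameter_um")`.
#'   Matching is case-insensitive.
#' @param year_range Plausible calendar-year range; rows outside it are a
#'   validation error.
#' @return A `data.frame` of validated cells sorted by
#'   `(tree_id, year, cell_index)`.
#' @export
read_cell_table <- function(path, delim = ",", aliases = NULL,
                            year_range = c(1000, 2100)) {
  if (!file.exists(path)) stop("cell table not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = delim,
                         stringsAsFactors = FALSE, check.names = FALSE)
  names(d) <- .canonical_names(names(d), aliases)
  missing <- setdiff(.cell_required_cols, names(d))
  if (length(missing) > 0L) {
    stop("cell table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  validate_cell_table(d, year_range = year_range)
  d <- d[order(d$tree_id, d$year, d$cell_index), , drop = FALSE]
  rownames(d) <- NULL
  d
}

.canonical_names <- function(nms, aliases = NULL) {
  canon <- c(.cell_required_cols, .cell_optional_cols)
  lut <- stats::setNames(canon, tolower(canon))
  if (!is.null(aliases)) {
    lut <- c(lut, stats::setNames(unname(aliases), tolower(names(aliases))))
  }
  hit <- lut[tolower(nms)]
  ifelse(is.na(hit), nms, hit)
}

#' Validate a cell table against the schema invariants
#'
#' Checks required columns, strict positivity of all dimension columns,
#' uniqueness of `(tree_id, year, cell_index)` and the plausible year range.
#' Errors cite the offending column and row.
#'
#' @inheritParams read_cell_table
#' @param cells A cell `data.frame`.
#' @return `cells`, invisibly, if valid.
#' @export
validate_cell_table <- function(cells, year_range = c(1000, 2100)) {
  missing <- setdiff(.cell_required_cols, names(cells))
  if (length(missing) > 0L) {
    stop("cell table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  for (col in .cell_dim_cols) {
    v <- cells[[col]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0L) {
      stop("cell table validation error: non-positive ", col,
           " on row ", bad[1L])
    }
  }
  bad_year <- which(cells$year < year_range[1L] | cells$year > year_range[2L])
  if (length(bad_year) > 0L) {
    stop("cell table validation error: year out of range on row ",
         bad_year[1L])
  }
  key <- paste(cells$tree_id, cells$year, cells$cell_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("cell table validation error: duplicate (tree_id, year, cell_index) ",
         "on row ", which(duplicated(key))[1L])
  }
  invisible(cells)
}

#' Write a cell table
#'
#' @param cells Cell `data.frame`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_cell_table <- function(cells, path, delim = ",") {
  utils::write.table(cells, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a Tucson (decadal) ring-width file
#'
#' Parses the community-standard `.rwl` layout: series ID, decade start year,
#' then up to ten ring-width values per line. The measurement unit is inferred
#' from the end-of-series sentinel: `999` means 0.01 mm units, `-9999` means
#' 0.001 mm units. Values are returned in millimetres.
#'
#' @param path Path to a `.rwl` file.
#' @return A `data.frame` with calendar years as row names and one column per
#'   series, `NA` where a series has no ring; widths in mm.
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop("rwl file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  series <- list()
  sentinel <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    id <- trimws(substr(ln, 1L, 8L))
    rest <- trimws(substr(ln, 9L, nchar(ln)))
    toks <- strsplit(rest, "[ \t]+")[[1L]]
    if (length(toks) < 2L || is.na(suppressWarnings(as.integer(toks[1L])))) {
      stop("rwl parse error on line ", i, ": malformed decade line")
    }
    decade <- as.integer(toks[1L])
    vals <- suppressWarnings(as.integer(toks[-1L]))
    if (anyNA(vals)) stop("rwl parse error on line ", i, ": non-numeric value")
    yrs <- decade + seq_along(vals) - 1L
    stopv <- vals %in% c(999L, -9999L)
    if (any(stopv)) {
      k <- which(stopv)[1L]
      sentinel[[id]] <- vals[k]
      vals <- vals[seq_len(k - 1L)]
      yrs <- yrs[seq_len(k - 1L)]
    }
    if (length(vals) > 0L) {
      series[[id]] <- rbind(series[[id]], cbind(year = yrs, value = vals))
    }
  }
  if (length(series) == 0L) stop("rwl parse error: no series found")
  all_years <- range(unlist(lapply(series, function(m) m[, "year"])))
  yrs <- seq(all_years[1L], all_years[2L])
  out <- matrix(NA_real_, nrow = length(yrs), ncol = length(series),
                dimnames = list(yrs, names(series)))
  for (id in names(series)) {
    m <- series[[id]]
    unit <- if (identical(sentinel[[id]], -9999L)) 0.001 else 0.01
    out[as.character(m[, "year"]), id] <- m[, "value"] * unit
  }
  as.data.frame(out, check.names = FALSE)
}

#' Write ring-width series in Tucson format
#'
#' @param rwl `data.frame` as returned by [read_rwl()]: years as row names,
#'   one column per series, widths in mm.
#' @param path Output path.
#' @param prec Storage precision in mm, `0.01` (sentinel 999) or `0.001`
#'   (sentinel -9999).
#' @export
write_rwl <- function(rwl, path, prec = c(0.01, 0.001)) {
  prec <- prec[1L]
  if (!prec %in% c(0.01, 0.001)) stop("prec must be 0.01 or 0.001")
  sent <- if (prec == 0.001) -9999L else 999L
  years <- as.integer(rownames(rwl))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(rwl)) {
    v <- rwl[[id]]
    ok <- which(!is.na(v))
    if (length(ok) == 0L) next
    yr0 <- years[min(ok)]
    yr1 <- years[max(ok)]
    vals <- c(as.integer(round(v[min(ok):max(ok)] / prec)), sent)
    yrs <- c(seq(yr0, yr1), yr1 + 1L)
    dec <- yrs - yrs %% 10L
    for (d in unique(dec)) {
      sel <- dec == d
      row_start <- yrs[sel][1L]
      writeLines(sprintf("%-8s%4d%s", substr(id, 1L, 8L), row_start,
                         paste(sprintf("%6d", vals[sel]), collapse = "")),
                 con)
    }
  }
  invisible(path)
}

#' Read a monthly climate table
#'
#' Expects a delimited file with columns `year`, `month`,
#' `temperature_mean_C`, `precipitation_sum_mm` (matched case-insensitively).
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter.
#' @return A validated `data.frame` ordered by year then month.
#' @export
read_climate <- function(path, delim = ",") {
  if (!file.exists(path)) stop("climate table not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = delim,
                         stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("year", "month", "temperature_mean_c", "precipitation_sum_mm")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L) {
    stop("climate table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  names(d)[names(d) == "temperature_mean_c"] <- "temperature_mean_C"
  validate_climate(d)
}

#' Validate a monthly climate table
#'
#' @param clim Climate `data.frame` with `year`, `month`,
#'   `temperature_mean_C`, `precipitation_sum_mm`.
#' @return The validated table, ordered by year then month.
#' @export
validate_climate <- function(clim) {
  if (any(clim$month < 1L | clim$month > 12L)) {
    stop("climate validation error: month outside 1-12")
  }
  if (any(clim$precipitation_sum_mm < 0)) {
    stop("climate validation error: negative precipitation")
  }
  key <- paste(clim$year, clim$month)
  if (anyDuplicated(key)) {
    stop("climate validation error: duplicate (year, month) ",
         key[which(duplicated(key))[1L]])
  }
  clim <- clim[order(clim$year, clim$month), , drop = FALSE]
  # months must be contiguous within the covered span
  idx <- clim$year * 12L + (clim$month - 1L)
  if (any(diff(idx) != 1L)) {
    stop("climate validation error: months not contiguous")
  }
  rownames(clim) <- NULL
  clim
}

#' Write a monthly climate table
#'
#' @param clim Climate `data.frame`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_climate <- function(clim, path, delim = ",") {
  utils::write.table(clim, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
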