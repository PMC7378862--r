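# Bootstrap correlations between detrended chronologies and monthly climate,
# with and without outbreak years.

#' Bootstrap monthly climate correlations of a chronology
#'
#' For each climate variable (monthly mean temperature, monthly precipitation
#' sum) and each requested month, computes the Pearson correlation between
#' the chronology and that month's series over their common years, and
#' bootstraps it by resampling year pairs with replacement. The reported `r`
#' is the bootstrap mean; the 95% confidence interval is the 2.5/97.5
#' percentile of the bootstrap distribution, and a correlation is flagged
#' significant when the interval excludes zero.
#'
#' @param crn Chronology: `data.frame` with `year` and `index`, or a named
#'   numeric vector.
#' @param climate Monthly climate table (see [read_climate()]).
#' @param months Months to test (default April-October, `4:10`).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for reproducible resampling.
#' @param exclude_years Years to drop before correlating (e.g. outbreak years
#'   plus carry-over; see [outbreak_exclusion_years()]).
#' @param min_overlap Minimum number of common years required (default 25).
#' @return `data.frame` with one row per (variable, month): `variable`
#'   (`"T"` or `"P"`), `month`, `r`, `ci_low`, `ci_high`, `significant`,
#'   `n_years`, `outbreaks_excluded`.
#' @export
monthly_correlations <- function(crn, climate, months = 4:10,
                                 n_boot = 1000L, seed = NULL,
                                 exclude_years = NULL, min_overlap = 25L) {
  x <- .as_year_series(crn)
  x <- x[!is.na(x)]
  if (!is.null(seed)) set.seed(seed)
  excluded <- length(exclude_years) > 0L
  if (excluded) x <- x[!as.integer(names(x)) %in% exclude_years]
  out <- list()
  for (variable in c("T", "P")) {
    col <- if (variable == "T") "temperature_mean_C" else "precipitation_sum_mm"
    for (m in months) {
      cm <- climate[climate$month == m, c("year", col)]
      cv <- stats::setNames(cm[[col]], cm$year)
      yrs <- intersect(names(x), names(cv))
      n <- length(yrs)
      if (n < min_overlap) {
        stop("monthly_correlations: only ", n, " overlapping years (minimum ",
             min_overlap, ")")
      }
      a <- unname(x[yrs])
      b <- unname(cv[yrs])
      boot_r <- .boot_cor(a, b, n_boot)
      ci <- stats::quantile(boot_r, c(0.025, 0.975), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        variable = variable, month = m, r = mean(boot_r),
        ci_low = ci[1L], ci_high = ci[2L],
        significant = ci[1L] > 0 | ci[2L] < 0,
        n_years = n, outbreaks_excluded = excluded,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# vectorized bootstrap of a Pearson correlation
.boot_cor <- function(a, b, n_boot) {
  n <- length(a)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  am <- matrix(a[idx], nrow = n)
  bm <- matrix(b[idx], nrow = n)
  am <- sweep(am, 2L, colMeans(am))
  bm <- sweep(bm, 2L, colMeans(bm))
  colSums(am * bm) / sqrt(colSums(am^2) * colSums(bm^2))
}

#' Years to exclude from climate correlations because of outbreaks
#'
#' Each outbreak start year plus `follow` subsequent years (default 2,
#' matching the multi-year carry-over of defoliation effects).
#'
#' @param events Events `data.frame` with `start_year`, or an integer vector
#'   of start years.
#' @param follow Number of years after each start year to exclude.
#' @return Sorted integer vector of years.
#' @export
outbreak_exclusion_years <- function(events, follow = 2L) {
  starts <- if (is.data.frame(events)) events$start_year else as.integer(events)
  sort(unique(unlist(lapply(starts, function(s) s + 0:follow))))
}
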