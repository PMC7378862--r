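# Detrended site chronologies: cubic smoothing spline with a 50% frequency
# cutoff, ratio indices, and Tukey biweight robust means.

#' Cubic smoothing spline detrending with a 50% frequency cutoff
#'
#' Fits a natural cubic smoothing spline (Reinsch penalty) to an annual
#' series, with the smoothing parameter chosen so that the spline's frequency
#' response equals 0.5 at the wavelength `cutoff` — the standard
#' dendrochronological spline parameterization. For annually spaced data the
#' spline smoother `(I + lambda K)^{-1}` attenuates a sinusoid of angular
#' frequency `w` by `1 / (1 + lambda mu(w))` with
#' `mu(w) = 3 (2 - 2 cos w)^2 / (2 + cos w)`, so `lambda = 1/mu(2 pi/cutoff)`.
#'
#' The returned index is the ratio observed/fitted, which removes
#' ontogenetic trends while preserving inter-annual variability around 1.
#' Internal gaps split the series; each contiguous segment of at least 10
#' years is detrended separately and shorter segments are dropped with a
#' warning. Years where the fitted curve is not strictly positive get `NA`
#' indices and are flagged.
#'
#' @param x Numeric series (strictly positive for ratio indices).
#' @param years Calendar years, same length as `x`; defaults to
#'   `seq_along(x)`.
#' @param cutoff Wavelength (years) at which the filter passes 50% amplitude;
#'   default 100.
#' @return `data.frame` with `year`, `value`, `fitted`, `index`.
#' @export
spline_detrend <- function(x, years = seq_along(x), cutoff = 100) {
  ok <- !is.na(x)
  x <- x[ok]
  years <- years[ok]
  if (length(x) < 10L) {
    stop("spline_detrend: series shorter than 10 years (", length(x), ")")
  }
  o <- order(years)
  x <- x[o]
  years <- years[o]
  seg <- cumsum(c(1L, as.integer(diff(years) != 1L)))
  out <- lapply(split(seq_along(x), seg), function(idx) {
    if (length(idx) < 10L) {
      warning("spline_detrend: dropping segment of ", length(idx),
              " years (< 10)")
      return(NULL)
    }
    fit <- .csaps_cutoff(x[idx], cutoff)
    bad <- fit <= 0
    if (any(bad)) {
      warning("spline_detrend: non-positive fitted values in ", sum(bad),
              " year(s); indices set to NA")
    }
    data.frame(year = years[idx], value = x[idx], fitted = fit,
               index = ifelse(bad, NA_real_, x[idx] / fit))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("spline_detrend: no segment of >= 10 years")
  rownames(out) <- NULL
  out
}

# Smoothing spline g = (I + lambda K)^{-1} y for unit-spaced data,
# K = Q R^{-1} Q^T (Reinsch), lambda set from the 50% cutoff wavelength.
.csaps_cutoff <- function(y, cutoff) {
  n <- length(y)
  w <- 2 * pi / cutoff
  mu <- 3 * (2 - 2 * cos(w))^2 / (2 + cos(w))
  lambda <- 1 / mu
  if (n < 3L) return(y)
  # Q: n x (n-2) second-difference operator; R: (n-2) tridiagonal
  Q <- matrix(0, n, n - 2L)
  for (j in seq_len(n - 2L)) {
    Q[j, j] <- 1
    Q[j + 1L, j] <- -2
    Q[j + 2L, j] <- 1
  }
  R <- diag(2 / 3, n - 2L)
  if (n > 3L) {
    for (j in seq_len(n - 3L)) {
      R[j, j + 1L] <- 1 / 6
      R[j + 1L, j] <- 1 / 6
    }
  }
  K <- Q %*% solve(R, t(Q))
  as.vector(solve(diag(n) + lambda * K, y))
}

#' Tukey biweight robust mean
#'
#' Iteratively reweighted location estimate: starting from the median `m`,
#' weights `(1 - u^2)^2` for `|u| < 1` (0 otherwise) with
#' `u = (x - m)/(c * S)`, where `S` is the median absolute deviation about the
#' median; the weighted mean is iterated to convergence. With fewer than 3
#' values the arithmetic mean is returned.
#'
#' @param x Numeric values (NAs dropped).
#' @param c Tuning constant (default 9).
#' @param tol Convergence tolerance on the location.
#' @param max_iter Iteration cap.
#' @return The robust location estimate.
#' @export
biweight_mean <- function(x, c = 9, tol = 1e-12, max_iter = 100L) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (length(x) < 3L) return(mean(x))
  m <- stats::median(x)
  S <- stats::median(abs(x - m))
  if (all(x == m)) return(m)
  # small additive guard keeps zero-MAD samples well-defined: values at the
  # median keep weight 1, distant values drop to weight 0
  denom <- c * S + 1e-9 * max(abs(x), 1)
  for (i in seq_len(max_iter)) {
    u <- (x - m) / denom
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Detrend each tree's series of a ring-level parameter
#'
#' Convenience wrapper: pivots a ring table to a year-by-tree matrix of the
#' chosen parameter and detrends each tree with [spline_detrend()].
#'
#' @param rings Ring table from [ring_table()] (columns `tree_id`, `year`, and
#'   the parameter), or an already-pivoted year-by-tree matrix with year row
#'   names.
#' @param parameter Column to detrend (e.g. `"mean_CWT"`, `"CN"`, `"RW"`).
#' @param cutoff Spline cutoff in years.
#' @return Year-by-tree matrix of ratio indices with year row names.
#' @export
detrend_trees <- function(rings, parameter = "mean_CWT", cutoff = 100) {
  mat <- if (is.matrix(rings)) rings else param_matrix(rings, parameter)
  idx <- mat
  idx[] <- NA_real_
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    det <- spline_detrend(v, years = as.integer(rownames(mat)),
                          cutoff = cutoff)
    idx[as.character(det$year), j] <- det$index
  }
  idx
}

#' Pivot a ring table to a year-by-tree matrix
#'
#' @inheritParams detrend_trees
#' @return Numeric matrix, years as row names, trees as column names.
#' @export
param_matrix <- function(rings, parameter) {
  if (!parameter %in% names(rings)) {
    stop("parameter not found in ring table: ", parameter)
  }
  yrs <- sort(unique(rings$year))
  trees <- sort(unique(as.character(rings$tree_id)))
  mat <- matrix(NA_real_, length(yrs), length(trees),
                dimnames = list(yrs, trees))
  mat[cbind(match(rings$year, yrs),
            match(as.character(rings$tree_id), trees))] <- rings[[parameter]]
  mat
}

#' Build a site chronology from per-tree detrended indices
#'
#' Per-year Tukey biweight robust mean of the available tree indices, with
#' sample depth; years with fewer than `min_depth` trees are masked (`NA`
#' index, depth still reported).
#'
#' @param index_mat Year-by-tree matrix of detrended indices
#'   (see [detrend_trees()]).
#' @param min_depth Minimum number of trees for the index to be reported.
#' @param c Biweight tuning constant.
#' @return `data.frame` with `year`, `index`, `depth`.
#' @export
build_chronology <- function(index_mat, min_depth = 4L, c = 9) {
  if (is.null(dim(index_mat))) {
    index_mat <- matrix(index_mat, ncol = 1L,
                        dimnames = list(names(index_mat), "tree1"))
  }
  depth <- apply(index_mat, 1L, function(v) sum(!is.na(v)))
  if (all(depth == 0L)) warning("build_chronology: no overlapping years")
  idx <- apply(index_mat, 1L, biweight_mean, c = c)
  idx[depth < min_depth] <- NA_real_
  data.frame(year = as.integer(rownames(index_mat)), index = idx,
             depth = as.integer(depth), row.names = NULL)
}

#' Pearson correlation between two annual series
#'
#' @param a,b Named numeric vectors (names = years) or `data.frame`s with
#'   `year` and `index` columns; correlated over common years.
#' @return List with `r`, `p` (two-sided, t transform), `n`.
#' @export
pearson_r <- function(a, b) {
  a <- .as_year_series(a)
  b <- .as_year_series(b)
  yrs <- intersect(names(a), names(b))
  av <- a[yrs]
  bv <- b[yrs]
  ok <- !is.na(av) & !is.na(bv)
  av <- av[ok]
  bv <- bv[ok]
  if (length(av) < 5L) stop("pearson_r: fewer than 5 common years")
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    stop("pearson_r: zero variance in one series; correlation undefined")
  }
  ct <- stats::cor.test(av, bv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(av))
}

.as_year_series <- function(x) {
  if (is.data.frame(x)) {
    val_col <- intersect(c("index", "value"), names(x))[1L]
    if (is.na(val_col)) stop("need an 'index' or 'value' column")
    stats::setNames(x[[val_col]], x$year)
  } else {
    if (is.null(names(x))) names(x) <- seq_along(x)
    x
  }
}
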