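# Outbreak identification from the host cell-wall-thickness chronology, with
# an optional non-host (climate control) veto, and severity classification.

#' Detect outbreak start years from a host CWT chronology
#'
#' A year `t` is a candidate outbreak start when the host chronology drops
#' more than `delta` below its own mean over the five preceding years:
#' `host(t) < (1 - delta) * mean(host[t-5 ... t-1])`. When a non-host
#' (climate control) chronology is supplied, candidates in which the non-host
#' also declines by at least `delta` relative to its own 5-year reference are
#' vetoed as climate-driven. Candidate years closer together than
#' `min_separation` are merged, keeping the year with the strongest relative
#' decline. The rule is invariant to multiplying a chronology by a positive
#' constant.
#'
#' Alternatively, known outbreak start years (e.g. from published outbreak
#' chronologies) can be supplied via `events`; detection is then skipped and
#' the function only computes each year's first-year ratio for severity
#' classification.
#'
#' @param host Host chronology: `data.frame` with `year` and `index` (see
#'   [build_chronology()]) or a named numeric vector.
#' @param nonhost Optional non-host chronology in the same form.
#' @param delta Relative decline threshold (default 0.10).
#' @param min_separation Minimum spacing (years) between reported events.
#' @param ref_window Length of the pre-event reference window (years).
#' @param events Optional integer vector of known start years.
#' @param site_id Site label carried into the output.
#' @return `data.frame` with `site_id`, `start_year`,
#'   `first_year_cwt_ratio`, sorted by year; attribute `"trace"` holds all
#'   candidate ratios and veto outcomes.
#' @export
detect_outbreaks <- function(host, nonhost = NULL, delta = 0.10,
                             min_separation = 6L, ref_window = 5L,
                             events = NULL, site_id = "site") {
  h <- .as_year_series(host)
  h <- h[!is.na(h)]
  if (length(h) == 0L) stop("detect_outbreaks: empty host chronology")
  if (is.null(events) && length(h) < 15L) {
    stop("detect_outbreaks: host chronology shorter than 15 years")
  }
  yrs <- as.integer(names(h))
  ratio_vs_ref <- function(series, year) {
    ref_years <- as.character(seq(year - ref_window, year - 1L))
    ref <- series[ref_years]
    if (anyNA(ref) || length(ref) < ref_window) return(NA_real_)
    unname(series[as.character(year)] / mean(ref))
  }

  if (!is.null(events)) {
    ratios <- vapply(events, ratio_vs_ref, numeric(1L), series = h)
    out <- data.frame(site_id = site_id, start_year = as.integer(events),
                      first_year_cwt_ratio = ratios)
    out <- out[order(out$start_year), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "trace") <- data.frame(year = out$start_year,
                                     ratio = out$first_year_cwt_ratio,
                                     vetoed = FALSE, supplied = TRUE)
    return(out)
  }

  nh <- if (!is.null(nonhost)) .as_year_series(nonhost) else NULL
  cand_years <- yrs[-seq_len(min(ref_window, length(yrs)))]
  ratios <- vapply(cand_years, ratio_vs_ref, numeric(1L), series = h)
  is_cand <- !is.na(ratios) & ratios < (1 - delta)
  vetoed <- rep(FALSE, length(cand_years))
  if (!is.null(nh)) {
    nh_ratio <- vapply(cand_years, ratio_vs_ref, numeric(1L), series = nh)
    vetoed <- is_cand & !is.na(nh_ratio) & nh_ratio < (1 - delta)
  }
  trace <- data.frame(year = cand_years, ratio = ratios,
                      candidate = is_cand, vetoed = vetoed)
  keep <- which(is_cand & !vetoed)
  if (length(keep) == 0L) {
    if (any(is_cand) && all(vetoed[is_cand])) {
      message("detect_outbreaks: all candidates vetoed by non-host control")
    }
    out <- data.frame(site_id = character(0), start_year = integer(0),
                      first_year_cwt_ratio = numeric(0))
    attr(out, "trace") <- trace
    return(out)
  }
  # merge candidates closer than min_separation, strongest decline first
  sel <- integer(0)
  for (i in keep[order(ratios[keep])]) {
    if (!any(abs(cand_years[sel] - cand_years[i]) < min_separation)) {
      sel <- c(sel, i)
    }
  }
  sel <- sel[order(cand_years[sel])]
  out <- data.frame(site_id = site_id, start_year = cand_years[sel],
                    first_year_cwt_ratio = unname(ratios[sel]))
  rownames(out) <- NULL
  attr(out, "trace") <- trace
  out
}

#' Split detected outbreaks into high/low severity classes
#'
#' Events are ranked by their first-year CWT ratio (ascending, i.e. strongest
#' reduction first); the lower half — `floor(n/2)` events — is labelled
#' `"high"`, the rest `"low"` (odd counts place the median event in `"low"`).
#' Ties on the ratio are broken by the earlier year taking `"high"`.
#'
#' @param events Events `data.frame` from [detect_outbreaks()].
#' @return The events with a `severity` column; with fewer than 2 events all
#'   are `"unclassified"` (with a warning).
#' @export
classify_severity <- function(events) {
  n <- nrow(events)
  if (n < 2L) {
    warning("classify_severity: fewer than 2 events; labelling unclassified")
    events$severity <- rep("unclassified", n)
    return(events)
  }
  o <- order(events$first_year_cwt_ratio, events$start_year)
  sev <- rep("low", n)
  sev[o[seq_len(floor(n / 2))]] <- "high"
  events$severity <- sev
  events
}
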