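#' Aggregate a daily or weekly panel to biweekly periods
#'
#' Sums weights within each 14-day half-open window `[anchor + 14k,
#' anchor + 14(k+1))`, per county and symptom. A biweekly cell is missing
#' only if every contributing sub-period cell is missing. Periods before the
#' anchor and trailing windows not fully covered by the input span are
#' dropped. Summation (rather than averaging) is safe because scaling is
#' consistent within a county, so the downstream share statistic is
#' invariant to this choice. A panel that is already on an aligned 14-day
#' grid is returned unchanged.
#'
#' @param panel a [symptom_panel()] on a regular 1- or 7-day grid.
#' @param anchor `Date`: start of the first biweekly window.
#' @return a biweekly [symptom_panel()]; periods labelled by window start.
#' @export
resample_to_biweekly <- function(panel, anchor) {
  anchor <- as.Date(anchor)
  dates <- sort(unique(panel$period_start))
  if (anchor > max(dates)) stop("anchor is after the last panel date: empty output")
  if (length(dates) > 1L) {
    step <- unique(diff(as.integer(dates)))
    if (length(step) != 1L) {
      stop("irregular input periods: spacing is not constant")
    }
  } else {
    step <- 14L  # single period: treat as pre-aggregated
  }
  if (!step %in% c(1L, 7L, 14L)) {
    stop("input period spacing must be 1, 7 or 14 days, got ", step)
  }
  if (step == 14L) {
    if (as.integer(min(dates) - anchor) %% 14L != 0L) {
      stop("panel already biweekly but not aligned to the anchor")
    }
    return(panel)
  }
  dt <- as.data.table(panel)
  dt <- dt[period_start >= anchor]
  if (!nrow(dt)) stop("anchor is after all panel dates: empty output")
  dt[, window_start := anchor + 14L * (as.integer(period_start - anchor) %/% 14L)]
  # a window is complete iff its last sub-period lies within the input span
  span_end <- max(dates) + step  # half-open end of input coverage
  dt <- dt[window_start + 14L <= span_end]
  if (!nrow(dt)) stop("no complete biweekly window inside the panel span")
  agg <- dt[, .(weight = if (all(is.na(weight))) NA_real_ else
    sum(weight, na.rm = TRUE)),
    by = .(county_fips, period_start = window_start, symptom_id)]
  symptom_panel(agg, registry = attr(panel, "registry"))
}
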