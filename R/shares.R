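#' Share of search
#'
#' The core normalization: each symptom's weight divided by the summed
#' weight of all symptoms for the same county and period, times 100. Because
#' the unknown per-region scale factor multiplies numerator and denominator
#' alike, shares are comparable across counties even though raw weights are
#' not. The denominator runs over the non-missing weights of that
#' county-period: suppressed cells reflect privacy thresholds, not absence
#' of searching, so they are excluded rather than imputed as zero (imputing
#' zero would bias observed symptoms' shares upward). If the denominator is
#' zero, every share in that county-period is missing.
#'
#' @param panel a [symptom_panel()].
#' @return `share_table`: data.table with `county_fips`, `period_start`,
#'   `symptom_id`, `share` (percent, 0-100 or `NA`); registry carried over.
#' @export
share_of_search <- function(panel) {
  dt <- copy(as.data.table(panel))
  dt[, denom := sum(weight, na.rm = TRUE), by = .(county_fips, period_start)]
  dt[, share := ifelse(denom > 0, 100 * weight / denom, NA_real_)]
  out <- dt[, .(county_fips, period_start, symptom_id, share)]
  setattr(out, "registry", attr(panel, "registry"))
  setattr(out, "class", c("share_table", class(out)))
  out
}

#' Composite share over a symptom set
#'
#' Per county-period sum of the member symptoms' shares (e.g. the
#' mental-health composite: what percentage of all symptom searching was for
#' mental-health topics). Missing only when every member share is missing.
#'
#' @param shares a `share_table` from [share_of_search()].
#' @param symptom_set character vector of member ids (or an
#'   `mh_symptom_set`, whose `final_ids` are used). Must be nonempty and,
#'   when a registry is attached, a subset of it.
#' @return `set_share_series`: data.table with `county_fips`, `period_start`,
#'   `set_share`.
#' @export
set_share <- function(shares, symptom_set) {
  if (inherits(symptom_set, "mh_symptom_set")) {
    symptom_set <- symptom_set$final_ids
  }
  symptom_set <- unique(as.character(symptom_set))
  if (!length(symptom_set)) stop("symptom set must be nonempty")
  reg <- attr(shares, "registry")
  if (!is.null(reg)) {
    unknown <- setdiff(symptom_set, reg$symptom_id)
    if (length(unknown)) {
      stop("symptom set id(s) not in registry: ",
           paste(unknown, collapse = ", "))
    }
  }
  dt <- as.data.table(shares)[symptom_id %in% symptom_set]
  out <- dt[, .(set_share = if (all(is.na(share))) NA_real_ else
    sum(share, na.rm = TRUE)),
    by = .(county_fips, period_start)]
  setattr(out, "class", c("set_share_series", class(out)))
  out
}

#' Per-county mean over a time window
#'
#' Unweighted mean of the non-missing values whose period start falls in the
#' half-open window `[start, end)`; counties (or county-symptom pairs) with
#' no observed period in the window are omitted.
#'
#' @param x a `share_table` or `set_share_series`.
#' @param window length-2 vector of dates `(start, end)`.
#' @return data.table of per-county (and per-symptom, for share tables)
#'   means in column `mean_share`.
#' @export
window_mean <- function(x, window) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[1] < window[2])
  dt <- as.data.table(x)
  valcol <- if ("share" %in% names(dt)) "share" else "set_share"
  dt <- dt[period_start >= window[1] & period_start < window[2]]
  if (!nrow(dt)) stop("window does not overlap the panel span")
  by_cols <- intersect(c("county_fips", "symptom_id"), names(dt))
  out <- dt[!is.na(get(valcol)),
            .(mean_share = mean(get(valcol)), n_obs = .N),
            by = by_cols]
  out[]
}
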