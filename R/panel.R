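#' Symptom search-weight panel
#'
#' The raw unit of analysis: long-form records of a nonnegative search weight
#' (or a missing value, when the provider suppressed the cell for privacy)
#' per county, period and symptom topic. Weights carry an unknown per-region
#' scale factor, so only ratios within a county-period are meaningful; see
#' [share_of_search()].
#'
#' @param records data.frame with columns `county_fips` (character, coerced
#'   to zero-padded 5-character codes), `period_start` (`Date`),
#'   `symptom_id` (character) and `weight` (nonnegative numeric; `NA` =
#'   privacy-suppressed).
#' @param registry symptom registry as returned by [symptom_registry()], or
#'   `NULL` to infer it from the distinct `symptom_id` values.
#' @return A `symptom_panel`: a `data.table` keyed by
#'   (`county_fips`, `period_start`, `symptom_id`) with the registry attached
#'   as attribute `"registry"`.
#' @export
symptom_panel <- function(records, registry = NULL) {
  dt <- as.data.table(records)
  need <- c("county_fips", "period_start", "symptom_id", "weight")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("panel records lack column(s): ", paste(miss, collapse = ", "))
  }
  dt <- dt[, need, with = FALSE]
  dt[, county_fips := pad_fips(county_fips)]
  if (!inherits(dt$period_start, "Date")) {
    dt[, period_start := as.Date(period_start)]
  }
  dt[, symptom_id := as.character(symptom_id)]
  dt[, weight := as.numeric(weight)]
  bad <- which(!is.na(dt$weight) & dt$weight < 0)
  if (length(bad)) {
    r <- dt[bad[1L]]
    stop(sprintf(
      "negative weight %g for county %s, period %s, symptom '%s'",
      r$weight, r$county_fips, format(r$period_start), r$symptom_id
    ))
  }
  if (anyDuplicated(dt, by = c("county_fips", "period_start", "symptom_id"))) {
    stop("duplicate (county_fips, period_start, symptom_id) records in panel")
  }
  if (is.null(registry)) {
    registry <- symptom_registry(sort(unique(dt$symptom_id)))
  } else {
    unknown <- setdiff(unique(dt$symptom_id), registry$symptom_id)
    if (length(unknown)) {
      stop("panel contains symptom_id(s) absent from registry: ",
           paste(head(unknown, 5L), collapse = ", "))
    }
  }
  setorder(dt, county_fips, period_start, symptom_id)
  setattr(dt, "registry", registry)
  setattr(dt, "class", c("symptom_panel", class(dt)))
  dt
}

#' Symptom registry
#'
#' Ordered lookup of symptom topic identifiers and display names. The real
#' provider dataset carries 422 topics; any nonempty set is accepted.
#'
#' @param symptom_id character vector of unique ids.
#' @param display_name optional display names (defaults to the ids).
#' @return data.frame of class `symptom_registry`.
#' @export
symptom_registry <- function(symptom_id, display_name = symptom_id) {
  symptom_id <- as.character(symptom_id)
  if (!length(symptom_id)) stop("registry must contain at least one symptom")
  if (anyDuplicated(symptom_id)) stop("registry symptom ids must be unique")
  out <- data.frame(symptom_id = symptom_id,
                    display_name = as.character(display_name),
                    stringsAsFactors = FALSE)
  class(out) <- c("symptom_registry", "data.frame")
  out
}

#' @export
print.symptom_panel <- function(x, ...) {
  reg <- attr(x, "registry")
  cat(sprintf(
    "<symptom_panel> %d records | %d counties | %d periods | %d symptoms | %d suppressed cells\n",
    nrow(x), uniqueN(x$county_fips), uniqueN(x$period_start),
    nrow(reg), sum(is.na(x$weight))
  ))
  print(as.data.table(head(as.data.frame(x), 6L)))
  invisible(x)
}

# zero-pad county codes to 5 characters; leading zeros (New England state
# codes 01-09) are silently destroyed by numeric storage, so always character
pad_fips <- function(x) {
  x <- trimws(as.character(x))
  short <- !is.na(x) & nchar(x) < 5L
  x[short] <- paste0(strrep("0", 5L - nchar(x[short])), x[short])
  x
}

uniqueN <- data.table::uniqueN

#' Panel provenance: suppression accounting
#'
#' Compares the counties present in a panel against a full expected county
#' list; whole counties absent from the panel are taken to be
#' privacy-suppressed (the provider withholds sparsely populated counties
#' entirely).
#'
#' @param panel a [symptom_panel()].
#' @param county_list character vector of all expected county FIPS codes
#'   (the US has 3143 counties and county equivalents).
#' @return list with `n_counties_expected`, `n_counties_present`,
#'   `suppressed_counties`.
#' @export
panel_provenance <- function(panel, county_list) {
  county_list <- pad_fips(county_list)
  present <- unique(panel$county_fips)
  suppressed <- setdiff(county_list, present)
  structure(
    list(
      n_counties_expected = length(county_list),
      n_counties_present = length(intersect(county_list, present)),
      suppressed_counties = suppressed
    ),
    class = "panel_provenance"
  )
}

#' @export
print.panel_provenance <- function(x, ...) {
  cat(sprintf("<panel_provenance> %d/%d counties present, %d suppressed\n",
              x$n_counties_present, x$n_counties_expected,
              length(x$suppressed_counties)))
  invisible(x)
}
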