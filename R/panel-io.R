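#' Read a wide symptom search-weight CSV
#'
#' Reads the provider dialect: one row per county and period, a county-code
#' column, a date column, and one column per symptom topic (header optionally
#' prefixed `"symptom:"`). Empty cells are privacy-suppressed and become
#' missing values, never zero; a literal `0` is an observed zero.
#'
#' @param path CSV file path.
#' @param registry_mode `"infer"` builds the registry from the symptom column
#'   headers; `"strict"` requires `registry` and rejects unknown columns.
#' @param registry registry for `"strict"` mode.
#' @return a [symptom_panel()].
#' @export
read_symptom_panel <- function(path, registry_mode = c("infer", "strict"),
                               registry = NULL) {
  registry_mode <- match.arg(registry_mode)
  wide <- fread(path, na.strings = "")
  county_col <- intersect(
    c("county_fips", "fips", "sub_region_2_code", "county"), names(wide))[1]
  date_col <- intersect(
    c("date", "period_start", "week_start"), names(wide))[1]
  if (is.na(county_col) || is.na(date_col)) {
    stop("format error: need a county-code column (county_fips/fips/",
         "sub_region_2_code) and a date column (date/period_start)")
  }
  sym_cols <- setdiff(names(wide), c(county_col, date_col))
  if (!length(sym_cols)) stop("format error: no symptom columns found")
  wide[[county_col]] <- pad_fips(wide[[county_col]])
  if (anyDuplicated(wide, by = c(county_col, date_col))) {
    d <- wide[duplicated(wide, by = c(county_col, date_col))][1L]
    stop(sprintf("duplicate row for county %s, date %s",
                 d[[county_col]], as.character(d[[date_col]])))
  }
  for (col in sym_cols) {  # uniform double type avoids melt coercion noise
    wide[[col]] <- suppressWarnings(as.numeric(wide[[col]]))
  }
  long <- melt(wide, id.vars = c(county_col, date_col),
               variable.name = "symptom_col", value.name = "weight",
               variable.factor = FALSE)
  setnames(long, c(county_col, date_col), c("county_fips", "period_start"))
  long[, symptom_id := sub("^symptom[:_]", "", symptom_col)]
  long[, symptom_col := NULL]
  long[, weight := suppressWarnings(as.numeric(weight))]
  if (registry_mode == "strict") {
    if (is.null(registry)) stop("strict mode requires a registry")
    ids <- sub("^symptom[:_]", "", sym_cols)
    unknown <- setdiff(ids, registry$symptom_id)
    if (length(unknown)) {
      stop("strict mode: symptom column(s) not in registry: ",
           paste(unknown, collapse = ", "))
    }
  }
  symptom_panel(long, registry = registry)
}

#' Write a panel back to the wide provider dialect
#'
#' Inverse of [read_symptom_panel()]: suppressed cells are written as empty
#' strings so a round trip preserves the missing/zero distinction.
#'
#' @param panel a [symptom_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  wide <- dcast(as.data.table(panel), county_fips + period_start ~ symptom_id,
                value.var = "weight")
  fwrite(wide, path, na = "")
  invisible(path)
}

#' Read county shortage and urbanization designations
#'
#' Merges the shortage-designation file (county FIPS plus a status of
#' `shortage`, `partial` or `nonshortage`, restricted to geographic-area
#' designations) with the 6-tier urbanization code file. Counties present in
#' only one file are retained with the other field `NA` (unknown). The 6-tier
#' code collapses to three: tiers 1-4 metro, 5 micropolitan, 6 rural; tier 1
#' alone marks a large central metro (population >= 1 million).
#'
#' @param shortage_path CSV with columns `fips`, `status`, optionally
#'   `designation_type` (rows other than geographic-area designations — e.g.
#'   population groups or facilities — are dropped).
#' @param nchs_path CSV with columns `fips`, `nchs6`.
#' @return data.table of class `county_designation` with columns
#'   `county_fips`, `shortage_status`, `nchs6`, `urban3`,
#'   `is_large_central_metro`.
#' @export
read_designations <- function(shortage_path, nchs_path) {
  hrsa <- fread(shortage_path)
  if (!all(c("fips", "status") %in% names(hrsa))) {
    stop("shortage file needs columns (fips, status)")
  }
  if ("designation_type" %in% names(hrsa)) {
    hrsa <- hrsa[grepl("geographic", tolower(designation_type))]
  }
  hrsa[, fips := pad_fips(fips)]
  status <- parse_shortage_status(hrsa$status)
  hrsa <- data.table(county_fips = hrsa$fips, shortage_status = status)

  nchs <- fread(nchs_path)
  if (!all(c("fips", "nchs6") %in% names(nchs))) {
    stop("urbanization file needs columns (fips, nchs6)")
  }
  nchs[, fips := pad_fips(fips)]
  nchs6 <- as.integer(nchs$nchs6)
  bad <- which(!is.na(nchs6) & !(nchs6 %in% 1:6))
  if (length(bad)) {
    stop(sprintf("nchs6 code %s for county %s outside 1-6",
                 nchs$nchs6[bad[1]], nchs$fips[bad[1]]))
  }
  nchs <- data.table(county_fips = nchs$fips, nchs6 = nchs6)

  out <- merge(hrsa, nchs, by = "county_fips", all = TRUE)
  county_designation(out)
}

parse_shortage_status <- function(x) {
  key <- gsub("[^a-z]", "", tolower(as.character(x)))
  map <- c(shortage = "shortage",
           partial = "partial", partialshortage = "partial",
           partialshortagearea = "partial",
           nonshortage = "nonshortage", none = "nonshortage",
           notshortage = "nonshortage", nonshortagearea = "nonshortage")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unparseable shortage status value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' County designation table constructor
#'
#' @param df data.frame with `county_fips`, `shortage_status`
#'   (shortage/partial/nonshortage or `NA`) and `nchs6` (1-6 or `NA`);
#'   `urban3` and `is_large_central_metro` are derived.
#' @return data.table of class `county_designation`.
#' @export
county_designation <- function(df) {
  dt <- as.data.table(df)
  if (!all(c("county_fips", "shortage_status", "nchs6") %in% names(dt))) {
    stop("designations need columns (county_fips, shortage_status, nchs6)")
  }
  dt[, county_fips := pad_fips(county_fips)]
  ok <- dt$shortage_status %in% c("shortage", "partial", "nonshortage") |
    is.na(dt$shortage_status)
  if (!all(ok)) {
    stop("invalid shortage_status: ",
         paste(unique(dt$shortage_status[!ok]), collapse = ", "))
  }
  dt[, nchs6 := as.integer(nchs6)]
  if (any(!is.na(dt$nchs6) & !(dt$nchs6 %in% 1:6))) {
    stop("nchs6 codes must be in 1..6")
  }
  dt[, urban3 := collapse_nchs6(nchs6)]
  dt[, is_large_central_metro := !is.na(nchs6) & nchs6 == 1L]
  if (anyDuplicated(dt$county_fips)) stop("duplicate county_fips in designations")
  setattr(dt, "class", c("county_designation", class(dt)))
  dt
}

#' Collapse the 6-tier urbanization code to 3 tiers
#'
#' Tiers 1-4 are metropolitan, tier 5 micropolitan, tier 6 rural (noncore).
#'
#' @param nchs6 integer codes in 1..6 (NA allowed).
#' @return character vector: `"metro"`, `"micropolitan"` or `"rural"`.
#' @export
collapse_nchs6 <- function(nchs6) {
  out <- rep(NA_character_, length(nchs6))
  out[!is.na(nchs6) & nchs6 <= 4L] <- "metro"
  out[!is.na(nchs6) & nchs6 == 5L] <- "micropolitan"
  out[!is.na(nchs6) & nchs6 == 6L] <- "rural"
  out
}

#' Write a designation table
#' @param designations a `county_designation`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_designations <- function(designations, path) {
  fwrite(as.data.table(designations), path, na = "")
  invisible(path)
}
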