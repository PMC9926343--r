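#' Contrast design: which counties are compared with which
#'
#' Group membership is expressed as predicates over the designation table
#' (functions taking a `county_designation` and returning a logical vector).
#' By default, partially designated shortage counties are excluded from
#' two-group contrasts — only counties entirely designated shortage or
#' entirely nonshortage are compared — though they still appear in rankings
#' and time series.
#'
#' @param name short identifier for the contrast family.
#' @param group_a,group_b predicates `function(designations) -> logical`.
#' @param label_a,label_b display labels for the groups.
#' @param exclude predicate for counties dropped before grouping; default
#'   drops `shortage_status == "partial"`.
#' @param unit observation unit: `"county_period"` (each county contributes
#'   one observation per biweekly period) or `"county_mean"` (one span mean
#'   per county).
#' @return object of class `contrast_design`.
#' @export
contrast_design <- function(name, group_a, group_b,
                            label_a = "group_a", label_b = "group_b",
                            exclude = function(d) {
                              !is.na(d$shortage_status) &
                                d$shortage_status == "partial"
                            },
                            unit = c("county_period", "county_mean")) {
  unit <- match.arg(unit)
  stopifnot(is.function(group_a), is.function(group_b), is.function(exclude))
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 label_a = label_a, label_b = label_b, exclude = exclude,
                 unit = unit),
            class = "contrast_design")
}

#' Named contrast designs
#'
#' The standard contrast families: shortage vs nonshortage overall and
#' within rural / urban strata, and rural vs urban / rural vs metro within
#' shortage areas. "Urban" means the micropolitan tier (6-tier code 5);
#' "metro" means large central metro (code 1, population >= 1 million).
#'
#' @param name one of `"shortage_vs_nonshortage"`,
#'   `"rural_shortage_vs_rural_nonshortage"`,
#'   `"urban_shortage_vs_urban_nonshortage"`, `"rural_vs_urban_shortage"`,
#'   `"rural_vs_metro_shortage"`.
#' @param unit passed to [contrast_design()].
#' @return a `contrast_design`.
#' @export
named_contrast <- function(name, unit = "county_period") {
  is_status <- function(s) function(d) {
    !is.na(d$shortage_status) & d$shortage_status == s
  }
  in_stratum <- function(s, u) function(d) {
    !is.na(d$shortage_status) & d$shortage_status == s &
      !is.na(d$urban3) & d$urban3 == u
  }
  metro_shortage <- function(d) {
    !is.na(d$shortage_status) & d$shortage_status == "shortage" &
      d$is_large_central_metro
  }
  switch(name,
    shortage_vs_nonshortage = contrast_design(
      name, is_status("shortage"), is_status("nonshortage"),
      "shortage", "nonshortage", unit = unit),
    rural_shortage_vs_rural_nonshortage = contrast_design(
      name, in_stratum("shortage", "rural"), in_stratum("nonshortage", "rural"),
      "rural shortage", "rural nonshortage", unit = unit),
    urban_shortage_vs_urban_nonshortage = contrast_design(
      name, in_stratum("shortage", "micropolitan"),
      in_stratum("nonshortage", "micropolitan"),
      "urban shortage", "urban nonshortage", unit = unit),
    rural_vs_urban_shortage = contrast_design(
      name, in_stratum("shortage", "rural"),
      in_stratum("shortage", "micropolitan"),
      "rural shortage", "urban shortage", unit = unit),
    rural_vs_metro_shortage = contrast_design(
      name, in_stratum("shortage", "rural"), metro_shortage,
      "rural shortage", "metro shortage", unit = unit),
    stop("unknown contrast name: ", name)
  )
}

# resolve a design against a designation table; errors name the offending
# predicate so pipeline failures are attributable
resolve_groups <- function(design, designations) {
  d <- as.data.frame(designations)
  excl <- design$exclude(d)
  a <- design$group_a(d) & !excl
  b <- design$group_b(d) & !excl
  if (any(a & b)) stop("group predicates are not disjoint in contrast '",
                       design$name, "'")
  if (!any(a)) stop("empty group A (", design$label_a, ") in contrast '",
                    design$name, "'")
  if (!any(b)) stop("empty group B (", design$label_b, ") in contrast '",
                    design$name, "'")
  list(fips_a = d$county_fips[a], fips_b = d$county_fips[b])
}

# unit observations for one symptom-level value column
unit_observations <- function(dt, valcol, fips, unit) {
  sub <- dt[county_fips %in% fips & !is.na(get(valcol))]
  if (unit == "county_mean") {
    sub <- sub[, .(value = mean(get(valcol))), by = county_fips]
    sub$value
  } else {
    sub[[valcol]]
  }
}

build_comparison <- function(obs_list, label_a, label_b, variant, fdr_method,
                             alpha) {
  rows <- lapply(obs_list, function(o) {
    tt <- two_group_ttest(o$a, o$b, variant = variant)
    data.table(
      symptom_id = o$id,
      mean_a = mean(o$a), sd_a = sd(o$a),
      mean_b = mean(o$b), sd_b = sd(o$b),
      n_a = length(o$a), n_b = length(o$b),
      t_stat = tt$t, df = tt$df, p_value = tt$p
    )
  })
  out <- rbindlist(rows)
  out[, q_value := bh_fdr(p_value, method = fdr_method)]
  out[, direction := ifelse(mean_a > mean_b, label_a,
                            ifelse(mean_b > mean_a, label_b, "tie"))]
  out[]
}

#' Two-group comparison table for one contrast family
#'
#' For each requested symptom, and for the composite set share as an
#' `"overall"` row, compares the two county groups' unit observations with a
#' two-tailed t test, then adjusts the whole family's p values to Q values
#' by Benjamini-Hochberg. The family is this one table: Q values are
#' comparable only within it.
#'
#' @param shares `share_table` from [share_of_search()].
#' @param set_series `set_share_series` for the composite row (e.g. the
#'   mental-health set share), or `NULL` to omit the overall row.
#' @param design a [contrast_design()].
#' @param designations a `county_designation`.
#' @param symptoms character vector of symptom ids to test (default: all in
#'   the share table's registry).
#' @param variant t-test variant, `"welch"` (default) or `"pooled"`.
#' @param fdr_method `"BH"` (default) or `"BY"`.
#' @param alpha family significance level (metadata; default 0.05).
#' @return `comparison_table`: data.table with one row per symptom plus
#'   `"overall"`, columns `symptom_id`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `n_a`, `n_b`, `t_stat`, `df`, `p_value`, `q_value`, `direction`;
#'   design metadata in attributes.
#' @export
compare_groups <- function(shares, set_series, design, designations,
                           symptoms = NULL, variant = c("welch", "pooled"),
                           fdr_method = c("BH", "BY"), alpha = 0.05) {
  variant <- match.arg(variant)
  fdr_method <- match.arg(fdr_method)
  stopifnot(inherits(design, "contrast_design"))
  g <- resolve_groups(design, designations)
  dt <- as.data.table(shares)
  # designations may list counties the provider suppressed entirely; only
  # counties observed in the panel belong to a contrast group
  observed <- unique(dt$county_fips)
  g$fips_a <- intersect(g$fips_a, observed)
  g$fips_b <- intersect(g$fips_b, observed)
  if (!length(g$fips_a)) stop("empty group A (", design$label_a,
                              ") after suppression in contrast '",
                              design$name, "'")
  if (!length(g$fips_b)) stop("empty group B (", design$label_b,
                              ") after suppression in contrast '",
                              design$name, "'")
  if (is.null(symptoms)) {
    reg <- attr(shares, "registry")
    symptoms <- if (!is.null(reg)) reg$symptom_id else
      sort(unique(dt$symptom_id))
  }
  obs <- list()
  if (!is.null(set_series)) {
    ss <- as.data.table(set_series)
    obs[["overall"]] <- list(
      id = "overall",
      a = unit_observations(ss, "set_share", g$fips_a, design$unit),
      b = unit_observations(ss, "set_share", g$fips_b, design$unit))
  }
  for (s in symptoms) {
    sub <- dt[symptom_id == s]
    obs[[s]] <- list(
      id = s,
      a = unit_observations(sub, "share", g$fips_a, design$unit),
      b = unit_observations(sub, "share", g$fips_b, design$unit))
  }
  out <- build_comparison(obs, design$label_a, design$label_b, variant,
                          fdr_method, alpha)
  setattr(out, "design", design$name)
  setattr(out, "labels", c(design$label_a, design$label_b))
  setattr(out, "unit", design$unit)
  setattr(out, "n_a", length(g$fips_a))
  setattr(out, "n_b", length(g$fips_b))
  setattr(out, "fdr_method", fdr_method)
  setattr(out, "alpha", alpha)
  setattr(out, "class", c("comparison_table", class(out)))
  out
}

#' Pre/post temporal contrast
#'
#' Within a selected set of counties, splits biweekly periods at a cutoff
#' date (period start `< cutoff` is "pre", `>= cutoff` is "post") and runs
#' the same per-symptom t test + family FDR machinery on pre vs post unit
#' observations. The conventional cutoff is 2020-03-11, the WHO pandemic
#' declaration, but any date inside the span is accepted.
#'
#' @param shares `share_table`.
#' @param set_series `set_share_series` for the overall row, or `NULL`.
#' @param counties predicate over the designation table, or a character
#'   vector of FIPS codes, selecting the counties analysed.
#' @param designations `county_designation` (needed when `counties` is a
#'   predicate).
#' @param cutoff `Date` splitting the span; each side must contain at least
#'   2 periods.
#' @param symptoms,variant,fdr_method,alpha as in [compare_groups()].
#' @return `comparison_table`; group A is pre, group B is post.
#' @export
temporal_contrast <- function(shares, set_series, counties = NULL,
                              designations = NULL, cutoff,
                              symptoms = NULL,
                              variant = c("welch", "pooled"),
                              fdr_method = c("BH", "BY"), alpha = 0.05) {
  variant <- match.arg(variant)
  fdr_method <- match.arg(fdr_method)
  cutoff <- as.Date(cutoff)
  dt <- as.data.table(shares)
  periods <- sort(unique(dt$period_start))
  n_pre <- sum(periods < cutoff)
  n_post <- sum(periods >= cutoff)
  if (n_pre < 2L || n_post < 2L) {
    stop("cutoff must leave at least 2 biweekly periods on each side ",
         "(got ", n_pre, " pre, ", n_post, " post)")
  }
  fips <- if (is.null(counties)) {
    unique(dt$county_fips)
  } else if (is.function(counties)) {
    if (is.null(designations)) stop("predicate selection needs designations")
    d <- as.data.frame(designations)
    d$county_fips[counties(d)]
  } else {
    pad_fips(counties)
  }
  if (is.null(symptoms)) {
    reg <- attr(shares, "registry")
    symptoms <- if (!is.null(reg)) reg$symptom_id else
      sort(unique(dt$symptom_id))
  }
  split_obs <- function(sub, valcol) {
    sub <- sub[county_fips %in% fips & !is.na(get(valcol))]
    list(a = sub[period_start < cutoff][[valcol]],
         b = sub[period_start >= cutoff][[valcol]])
  }
  obs <- list()
  if (!is.null(set_series)) {
    sp <- split_obs(as.data.table(set_series), "set_share")
    obs[["overall"]] <- list(id = "overall", a = sp$a, b = sp$b)
  }
  for (s in symptoms) {
    sp <- split_obs(dt[symptom_id == s], "share")
    obs[[s]] <- list(id = s, a = sp$a, b = sp$b)
  }
  out <- build_comparison(obs, "pre", "post", variant, fdr_method, alpha)
  setattr(out, "design", "pre_vs_post")
  setattr(out, "labels", c("pre", "post"))
  setattr(out, "unit", "county_period")
  setattr(out, "cutoff", cutoff)
  setattr(out, "n_pre_periods", n_pre)
  setattr(out, "n_post_periods", n_post)
  setattr(out, "fdr_method", fdr_method)
  setattr(out, "alpha", alpha)
  setattr(out, "class", c("comparison_table", class(out)))
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %s (%s vs %s), unit = %s, FDR = %s\n",
              attr(x, "design"), attr(x, "labels")[1], attr(x, "labels")[2],
              attr(x, "unit"), attr(x, "fdr_method")))
  print(as.data.table(as.data.frame(x)))
  invisible(x)
}

#' Rank counties by span-mean composite share
#'
#' Top-k and bottom-k counties by their mean set share over the full span.
#' All counties appear here, including partially designated shortage
#' counties (rankings are descriptive; only two-group contrasts exclude
#' them). Ties are broken by ascending FIPS code.
#'
#' @param set_series `set_share_series`.
#' @param designations `county_designation` (for the status column; counties
#'   absent from it get `NA`).
#' @param k list length (>= 1); truncated with a warning if it exceeds the
#'   county count.
#' @return list with data.tables `top` and `bottom` (columns `rank`,
#'   `county_fips`, `mean_share`, `shortage_status`).
#' @export
rank_counties <- function(set_series, designations, k) {
  stopifnot(k >= 1)
  means <- as.data.table(set_series)[!is.na(set_share),
                                     .(mean_share = mean(set_share)),
                                     by = county_fips]
  des <- as.data.table(designations)[, .(county_fips, shortage_status)]
  means <- merge(means, des, by = "county_fips", all.x = TRUE)
  if (k > nrow(means)) {
    warning("k = ", k, " exceeds county count ", nrow(means),
            "; lists truncated")
    k <- nrow(means)
  }
  setorder(means, -mean_share, county_fips)
  top <- means[seq_len(k)]
  top[, rank := .I]
  setorder(means, mean_share, county_fips)
  bottom <- means[seq_len(k)]
  bottom[, rank := .I]
  cols <- c("rank", "county_fips", "mean_share", "shortage_status")
  list(top = top[, cols, with = FALSE], bottom = bottom[, cols, with = FALSE])
}

#' Per-period group means with confidence bands
#'
#' For each period and county group: mean across counties, standard error
#' and symmetric normal-approximation confidence interval — the tidy input
#' for group time-series plots. Single-county groups get `NA` bands (no
#' spread to estimate).
#'
#' @param x `set_share_series` (or `share_table` filtered to one symptom).
#' @param groups named list of predicates over the designation table.
#' @param designations `county_designation`.
#' @param ci_level confidence level (default 0.95).
#' @return data.table with `group`, `period_start`, `n`, `mean`, `se`,
#'   `lo`, `hi`.
#' @export
group_time_series <- function(x, groups, designations, ci_level = 0.95) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  dt <- as.data.table(x)
  valcol <- if ("set_share" %in% names(dt)) "set_share" else "share"
  d <- as.data.frame(designations)
  z <- qnorm(1 - (1 - ci_level) / 2)
  rows <- lapply(names(groups), function(gname) {
    fips <- d$county_fips[groups[[gname]](d)]
    if (!length(fips)) stop("group '", gname, "' selects no counties")
    sub <- dt[county_fips %in% fips & !is.na(get(valcol))]
    agg <- sub[, .(n = .N, mean = mean(get(valcol)),
                   se = if (.N >= 2L) sd(get(valcol)) / sqrt(.N) else
                     NA_real_),
               by = period_start]
    agg[, `:=`(group = gname, lo = mean - z * se, hi = mean + z * se)]
    agg
  })
  out <- rbindlist(rows)
  setorder(out, group, period_start)
  out[, .(group, period_start, n, mean, se, lo, hi)]
}
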