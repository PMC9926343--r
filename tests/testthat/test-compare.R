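# noise-free simulated world with one planted deficit, used across blocks
planted_world <- function(mult = 0.8, n_counties = 12, n_periods = 4,
                          noise = list(lognormal_sd = 0, laplace_b = 0),
                          fraction_partial = 0, temporal_step = NULL) {
  cfg <- simulation_config(
    n_counties = n_counties, n_periods = n_periods,
    symptoms = data.frame(symptom_id = c("a", "b", "c"),
                          class = c("broad", "specific", "non_mh"),
                          lambda = c(2, 3, 5)),
    fraction_shortage = 0.5, fraction_partial = fraction_partial,
    fraction_rural = 0, fraction_micropolitan = 0,
    effect_multipliers = if (is.na(mult)) NULL else
      data.frame(status = "shortage", urban3 = NA, symptom_id = "a",
                 class = NA, multiplier = mult),
    temporal_step = temporal_step,
    noise = noise
  )
  sim <- generate_panel(cfg)
  sh <- share_of_search(sim$panel)
  ss <- set_share(sh, c("a", "b"))
  c(sim, list(shares = sh, set_series = ss))
}

test_that("planted deficit is recovered exactly with noise off, q < .05", {
  w <- planted_world(0.8)
  tab <- compare_groups(w$shares, w$set_series,
                        named_contrast("shortage_vs_nonshortage"),
                        w$designations)
  tab <- as.data.frame(tab)
  row_a <- tab[tab$symptom_id == "a", ]
  truth_diff <- true_contrast_diff(w$truth, "a", list(status = "shortage"),
                                   list(status = "nonshortage"))
  expect_equal(row_a$mean_a - row_a$mean_b, truth_diff)
  expect_lt(row_a$q_value, 0.05)
  expect_equal(row_a$direction, "nonshortage")  # deficit in shortage group
  # direction fidelity for every row with a nonzero true difference
  for (s in c("a", "b", "c")) {
    td <- true_contrast_diff(w$truth, s, list(status = "shortage"),
                             list(status = "nonshortage"))
    obs <- tab[tab$symptom_id == s, ]
    expect_equal(sign(obs$mean_a - obs$mean_b), sign(td))
  }
  # q >= p under BH, always
  expect_true(all(tab$q_value >= tab$p_value - 1e-15))
})

test_that("comparison table shape: one requested symptom plus overall", {
  w <- planted_world(0.8)
  tab <- compare_groups(w$shares, w$set_series,
                        named_contrast("shortage_vs_nonshortage"),
                        w$designations, symptoms = "a")
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$symptom_id, c("overall", "a"))
  no_overall <- compare_groups(w$shares, NULL,
                               named_contrast("shortage_vs_nonshortage"),
                               w$designations, symptoms = "a")
  expect_equal(nrow(no_overall), 1L)
})

test_that("empty groups error naming the predicate's label", {
  w <- planted_world(0.8)
  d <- named_contrast("rural_shortage_vs_rural_nonshortage")
  expect_error(compare_groups(w$shares, w$set_series, d, w$designations),
               "empty group A \\(rural shortage\\)")
  overlapping <- contrast_design(
    "bad", function(d) rep(TRUE, nrow(d)), function(d) rep(TRUE, nrow(d)))
  expect_error(compare_groups(w$shares, w$set_series, overlapping,
                              w$designations), "not disjoint")
})

test_that("partial-shortage counties are excluded from contrasts only", {
  w <- planted_world(0.8, n_counties = 20, fraction_partial = 0.2)
  d <- as.data.frame(w$designations)
  n_partial <- sum(d$shortage_status == "partial")
  expect_gt(n_partial, 0)
  tab <- compare_groups(w$shares, w$set_series,
                        named_contrast("shortage_vs_nonshortage"),
                        w$designations)
  expect_equal(attr(tab, "n_a") + attr(tab, "n_b"), 20 - n_partial)
  # but rankings include them
  rk <- rank_counties(w$set_series, w$designations, k = 20)
  expect_true(any(rk$top$shortage_status == "partial"))
})

test_that("county-mean unit gives one observation per county", {
  w <- planted_world(0.8)
  tab <- compare_groups(w$shares, w$set_series,
                        named_contrast("shortage_vs_nonshortage",
                                       unit = "county_mean"),
                        w$designations, symptoms = "a")
  expect_equal(tab$n_a[1], attr(tab, "n_a"))
  tab_cp <- compare_groups(w$shares, w$set_series,
                           named_contrast("shortage_vs_nonshortage"),
                           w$designations, symptoms = "a")
  expect_equal(tab_cp$n_a[1], attr(tab_cp, "n_a") * 4L)  # 4 periods
})

test_that("temporal step is flagged with the correct direction", {
  w <- planted_world(NA, n_counties = 10, n_periods = 8,
                     noise = list(lognormal_sd = 0.05, laplace_b = 0),
                     temporal_step = list(cutoff_period = 5,
                                          multipliers = c(a = 1.5)))
  cutoff <- as.Date("2019-01-02") + 14 * 4
  tab <- temporal_contrast(w$shares, w$set_series, cutoff = cutoff)
  tab <- as.data.frame(tab)
  row_a <- tab[tab$symptom_id == "a", ]
  expect_lt(row_a$q_value, 0.05)
  expect_equal(row_a$direction, "post")
  expect_gt(row_a$mean_b, row_a$mean_a)
  # noise-off world: post-pre equals the analytic step-induced share change
  w0 <- planted_world(NA, n_counties = 6, n_periods = 8,
                      temporal_step = list(cutoff_period = 5,
                                           multipliers = c(a = 1.5)))
  t0 <- temporal_contrast(w0$shares, w0$set_series, cutoff = cutoff)
  t0 <- as.data.frame(t0)
  expected <- true_mean_share(w0$truth, "a", regime = "post") -
    true_mean_share(w0$truth, "a", regime = "pre")
  expect_equal(t0[t0$symptom_id == "a", "mean_b"] -
                 t0[t0$symptom_id == "a", "mean_a"], expected)
})

test_that("temporal contrast rejects cutoffs outside the span", {
  w <- planted_world(NA, n_periods = 6)
  expect_error(temporal_contrast(w$shares, w$set_series,
                                 cutoff = as.Date("2015-01-01")),
               "at least 2 biweekly periods")
  expect_error(temporal_contrast(w$shares, w$set_series,
                                 cutoff = as.Date("2025-01-01")),
               "at least 2 biweekly periods")
})

test_that("county rankings order, tie-break and truncate as stated", {
  ss <- data.table::data.table(
    county_fips = rep(c("00003", "00001", "00002"), each = 2),
    period_start = rep(as.Date("2020-01-01") + c(0, 14), 3),
    set_share = c(30, 30, 10, 10, 20, 20)
  )
  des <- county_designation(data.frame(
    county_fips = c("00001", "00002", "00003"),
    shortage_status = c("shortage", "partial", "nonshortage"),
    nchs6 = c(6, 5, 1)
  ))
  rk <- rank_counties(ss, des, k = 1)
  expect_equal(rk$top$county_fips, "00003")
  expect_equal(rk$top$mean_share, 30)
  expect_equal(rk$bottom$county_fips, "00001")

  # tie: lower FIPS first
  ss2 <- data.table::copy(ss)
  ss2$set_share <- c(20, 20, 20, 20, 10, 10)
  rk2 <- rank_counties(ss2, des, k = 2)
  expect_equal(rk2$top$county_fips, c("00001", "00003"))

  expect_warning(rk3 <- rank_counties(ss, des, k = 9), "truncated")
  expect_equal(nrow(rk3$top), 3L)
})

test_that("group time series: flat series, CI width, and step-down slope", {
  w <- planted_world(NA, n_counties = 6, n_periods = 6)
  groups <- list(
    shortage = function(d) d$shortage_status == "shortage",
    nonshortage = function(d) d$shortage_status == "nonshortage"
  )
  ts <- group_time_series(w$set_series, groups, w$designations)
  # noise off: constant in time, equal across groups (null world)
  expect_equal(length(unique(round(ts$mean, 9))), 1L)
  expect_true(all(ts$n == 3))

  # single-county group: no spread to estimate, bands reported missing
  one <- list(single = function(d) d$county_fips == d$county_fips[1])
  ts1 <- group_time_series(w$set_series, one, w$designations)
  expect_true(all(is.na(ts1$se)))

  # planted downward step: fitted slope of group means is negative
  wd <- planted_world(NA, n_counties = 8, n_periods = 8,
                      noise = list(lognormal_sd = 0.02, laplace_b = 0),
                      temporal_step = list(cutoff_period = 4,
                                           multipliers = c(a = 0.5)))
  tsa <- group_time_series(set_share(wd$shares, "a"), groups,
                           wd$designations)
  sub <- tsa[tsa$group == "shortage", ]
  slope <- stats::coef(stats::lm(mean ~ as.numeric(period_start),
                                 data = sub))[2]
  expect_lt(slope, 0)
})
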