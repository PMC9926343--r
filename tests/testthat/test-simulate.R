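three_symptom_config <- function(mult = 0.8, ...) {
  simulation_config(
    n_counties = 10, n_periods = 2,
    symptoms = data.frame(symptom_id = c("a", "b", "c"),
                          class = c("broad", "non_mh", "non_mh"),
                          lambda = c(2, 3, 5)),
    fraction_shortage = 0.5, fraction_partial = 0,
    fraction_rural = 0, fraction_micropolitan = 0,
    effect_multipliers = data.frame(status = "shortage", urban3 = NA,
                                    symptom_id = "a", class = NA,
                                    multiplier = mult),
    noise = list(lognormal_sd = 0, laplace_b = 0),
    ...
  )
}

test_that("null config with all randomness off reproduces lambda exactly", {
  cfg <- simulation_config(
    n_counties = 4, n_periods = 3,
    symptoms = data.frame(symptom_id = c("a", "b"), class = "non_mh",
                          lambda = c(2, 7)),
    region_scale_range = c(1, 1),
    noise = list(lognormal_sd = 0, laplace_b = 0)
  )
  sim <- generate_panel(cfg)
  w <- sim$panel
  expect_equal(unique(w$weight[w$symptom_id == "a"]), 2)
  expect_equal(unique(w$weight[w$symptom_id == "b"]), 7)
})

test_that("planted multiplier yields the hand-computed share difference exactly", {
  sim <- generate_panel(three_symptom_config(0.8))
  # independent arithmetic: shortage weights (1.6, 3, 5), nonshortage (2, 3, 5)
  expected_diff <- 100 * (1.6 / 9.6 - 2 / 10)
  sh <- share_of_search(sim$panel)
  ss <- set_share(sh, "a")
  d <- as.data.frame(sim$designations)
  emp <- function(st) {
    mean(ss$set_share[ss$county_fips %in%
                        d$county_fips[d$shortage_status == st]])
  }
  expect_equal(emp("shortage") - emp("nonshortage"), expected_diff)
  expect_equal(
    true_contrast_diff(sim$truth, "a", list(status = "shortage"),
                       list(status = "nonshortage")),
    expected_diff
  )
})

test_that("null ground truth is exactly zero and matches noise-off data", {
  sim <- generate_panel(three_symptom_config(1))
  expect_equal(
    true_contrast_diff(sim$truth, c("a", "b"), list(status = "shortage"),
                       list(status = "nonshortage")),
    0
  )
})

test_that("generation is deterministic and county substreams are stable", {
  cfg <- simulation_config(n_counties = 8, n_periods = 3, seed = 42)
  p1 <- generate_panel(cfg)$panel
  p2 <- generate_panel(cfg)$panel
  expect_identical(as.data.frame(p1), as.data.frame(p2))

  # enlarging the panel must not perturb existing counties' draws
  cfg_big <- simulation_config(n_counties = 12, n_periods = 3, seed = 42)
  p3 <- generate_panel(cfg_big)$panel
  first8 <- as.data.frame(p3)[p3$county_fips %in% unique(p1$county_fips), ]
  expect_equal(first8, as.data.frame(p1), ignore_attr = TRUE)
})

test_that("scale confounding is invisible to shares (central invariance)", {
  cfg <- simulation_config(n_counties = 10, n_periods = 3,
                           region_scale_range = c(0.1, 10), seed = 3)
  sim <- generate_panel(cfg)
  sh1 <- share_of_search(sim$panel)
  # rescale each county by an arbitrary positive constant
  k <- stats::setNames(stats::runif(10, 0.01, 100),
                       unique(sim$panel$county_fips))
  p2 <- as.data.frame(sim$panel)
  p2$weight <- p2$weight * k[p2$county_fips]
  sh2 <- share_of_search(symptom_panel(p2))
  expect_lt(max(abs(sh1$share - sh2$share), na.rm = TRUE), 1e-9)
})

test_that("suppression removes whole counties and thresholds cells", {
  cfg <- simulation_config(
    n_counties = 10, n_periods = 2,
    suppression = list(n_suppressed_counties = 3, cell_threshold = 0.05),
    seed = 5
  )
  sim <- generate_panel(cfg)
  expect_equal(data.table::uniqueN(sim$panel$county_fips), 7L)
  expect_equal(nrow(sim$designations), 10L)  # designations keep all counties
  prov <- panel_provenance(sim$panel, sim$designations$county_fips)
  expect_equal(length(prov$suppressed_counties), 3L)
  expect_setequal(prov$suppressed_counties,
                  sim$truth$assignments$county_fips[
                    sim$truth$assignments$suppressed])
  # thresholded cells are missing, not zero; survivors are >= threshold
  expect_true(all(sim$panel$weight >= 0.05 | is.na(sim$panel$weight)))
  expect_gt(sum(is.na(sim$panel$weight)), 0L)
})

test_that("config invariants are enforced before any sampling", {
  expect_error(simulation_config(1, 3), "n_counties")
  expect_error(simulation_config(
    10, 3, symptoms = data.frame(symptom_id = "a", class = "broad",
                                 lambda = -1)), "lambda")
  expect_error(simulation_config(10, 3, fraction_shortage = 0.8,
                                 fraction_partial = 0.5), "exceeds 1")
  expect_error(simulation_config(
    10, 3, effect_multipliers = data.frame(status = "shortage", urban3 = NA,
                                           symptom_id = "anxiety",
                                           class = NA, multiplier = 0)),
    "positive")
  expect_error(simulation_config(
    10, 3, suppression = list(n_suppressed_counties = 10,
                              cell_threshold = 0)), "n_suppressed")
  expect_error(simulation_config(
    10, 3, temporal_step = list(cutoff_period = 9, multipliers = c(a = 2))),
    "cutoff_period|unknown symptom")
})

test_that("coder label generator honours its agreement contract", {
  same <- generate_coder_labels(50, 0.3, 0, seed = 1)
  expect_identical(same$a, same$b)

  opp <- generate_coder_labels(50, 1, 1, seed = 1)
  expect_true(all(opp$a == 1L) && all(opp$b == 0L))
  expect_equal(mean(opp$a == opp$b), 0)

  # binomial oracle: observed agreement within 3 SE of 1 - p_disagree
  big <- generate_coder_labels(10000, 0.1, 0.02, seed = 99)
  se <- sqrt(0.98 * 0.02 / 10000)
  expect_lt(abs(mean(big$a == big$b) - 0.98), 3 * se)

  expect_error(generate_coder_labels(0, 0.5, 0.5), "n_items")
})

test_that("affiliation generator covers degenerate and reproducible cases", {
  ids <- paste0("s", 1:6)
  expect_equal(nrow(generate_affiliation_table(ids, ids[1:2], 0)), 0L)

  full <- generate_affiliation_table(ids, ids[1:2], 1,
                                     relevance_range = c(5, 5))
  expect_equal(nrow(full), 2 * (6 - 1))
  expect_true(all(full$relevance == 5))

  t1 <- generate_affiliation_table(ids, ids[1:3], 0.5, seed = 7)
  t2 <- generate_affiliation_table(ids, ids[1:3], 0.5, seed = 7)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  expect_error(generate_affiliation_table(character(0), character(0), 0.5),
               "empty")
})
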