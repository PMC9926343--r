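#' Plant exact true share targets for a stratum
#'
#' Appends multiplier rows to a configuration so that, in the selected
#' stratum, the true shares of the targeted symptoms equal the requested
#' percentages exactly. Closed form: untargeted symptoms keep their current
#' effect, so their propensity mass `L0 = sum(lambda * e)` is fixed and the
#' targeted denominator must be `D = 100 * L0 / (100 - sum(targets))`; each
#' targeted symptom then needs total propensity `target * D / 100`, i.e. an
#' extra multiplier `target * D / (100 * lambda * e_current)`.
#'
#' Because effects are multiplicative, targets planted for a broad stratum
#' (e.g. all shortage counties) and then refined for a narrower one (e.g.
#' rural shortage) compose: the narrower call solves on top of the broader
#' effect already in place.
#'
#' @param config a [simulation_config()].
#' @param targets named numeric vector: symptom id -> true share (percent);
#'   must sum to < 100.
#' @param status,urban3 stratum selector (either may be `NA` for "any").
#' @return the configuration with multiplier rows appended.
#' @export
plant_share_targets <- function(config, targets, status = NA,
                                urban3 = NA) {
  stopifnot(inherits(config, "simulation_config"))
  sym <- config$symptoms
  ids <- names(targets)
  if (is.null(ids) || !all(ids %in% sym$symptom_id)) {
    stop("targets must be named by symptom ids present in the config")
  }
  if (sum(targets) >= 100) stop("targets must sum to less than 100")
  # current effects in the selected stratum (representative cell: wildcards
  # resolved to concrete values only for lookup)
  st <- if (is.na(status)) "shortage" else status
  ur <- if (is.na(urban3)) "rural" else urban3
  e_cur <- stratum_effects(config, st, ur)
  names(e_cur) <- sym$symptom_id
  tgt <- sym$symptom_id %in% ids
  L0 <- sum(sym$lambda[!tgt] * e_cur[!tgt])
  D <- 100 * L0 / (100 - sum(targets))
  mult <- (targets * D) / (100 * sym$lambda[match(ids, sym$symptom_id)] *
                             e_cur[ids])
  if (any(mult <= 0) || any(!is.finite(mult))) {
    stop("derived multipliers are not positive finite; check targets")
  }
  rows <- data.frame(status = status, urban3 = urban3, symptom_id = ids,
                     class = NA_character_, multiplier = unname(mult),
                     stringsAsFactors = FALSE)
  config$effect_multipliers <- rbind(config$effect_multipliers, rows)
  config
}

#' Reference disparity configuration
#'
#' A stated-world demonstration configuration whose *true* shares echo the
#' disparity magnitudes observed in US county search panels: the
#' mental-health composite is 13.42% of all symptom searching in shortage
#' counties vs 15.06% in nonshortage counties; anxiety is elevated in
#' shortage counties (2.03% vs 1.80%) while specific clinical topics are
#' depressed there; and within rural counties the gap widens (12.44% vs
#' 14.71% composite) with suicidal-ideation searching especially depressed
#' in rural shortage counties (0.024% vs 0.088%). Planted exactly via
#' [plant_share_targets()]; the base (metro/micropolitan nonshortage)
#' profile is [default_symptom_table()].
#'
#' @param n_counties,n_periods,seed panel dimensions and seed.
#' @param noise noise settings (moderate by default).
#' @return a [simulation_config()].
#' @export
config_disparity_demo <- function(n_counties = 120, n_periods = 10,
                                  seed = 1L,
                                  noise = list(lognormal_sd = 0.2,
                                               laplace_b = 0.005)) {
  cfg <- simulation_config(
    n_counties = n_counties, n_periods = n_periods,
    fraction_shortage = 0.45, fraction_partial = 0.10,
    fraction_rural = 0.35, fraction_micropolitan = 0.30,
    noise = noise, seed = seed
  )
  shortage_targets <- c(
    anxiety = 2.03, depression = 1.15, fatigue = 1.21, headache = 1.03,
    alcoholism = 0.93, adhd = 0.73, binge_eating = 0.02,
    compulsive_behavior = 0.07, dysphoria = 0.01,
    generalized_anxiety_disorder = 0.18, hypochondriasis = 0.008,
    hypomania = 0.009, major_depressive_disorder = 1.01,
    manic_disorder = 0.08, mood_disorder = 0.17, psychosis = 0.30,
    suicidal_ideation = 0.05
  )
  # bucket absorbs the remainder of the 13.42% shortage composite
  shortage_targets <- c(shortage_targets,
                        other_mental_health = 13.42 - sum(shortage_targets))
  cfg <- plant_share_targets(cfg, shortage_targets, status = "shortage")

  rural_shortage <- c(
    anxiety = 2.24, depression = 1.19, fatigue = 1.28, headache = 1.05,
    alcoholism = 0.93, adhd = 0.68, binge_eating = 0.013,
    compulsive_behavior = 0.033, dysphoria = 0.009,
    generalized_anxiety_disorder = 0.119, hypochondriasis = 0.008,
    hypomania = 0.008, major_depressive_disorder = 1.05,
    manic_disorder = 0.040, mood_disorder = 0.117, psychosis = 0.241,
    suicidal_ideation = 0.024
  )
  rural_shortage <- c(rural_shortage,
                      other_mental_health = 12.44 - sum(rural_shortage))
  cfg <- plant_share_targets(cfg, rural_shortage, status = "shortage",
                             urban3 = "rural")

  rural_nonshortage <- c(
    anxiety = 1.87, depression = 1.12, fatigue = 1.06, headache = 0.95,
    alcoholism = 1.18, adhd = 0.80, binge_eating = 0.019,
    compulsive_behavior = 0.121, dysphoria = 0.021,
    generalized_anxiety_disorder = 0.25, hypochondriasis = 0.003,
    hypomania = 0.02, major_depressive_disorder = 0.95,
    manic_disorder = 0.13, mood_disorder = 0.255, psychosis = 0.383,
    suicidal_ideation = 0.088
  )
  rural_nonshortage <- c(rural_nonshortage,
                         other_mental_health = 14.71 - sum(rural_nonshortage))
  cfg <- plant_share_targets(cfg, rural_nonshortage, status = "nonshortage",
                             urban3 = "rural")
  cfg
}

#' Power-demo configuration: a planted composite deficit
#'
#' Plants a uniform proportional deficit on every mental-health symptom in
#' shortage counties so the true mental-health composite share is lower
#' there by `deficit_pp` percentage points than the nonshortage value
#' (15.06%), under moderate log-normal and additive noise and strong
#' per-county scale confounding.
#'
#' @param deficit_pp composite deficit in percentage points (default 0.3).
#' @param n_counties,n_periods,seed panel dimensions and seed.
#' @return a [simulation_config()].
#' @export
config_planted_deficit <- function(deficit_pp = 0.3, n_counties = 400,
                                   n_periods = 26, seed = 1L) {
  cfg <- simulation_config(
    n_counties = n_counties, n_periods = n_periods,
    fraction_shortage = 0.45, fraction_partial = 0.10,
    noise = list(lognormal_sd = 0.2, laplace_b = 0.01), seed = seed
  )
  sym <- cfg$symptoms
  mh <- sym$class != "non_mh"
  base_comp <- sum(sym$lambda[mh])  # 15.06 by construction
  scale <- (base_comp - deficit_pp) / base_comp
  targets <- setNames(sym$lambda[mh] * scale, sym$symptom_id[mh])
  plant_share_targets(cfg, targets, status = "shortage")
}

#' Null configuration (no planted effects)
#'
#' Noise, per-county scale confounding and stratification are on; every
#' effect multiplier is 1, so all true contrast differences are exactly 0.
#'
#' @param n_counties,n_periods,seed panel dimensions and seed.
#' @param lognormal_sd,laplace_b noise magnitudes.
#' @return a [simulation_config()].
#' @export
config_null <- function(n_counties = 60, n_periods = 6, seed = 1L,
                        lognormal_sd = 0.2, laplace_b = 0.01) {
  simulation_config(
    n_counties = n_counties, n_periods = n_periods,
    fraction_shortage = 0.5, fraction_partial = 0,
    noise = list(lognormal_sd = lognormal_sd, laplace_b = laplace_b),
    seed = seed
  )
}
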