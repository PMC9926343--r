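#' Default symptom table for simulation
#'
#' A desk-scale registry standing in for the provider's 422-topic catalogue:
#' 17 named mental-health topics (4 broad/somatic, 13 specific conditions),
#' one `other_mental_health` bucket absorbing the rest of the mental-health
#' composite, and 5 high-volume non-mental-health topics. Base propensities
#' `lambda` are expressed directly on the share scale (they sum to 100), so a
#' null configuration has true nonshortage-like shares equal to `lambda`:
#' a 15.06% mental-health composite split as observed in large US
#' nonshortage county panels, with anxiety at 1.8%, suicidal ideation at
#' 0.10%, and five somatic/infectious bulk topics carrying the other 84.94%.
#'
#' @return data.frame with columns `symptom_id`, `class`
#'   (`broad`/`specific`/`non_mh`) and `lambda` (positive, summing to 100).
#' @export
default_symptom_table <- function() {
  mh <- data.frame(
    symptom_id = c("anxiety", "depression", "fatigue", "headache",
                   "alcoholism", "adhd", "binge_eating",
                   "compulsive_behavior", "dysphoria",
                   "generalized_anxiety_disorder", "hypochondriasis",
                   "hypomania", "major_depressive_disorder", "manic_disorder",
                   "mood_disorder", "psychosis", "suicidal_ideation"),
    class = c(rep("broad", 4L), rep("specific", 13L)),
    lambda = c(1.80, 1.08, 1.05, 0.95,
               0.97, 0.77, 0.05, 0.14, 0.03, 0.25, 0.017, 0.02, 0.92,
               0.13, 0.25, 0.37, 0.10),
    stringsAsFactors = FALSE
  )
  bucket <- data.frame(symptom_id = "other_mental_health", class = "broad",
                       lambda = 15.06 - sum(mh$lambda),
                       stringsAsFactors = FALSE)
  non_mh_total <- 100 - 15.06
  non <- data.frame(
    symptom_id = c("common_cold", "fever", "back_pain", "allergy", "rash"),
    class = "non_mh",
    lambda = non_mh_total * c(0.30, 0.25, 0.20, 0.15, 0.10),
    stringsAsFactors = FALSE
  )
  rbind(mh, bucket, non)
}

#' Mental-health symptom ids of a simulation symptom table
#' @param symptoms symptom table (as in [default_symptom_table()]).
#' @return character vector of ids with class `broad` or `specific`.
#' @export
mh_ids <- function(symptoms) {
  symptoms$symptom_id[symptoms$class != "non_mh"]
}

#' Simulation configuration
#'
#' Describes a synthetic county-by-period symptom search-weight panel with
#' known ground truth. The generative model for the weight of symptom `s` in
#' county `c` at period `t` is
#' \deqn{w(c,t,s) = \sigma(c)\,\lambda(s)\,e(\mathrm{stratum}(c),s)\,
#'   m(t,s)\,\exp(\epsilon) + L,}
#' where `sigma(c)` is an unknown per-county scale factor (the scaling
#' inconsistency of real anonymized panels), `lambda(s)` the base search
#' propensity, `e` a planted multiplicative stratum effect, `m(t,s)` a
#' per-symptom step multiplier switching on at a cutoff period,
#' `epsilon ~ N(0, lognormal_sd^2)` and `L ~ Laplace(0, laplace_b)`
#' mimicking differential-privacy noise. Cells whose pre-truncation value
#' falls below `cell_threshold` are suppressed (missing); otherwise weights
#' are truncated at 0. Whole counties may additionally be suppressed,
#' emulating the provider's withholding of sparsely populated counties.
#'
#' Effects are multiplicative, not additive, so planted group differences
#' survive the unknown scale factor exactly as real behavioural differences
#' would — shares are invariant to `sigma(c)`.
#'
#' @param n_counties,n_periods panel dimensions (periods are biweekly).
#' @param symptoms symptom table: `symptom_id`, `class`, `lambda > 0`.
#' @param fraction_shortage,fraction_partial county fractions by shortage
#'   designation; the remainder is nonshortage.
#' @param fraction_rural,fraction_micropolitan urbanization fractions within
#'   each shortage stratum; the remainder is (large central) metro. Rural
#'   counties get 6-tier code 6, micropolitan 5, metro 1.
#' @param effect_multipliers `NULL` (null model) or data.frame with columns
#'   `status`, `urban3`, `symptom_id`, `class`, `multiplier` (> 0). `NA` in a
#'   key column is a wildcard; a county-symptom effect is the product of all
#'   matching rows.
#' @param temporal_step `NULL` or `list(cutoff_period =` 1-based period index
#'   at which the step switches on, `multipliers =` named vector
#'   symptom -> factor`)`.
#' @param region_scale_range interval for the per-county scale
#'   `sigma(c) ~ U(lo, hi)`, `lo > 0`.
#' @param noise `list(lognormal_sd >= 0, laplace_b >= 0)`.
#' @param suppression `list(n_suppressed_counties, cell_threshold >= 0)`.
#' @param start_date `Date` of the first biweekly period.
#' @param seed integer master seed; per-county substreams are derived from it
#'   so that adding counties does not perturb existing ones.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_counties, n_periods,
                              symptoms = default_symptom_table(),
                              fraction_shortage = 0.45,
                              fraction_partial = 0.10,
                              fraction_rural = 0.35,
                              fraction_micropolitan = 0.30,
                              effect_multipliers = NULL,
                              temporal_step = NULL,
                              region_scale_range = c(0.5, 2),
                              noise = list(lognormal_sd = 0.2,
                                           laplace_b = 0.01),
                              suppression = list(n_suppressed_counties = 0L,
                                                 cell_threshold = 0),
                              start_date = as.Date("2019-01-02"),
                              seed = 1L) {
  stopifnot(n_counties >= 2, n_periods >= 1)
  symptoms <- as.data.frame(symptoms)
  if (!all(c("symptom_id", "class", "lambda") %in% names(symptoms))) {
    stop("symptoms needs columns (symptom_id, class, lambda)")
  }
  if (any(symptoms$lambda <= 0)) stop("all base propensities lambda must be > 0")
  if (anyDuplicated(symptoms$symptom_id)) stop("duplicate symptom ids")
  if (!all(symptoms$class %in% c("broad", "specific", "non_mh"))) {
    stop("symptom class must be broad, specific or non_mh")
  }
  fr <- c(fraction_shortage, fraction_partial, fraction_rural,
          fraction_micropolitan)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (fraction_shortage + fraction_partial > 1) {
    stop("fraction_shortage + fraction_partial exceeds 1")
  }
  if (fraction_rural + fraction_micropolitan > 1) {
    stop("fraction_rural + fraction_micropolitan exceeds 1")
  }
  if (!is.null(effect_multipliers)) {
    effect_multipliers <- as.data.frame(effect_multipliers)
    need <- c("status", "urban3", "symptom_id", "class", "multiplier")
    miss <- setdiff(need, names(effect_multipliers))
    for (m in miss) effect_multipliers[[m]] <- NA
    effect_multipliers <- effect_multipliers[, need]
    if (any(!is.finite(effect_multipliers$multiplier)) ||
        any(effect_multipliers$multiplier <= 0)) {
      stop("effect multipliers must be positive and finite")
    }
  }
  if (!is.null(temporal_step)) {
    if (is.null(temporal_step$cutoff_period) ||
        temporal_step$cutoff_period < 2 ||
        temporal_step$cutoff_period > n_periods) {
      stop("temporal_step$cutoff_period must lie in 2..n_periods")
    }
    if (any(temporal_step$multipliers <= 0)) {
      stop("temporal step multipliers must be > 0")
    }
    unknown <- setdiff(names(temporal_step$multipliers), symptoms$symptom_id)
    if (length(unknown)) stop("temporal step names unknown symptom(s)")
  }
  if (length(region_scale_range) != 2L || region_scale_range[1] <= 0 ||
      diff(region_scale_range) < 0) {
    stop("region_scale_range must be a positive interval (lo, hi)")
  }
  if (noise$lognormal_sd < 0 || noise$laplace_b < 0) {
    stop("noise magnitudes must be >= 0")
  }
  if (suppression$n_suppressed_counties >= n_counties) {
    stop("n_suppressed_counties must be < n_counties")
  }
  if (suppression$cell_threshold < 0) stop("cell_threshold must be >= 0")
  structure(list(
    n_counties = as.integer(n_counties), n_periods = as.integer(n_periods),
    symptoms = symptoms,
    fraction_shortage = fraction_shortage, fraction_partial = fraction_partial,
    fraction_rural = fraction_rural,
    fraction_micropolitan = fraction_micropolitan,
    effect_multipliers = effect_multipliers, temporal_step = temporal_step,
    region_scale_range = region_scale_range, noise = noise,
    suppression = suppression, start_date = as.Date(start_date),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# deterministic stratum assignment: status in blocks, urbanization allocated
# proportionally within each status block so every stratum cell is populated
assign_strata <- function(config) {
  n <- config$n_counties
  n_short <- round(config$fraction_shortage * n)
  n_part <- round(config$fraction_partial * n)
  status <- rep(c("shortage", "partial", "nonshortage"),
                c(n_short, n_part, n - n_short - n_part))
  urban <- character(n)
  for (st in unique(status)) {
    idx <- which(status == st)
    m <- length(idx)
    n_r <- round(config$fraction_rural * m)
    n_mi <- round(config$fraction_micropolitan * m)
    urban[idx] <- rep(c("rural", "micropolitan", "metro"),
                      c(n_r, n_mi, m - n_r - n_mi))
  }
  data.table(
    county_fips = pad_fips(seq_len(n)),
    shortage_status = status,
    urban3 = urban,
    nchs6 = c(rural = 6L, micropolitan = 5L, metro = 1L)[urban]
  )
}

# product of all matching effect rows for one (status, urban3) stratum,
# vectorised over the symptom table
stratum_effects <- function(config, status, urban3) {
  sym <- config$symptoms
  e <- rep(1, nrow(sym))
  em <- config$effect_multipliers
  if (is.null(em) || !nrow(em)) return(e)
  for (i in seq_len(nrow(em))) {
    row <- em[i, ]
    if (!is.na(row$status) && row$status != status) next
    if (!is.na(row$urban3) && row$urban3 != urban3) next
    hit <- rep(TRUE, nrow(sym))
    if (!is.na(row$symptom_id)) hit <- sym$symptom_id == row$symptom_id
    if (!is.na(row$class)) hit <- hit & sym$class == row$class
    e[hit] <- e[hit] * row$multiplier
  }
  e
}

step_multipliers <- function(config) {
  sym <- config$symptoms$symptom_id
  m <- setNames(rep(1, length(sym)), sym)
  ts <- config$temporal_step
  if (!is.null(ts)) m[names(ts$multipliers)] <- ts$multipliers
  m
}

# bounded deterministic per-county substream seed (< 2^31)
county_seed <- function(seed, idx) {
  ((seed %% 100003L) * 20011 + idx * 7919) %% 2147483629 + 1
}

rlaplace <- function(n, b) {
  if (b == 0) return(numeric(n))
  u <- runif(n) - 0.5
  -b * sign(u) * log1p(-2 * abs(u))
}

#' Generate a synthetic symptom panel with known ground truth
#'
#' Draws a panel under the model documented in [simulation_config()].
#' Deterministic given the config seed; each county has its own derived
#' random substream, so enlarging `n_counties` leaves earlier counties'
#' draws untouched.
#'
#' @param config a [simulation_config()].
#' @return list with elements `panel` (a [symptom_panel()], suppressed
#'   counties removed), `designations` (a `county_designation` covering all
#'   counties, including suppressed ones), `truth` (a `panel_truth`: stratum
#'   assignments and analytic true shares, see [true_mean_share()]) and
#'   `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  strata <- assign_strata(config)
  sym <- config$symptoms
  S <- nrow(sym)
  Tn <- config$n_periods
  periods <- config$start_date + 14L * (seq_len(Tn) - 1L)
  stepm <- step_multipliers(config)
  cutoff <- if (is.null(config$temporal_step)) Tn + 1L else
    config$temporal_step$cutoff_period
  post <- seq_len(Tn) >= cutoff
  # step factor matrix T x S
  stepmat <- matrix(1, Tn, S)
  if (any(post)) stepmat[post, ] <- matrix(stepm, sum(post), S, byrow = TRUE)

  key <- paste(strata$shortage_status, strata$urban3)
  ukey <- unique(key)
  emat <- do.call(rbind, lapply(strsplit(ukey, " "), function(k) {
    stratum_effects(config, k[1], k[2])
  }))
  rownames(emat) <- ukey

  n_sup <- config$suppression$n_suppressed_counties
  theta <- config$suppression$cell_threshold
  suppressed <- rep(FALSE, config$n_counties)
  if (n_sup > 0) suppressed[seq(config$n_counties - n_sup + 1L,
                                config$n_counties)] <- TRUE

  out <- vector("list", config$n_counties)
  sigma <- numeric(config$n_counties)
  for (i in seq_len(config$n_counties)) {
    set.seed(county_seed(config$seed, i))
    sigma[i] <- runif(1, config$region_scale_range[1],
                      config$region_scale_range[2])
    base <- sigma[i] * sym$lambda * emat[key[i], ]          # length S
    mu <- stepmat * matrix(base, Tn, S, byrow = TRUE)       # T x S
    if (config$noise$lognormal_sd > 0) {
      mu <- mu * exp(matrix(rnorm(Tn * S, 0, config$noise$lognormal_sd),
                            Tn, S))
    }
    w <- mu + matrix(rlaplace(Tn * S, config$noise$laplace_b), Tn, S)
    wv <- as.vector(w)  # column-major: symptom varies slowest
    wv[wv < theta] <- NA_real_
    wv <- pmax(wv, 0)
    if (suppressed[i]) next
    out[[i]] <- data.table(
      county_fips = strata$county_fips[i],
      period_start = rep(periods, times = S),
      symptom_id = rep(sym$symptom_id, each = Tn),
      weight = wv
    )
  }
  panel <- symptom_panel(rbindlist(out),
                         registry = symptom_registry(sym$symptom_id))
  designations <- county_designation(strata[, .(county_fips, shortage_status,
                                                nchs6)])
  shares <- function(regime) {
    m <- emat * matrix(sym$lambda, nrow(emat), S, byrow = TRUE)
    if (regime == "post") m <- m * matrix(stepm, nrow(emat), S, byrow = TRUE)
    sh <- 100 * m / rowSums(m)
    colnames(sh) <- sym$symptom_id
    sh
  }
  truth <- structure(list(
    assignments = data.table(strata, suppressed = suppressed),
    symptoms = sym,
    shares_pre = shares("pre"),
    shares_post = shares("post"),
    n_pre = sum(!post), n_post = sum(post),
    sigma = sigma
  ), class = "panel_truth")
  list(panel = panel, designations = designations, truth = truth,
       config = config)
}

#' Analytic (ground-truth) mean share for a county selection
#'
#' The true expected set share — computed from the configuration's base
#' propensities and planted multipliers alone, no simulation — averaged over
#' the selected non-suppressed counties and the periods of the chosen
#' regime. With generator noise off, empirical county-period means match
#' this value exactly.
#'
#' @param truth `panel_truth` from [generate_panel()].
#' @param ids symptom ids making up the set.
#' @param status,urban3 optional stratum filters.
#' @param fips optional explicit county filter.
#' @param regime `"all"` (period-weighted over pre and post), `"pre"` or
#'   `"post"`.
#' @return scalar true mean set share (percent).
#' @export
true_mean_share <- function(truth, ids, status = NULL, urban3 = NULL,
                            fips = NULL, regime = c("all", "pre", "post")) {
  regime <- match.arg(regime)
  a <- as.data.frame(truth$assignments)
  a <- a[!a$suppressed, , drop = FALSE]
  if (!is.null(status)) a <- a[a$shortage_status %in% status, , drop = FALSE]
  if (!is.null(urban3)) a <- a[a$urban3 %in% urban3, , drop = FALSE]
  if (!is.null(fips)) a <- a[a$county_fips %in% pad_fips(fips), , drop = FALSE]
  if (!nrow(a)) stop("no counties match the ground-truth selection")
  key <- paste(a$shortage_status, a$urban3)
  per_stratum <- function(sh) rowSums(sh[key, ids, drop = FALSE])
  pre <- per_stratum(truth$shares_pre)
  post <- per_stratum(truth$shares_post)
  val <- switch(regime,
    pre = pre, post = post,
    all = (truth$n_pre * pre + truth$n_post * post) /
      (truth$n_pre + truth$n_post))
  mean(val)
}

#' True contrast difference implied by a configuration
#'
#' @param truth `panel_truth`.
#' @param ids symptom ids of the set.
#' @param a,b lists of filters passed to [true_mean_share()] for each group,
#'   e.g. `list(status = "shortage")`.
#' @param regime passed through.
#' @return true difference `mean_a - mean_b` in share percentage points.
#' @export
true_contrast_diff <- function(truth, ids, a, b,
                               regime = c("all", "pre", "post")) {
  regime <- match.arg(regime)
  do.call(true_mean_share, c(list(truth, ids, regime = regime), a)) -
    do.call(true_mean_share, c(list(truth, ids, regime = regime), b))
}

#' Simulate two raters' binary labels
#'
#' Fixture generator for agreement statistics: rater A labels items
#' `Bernoulli(p_positive)`; rater B copies A and flips each label
#' independently with probability `p_disagree`.
#'
#' @param n_items number of items (>= 1).
#' @param p_positive,p_disagree probabilities in \[0, 1\].
#' @param seed integer seed.
#' @return list with integer 0/1 vectors `a` and `b`.
#' @export
generate_coder_labels <- function(n_items, p_positive, p_disagree, seed = 1L) {
  if (n_items < 1) stop("n_items must be >= 1")
  stopifnot(p_positive >= 0, p_positive <= 1, p_disagree >= 0, p_disagree <= 1)
  set.seed(seed)
  a <- rbinom(n_items, 1L, p_positive)
  flip <- rbinom(n_items, 1L, p_disagree) == 1L
  b <- ifelse(flip, 1L - a, a)
  list(a = as.integer(a), b = as.integer(b))
}

#' Simulate a co-search affiliation table
#'
#' Each (seed symptom, other symptom) pair is linked with probability
#' `p_link`; linked pairs get a relevance score drawn uniformly on
#' `relevance_range`.
#'
#' @param symptom_ids full symptom catalogue.
#' @param seed_set subset of `symptom_ids` acting as sources.
#' @param p_link link probability in \[0, 1\].
#' @param relevance_range interval for the relevance score (nonnegative).
#' @param seed integer seed.
#' @return data.table (`affiliation_table`) with columns `source_symptom`,
#'   `related_symptom`, `relevance`.
#' @export
generate_affiliation_table <- function(symptom_ids, seed_set, p_link,
                                       relevance_range = c(0, 10), seed = 1L) {
  if (!length(symptom_ids)) stop("empty symptom list")
  if (!all(seed_set %in% symptom_ids)) {
    stop("seed_set must be a subset of symptom_ids")
  }
  stopifnot(p_link >= 0, p_link <= 1, relevance_range[1] >= 0)
  set.seed(seed)
  pairs <- CJ(source_symptom = seed_set, related_symptom = symptom_ids)
  pairs <- pairs[source_symptom != related_symptom]
  keep <- runif(nrow(pairs)) < p_link
  tab <- pairs[keep]
  tab[, relevance := runif(.N, relevance_range[1], relevance_range[2])]
  affiliation_table(tab)
}

#' @importFrom data.table CJ
NULL
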