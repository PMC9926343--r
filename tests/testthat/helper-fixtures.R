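# Shared fixture builders. Everything is generated in code; no stored data.

# wide provider-dialect CSV from a named list: rows are county-date pairs
write_wide_csv <- function(rows, path = tempfile(fileext = ".csv"),
                           symptom_prefix = "symptom:") {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  sym_cols <- setdiff(names(df), c("county_fips", "date"))
  names(df)[match(sym_cols, names(df))] <- paste0(symptom_prefix, sym_cols)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# minimal long-form panel from a weight matrix: counties x symptoms,
# replicated over periods (weights constant in time unless a function of t)
make_panel <- function(weights, counties = NULL, periods = 2,
                       start = as.Date("2020-01-01")) {
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  n_c <- nrow(weights); n_s <- ncol(weights)
  if (is.null(counties)) counties <- sprintf("%05d", seq_len(n_c))
  syms <- colnames(weights)
  if (is.null(syms)) syms <- paste0("s", seq_len(n_s))
  recs <- expand.grid(county_fips = counties,
                      period_start = start + 14 * (seq_len(periods) - 1),
                      symptom_id = syms, stringsAsFactors = FALSE)
  recs$weight <- weights[cbind(match(recs$county_fips, counties),
                               match(recs$symptom_id, syms))]
  symptom_panel(recs)
}

# random panel with per-county scale confounding, some suppressed cells
random_panel <- function(seed, n_c = 8, n_s = 5, periods = 3,
                         p_missing = 0.1) {
  set.seed(seed)
  counties <- sprintf("%05d", sample(1:99999, n_c))
  syms <- paste0("s", seq_len(n_s))
  recs <- expand.grid(county_fips = counties,
                      period_start = as.Date("2020-01-01") +
                        14 * (seq_len(periods) - 1),
                      symptom_id = syms, stringsAsFactors = FALSE)
  sigma <- stats::runif(n_c, 0.2, 5)
  recs$weight <- sigma[match(recs$county_fips, counties)] *
    stats::rlnorm(nrow(recs), 0, 0.5)
  recs$weight[stats::runif(nrow(recs)) < p_missing] <- NA
  symptom_panel(recs)
}

tiny_designations <- function() {
  county_designation(data.frame(
    county_fips = sprintf("%05d", 1:6),
    shortage_status = c("shortage", "shortage", "nonshortage",
                        "nonshortage", "partial", "shortage"),
    nchs6 = c(6, 5, 6, 1, 6, 1)
  ))
}

# independent brute-force step-up FDR oracle (quadratic, by definition)
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) {
    min(ps[i:m] * m / (i:m))
  }, numeric(1))
  qs <- pmin(qs, 1)
  q <- numeric(m)
  q[o] <- qs
  q
}

# direct-formula kappa oracle from a 2x2 confusion table
kappa_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  (po - pe) / (1 - pe)
}
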