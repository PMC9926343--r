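#' Two-sample two-tailed t test
#'
#' Plain two-group t statistic with a two-sided p value from the t
#' distribution. `"welch"` (default) uses the Welch-Satterthwaite degrees of
#' freedom and makes no equal-variance assumption — appropriate here because
#' the contrasted county groups typically have grossly unequal spreads and
#' sizes; `"pooled"` is the classical equal-variance Student test.
#'
#' Degenerate inputs: if both groups have zero variance and equal means,
#' `t = 0, p = 1` by convention; if both have zero variance and different
#' means, `p = 0` with `degenerate = TRUE`.
#'
#' @param x,y numeric observation vectors (NAs dropped; >= 2 values each).
#' @param variant `"welch"` or `"pooled"`.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
two_group_ttest <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) {
      return(list(t = 0, df = nx + ny - 2, p = 1, degenerate = FALSE))
    }
    return(list(t = sign(mx - my) * Inf, df = nx + ny - 2, p = 0,
                degenerate = TRUE))
  }
  if (variant == "pooled") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate (Q values)
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1. Ties share ranks
#' stably. A Q value is the smallest FDR level at which that test would be
#' called significant.
#'
#' @param p_values numeric vector of p values in \[0, 1\] (no NAs).
#' @param method `"BH"` (default) or `"BY"` (Benjamini-Yekutieli, valid
#'   under arbitrary dependence: BH values scaled by `sum(1/(1:m))`).
#' @return numeric vector of Q values, same order as the input.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  q_sorted <- rev(cummin(rev(ps * cm * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
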