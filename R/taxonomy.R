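#' Cohen's kappa for two raters
#'
#' Chance-corrected inter-rater agreement,
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, with \eqn{p_o} the observed
#' agreement and \eqn{p_e = \sum_k p_A(k)\,p_B(k)} the agreement expected if
#' both raters labelled independently with their marginal rates. Used here
#' to quantify agreement between two coders labelling symptom topics as
#' mental-health-relevant or not. When both raters are constant and agree
#' (`p_e = 1`, `p_o = 1`) kappa is defined as 1.
#'
#' @param labels_a,labels_b equal-length label vectors (any two or more
#'   categories; typically binary include/exclude).
#' @return `agreement_result`: list with `kappa`, `percent_agreement`
#'   (0-100) and `confusion_counts` (square contingency table).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences must have equal length")
  }
  n <- length(labels_a)
  if (n == 0L) stop("empty label sequences")
  if (anyNA(labels_a) || anyNA(labels_b)) stop("labels must not be missing")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  tab <- table(rater_a = a, rater_b = b)
  p_o <- sum(diag(tab)) / n
  p_e <- sum((rowSums(tab) / n) * (colSums(tab) / n))
  kappa <- if (p_e == 1) {
    if (p_o == 1) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = kappa, percent_agreement = 100 * p_o,
                 confusion_counts = tab),
            class = "agreement_result")
}

#' Kappa directly from 2x2 confusion counts
#'
#' @param a both positive; @param b A positive, B negative;
#' @param c A negative, B positive; @param d both negative.
#' @return `agreement_result`, as [cohen_kappa()].
#' @export
kappa_from_counts <- function(a, b, c, d) {
  cohen_kappa(rep(c(1L, 1L, 0L, 0L), c(a, b, c, d)),
              rep(c(1L, 0L, 1L, 0L), c(a, b, c, d)))
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> kappa = %.3f, agreement = %.1f%% (n = %d)\n",
              x$kappa, x$percent_agreement, sum(x$confusion_counts)))
  print(x$confusion_counts)
  invisible(x)
}

#' Affiliation table constructor
#'
#' Co-search affiliations: for a source symptom, the related topics the
#' search provider reports alongside it, with an opaque nonnegative
#' relevance score.
#'
#' @param df data.frame with columns `source_symptom`, `related_symptom`,
#'   `relevance`.
#' @return data.table of class `affiliation_table`.
#' @export
affiliation_table <- function(df) {
  dt <- as.data.table(df)
  need <- c("source_symptom", "related_symptom", "relevance")
  if (!all(need %in% names(dt))) {
    stop("affiliation table needs columns (source_symptom, related_symptom, relevance)")
  }
  dt <- dt[, need, with = FALSE]
  if (any(!is.na(dt$relevance) & dt$relevance < 0)) {
    stop("relevance scores must be >= 0")
  }
  if (anyDuplicated(dt, by = c("source_symptom", "related_symptom"))) {
    stop("duplicate (source, related) pairs in affiliation table")
  }
  setattr(dt, "class", c("affiliation_table", class(dt)))
  dt
}

#' Expand a seed symptom set via co-search affiliations
#'
#' Returns the related symptoms of affiliation rows whose source is in the
#' seed set and whose relevance clears the threshold. Associations below the
#' threshold are removed (the removal rule is `relevance < threshold`, so a
#' score exactly at the threshold is kept). Seeds themselves are not
#' returned. Single-pass by default; `transitive = TRUE` iterates expansion
#' from newly added symptoms to a fixed point.
#'
#' @param seed_set character vector of seed symptom ids.
#' @param table an [affiliation_table()].
#' @param threshold minimum relevance kept (default 2).
#' @param transitive expand from expanded symptoms too?
#' @param known_ids optional catalogue; related ids outside it pass through
#'   with a warning.
#' @return character vector of newly added symptom ids (sorted).
#' @export
expand_by_affiliation <- function(seed_set, table, threshold = 2,
                                  transitive = FALSE, known_ids = NULL) {
  if (threshold < 0) stop("threshold must be >= 0")
  seed_set <- unique(as.character(seed_set))
  if (!length(seed_set)) return(character(0))
  tab <- as.data.table(table)
  kept <- tab[relevance >= threshold]
  one_pass <- function(src) {
    sort(unique(kept$related_symptom[kept$source_symptom %in% src]))
  }
  added <- setdiff(one_pass(seed_set), seed_set)
  if (transitive) {
    frontier <- added
    while (length(frontier)) {
      new <- setdiff(one_pass(frontier), c(seed_set, added))
      added <- c(added, new)
      frontier <- new
    }
    added <- sort(added)
  }
  if (!is.null(known_ids)) {
    unknown <- setdiff(added, known_ids)
    if (length(unknown)) {
      warning("expansion yielded id(s) outside the known catalogue: ",
              paste(unknown, collapse = ", "))
    }
  }
  added
}

#' Apply exclusion rules and assemble the final symptom set
#'
#' The curated set is `(seeds U expanded) \ excluded`; every exclusion is
#' recorded with its reason (e.g. respiratory symptoms, nonpsychiatric
#' syndromes). Rules naming an id not among the candidates are warned about
#' and skipped.
#'
#' @param seed_ids manually coded seed symptoms.
#' @param expanded_ids symptoms added by [expand_by_affiliation()].
#' @param rules data.frame with columns `symptom_id`, `reason`, or `NULL`.
#' @return `mh_symptom_set`: list with `seed_ids`, `expanded_ids`,
#'   `excluded` (data.frame id + reason) and `final_ids`.
#' @export
apply_exclusions <- function(seed_ids, expanded_ids = character(0),
                             rules = NULL) {
  seed_ids <- unique(as.character(seed_ids))
  expanded_ids <- setdiff(unique(as.character(expanded_ids)), seed_ids)
  candidates <- union(seed_ids, expanded_ids)
  excluded <- data.frame(symptom_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(rules) && nrow(rules)) {
    rules <- as.data.frame(rules)
    missing_ids <- setdiff(rules$symptom_id, candidates)
    if (length(missing_ids)) {
      warning("exclusion rule(s) name id(s) absent from candidates: ",
              paste(missing_ids, collapse = ", "))
    }
    keep <- rules$symptom_id %in% candidates
    excluded <- data.frame(symptom_id = as.character(rules$symptom_id[keep]),
                           reason = as.character(rules$reason[keep]),
                           stringsAsFactors = FALSE)
  }
  final <- setdiff(candidates, excluded$symptom_id)
  structure(list(seed_ids = seed_ids, expanded_ids = expanded_ids,
                 excluded = excluded, final_ids = final),
            class = "mh_symptom_set")
}

#' @export
print.mh_symptom_set <- function(x, ...) {
  cat(sprintf(
    "<mh_symptom_set> %d seeds + %d expanded - %d excluded = %d final\n",
    length(x$seed_ids), length(x$expanded_ids), nrow(x$excluded),
    length(x$final_ids)))
  invisible(x)
}

#' Sweep the affiliation relevance threshold
#'
#' Reports the expanded- and final-set size at each candidate threshold; a
#' reading aid for choosing a cutoff (coverage vs noise), not an optimizer —
#' that trade-off is a judgement call.
#'
#' @param seed_set,table,known_ids as in [expand_by_affiliation()].
#' @param thresholds numeric vector of thresholds to try.
#' @return data.frame with `threshold`, `n_expanded`, `n_final`.
#' @export
threshold_sweep <- function(seed_set, table, thresholds = 0:5,
                            known_ids = NULL) {
  rows <- lapply(thresholds, function(th) {
    exp <- expand_by_affiliation(seed_set, table, threshold = th,
                                 known_ids = known_ids)
    data.frame(threshold = th, n_expanded = length(exp),
               n_final = length(seed_set) + length(exp))
  })
  do.call(rbind, rows)
}
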