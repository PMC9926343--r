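#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates: obtain a panel (either read from CSV files or simulated),
#' resolve the analysis symptom set, compute shares and the composite set
#' share, run the requested contrast families and the pre/post temporal
#' contrast, rank counties, emit group time series, and write every table as
#' CSV plus a JSON run manifest with content hashes. Deterministic for fixed
#' inputs, config and seed; on any stage error the partially written outputs
#' are removed and the error names the failing stage.
#'
#' @param config either a path to a JSON config file or a list with fields:
#'   `simulate` (a [simulation_config()] or list of its arguments) *or*
#'   `panel_path` + `shortage_path` + `nchs_path`; optional `symptom_set`
#'   (character vector of ids; default: the simulated mental-health ids, or
#'   all registry symptoms for file input); `contrasts` (names understood by
#'   [named_contrast()]; default all five); `cutoff` (date, default
#'   2020-03-11); `alpha`, `fdr_method`, `variant`, `unit`, `rank_k`
#'   (default 10); `out_dir` (required); `seed`.
#' @return invisibly, a list with the in-memory tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$out_dir)) stop("config needs out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    fwrite(as.data.table(as.data.frame(obj)), path)
    written <<- c(written, path)
    path
  }
  stage <- "init"
  result <- tryCatch({
    # --- input stage -----------------------------------------------------
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sc <- config$simulate
      if (!inherits(sc, "simulation_config")) {
        if (!is.null(config$seed)) sc$seed <- config$seed
        sc <- do.call(simulation_config, sc)
      }
      sim <- generate_panel(sc)
      panel <- sim$panel
      designations <- sim$designations
      default_set <- mh_ids(sc$symptoms)
    } else {
      stage <- "read_symptom_panel"
      if (is.null(config$panel_path)) {
        stop("config needs either simulate or panel_path")
      }
      panel <- read_symptom_panel(config$panel_path)
      sim <- NULL
      stage <- "read_designations"
      designations <- read_designations(config$shortage_path,
                                        config$nchs_path)
      default_set <- attr(panel, "registry")$symptom_id
    }
    stage <- "symptom_set"
    set_ids <- config$symptom_set
    if (is.null(set_ids)) set_ids <- default_set
    reg_ids <- attr(panel, "registry")$symptom_id
    if (!all(set_ids %in% reg_ids)) {
      stop("symptom_set contains ids absent from the panel registry")
    }
    # --- shares ----------------------------------------------------------
    stage <- "shares"
    shares <- share_of_search(panel)
    series <- set_share(shares, set_ids)
    emit(shares, "share_table.csv")
    emit(series, "set_share_series.csv")
    # per-county span means: the choropleth export (FIPS -> share)
    span <- range(shares$period_start)
    county_means <- window_mean(series, c(span[1], span[2] + 14L))
    emit(county_means, "county_mean_share.csv")
    # --- contrasts -------------------------------------------------------
    stage <- "compare_groups"
    contrast_names <- config$contrasts
    if (is.null(contrast_names)) {
      contrast_names <- c("shortage_vs_nonshortage",
                          "rural_shortage_vs_rural_nonshortage",
                          "urban_shortage_vs_urban_nonshortage",
                          "rural_vs_urban_shortage",
                          "rural_vs_metro_shortage")
    }
    unit <- if (is.null(config$unit)) "county_period" else config$unit
    variant <- if (is.null(config$variant)) "welch" else config$variant
    fdr <- if (is.null(config$fdr_method)) "BH" else config$fdr_method
    alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
    comparisons <- list()
    for (cn in contrast_names) {
      tab <- compare_groups(shares, series, named_contrast(cn, unit = unit),
                            designations, symptoms = set_ids,
                            variant = variant, fdr_method = fdr,
                            alpha = alpha)
      comparisons[[cn]] <- tab
      emit(tab, paste0("comparison_", cn, ".csv"))
    }
    # --- temporal --------------------------------------------------------
    stage <- "temporal_contrast"
    cutoff <- as.Date(if (is.null(config$cutoff)) "2020-03-11" else
      config$cutoff)
    periods <- sort(unique(shares$period_start))
    temporal <- NULL
    if (sum(periods < cutoff) >= 2L && sum(periods >= cutoff) >= 2L) {
      for (st in c("shortage", "nonshortage")) {
        pred <- function(d) !is.na(d$shortage_status) &
          d$shortage_status == st
        tab <- temporal_contrast(shares, series, counties = pred,
                                 designations = designations,
                                 cutoff = cutoff, symptoms = set_ids,
                                 variant = variant, fdr_method = fdr,
                                 alpha = alpha)
        comparisons[[paste0("pre_vs_post_", st)]] <- tab
        emit(tab, paste0("comparison_pre_vs_post_", st, ".csv"))
      }
    }
    # --- rankings and time series ---------------------------------------
    stage <- "rank_counties"
    k <- if (is.null(config$rank_k)) 10L else config$rank_k
    ranks <- rank_counties(series, designations, k = min(k,
      uniqueN(series$county_fips)))
    emit(ranks$top, "rank_top.csv")
    emit(ranks$bottom, "rank_bottom.csv")
    stage <- "group_time_series"
    ts_groups <- list(
      shortage = function(d) !is.na(d$shortage_status) &
        d$shortage_status == "shortage",
      nonshortage = function(d) !is.na(d$shortage_status) &
        d$shortage_status == "nonshortage"
    )
    ts <- group_time_series(series, ts_groups, designations)
    emit(ts, "time_series.csv")
    # --- manifest --------------------------------------------------------
    stage <- "manifest"
    manifest <- list(
      seed = config$seed,
      cutoff = as.character(cutoff),
      unit = unit, variant = variant, fdr_method = fdr, alpha = alpha,
      symptom_set = set_ids,
      n_counties = uniqueN(panel$county_fips),
      n_periods = uniqueN(panel$period_start),
      package_version = as.character(utils::packageVersion("searchshare")),
      files = lapply(setNames(nm = basename(written)), function(f) {
        path <- file.path(out_dir, f)
        list(rows = nrow(fread(path)), md5 = unname(tools::md5sum(path)))
      })
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    list(panel = panel, designations = designations, shares = shares,
         set_series = series, comparisons = comparisons, ranks = ranks,
         time_series = ts, manifest = manifest, sim = sim)
  }, error = function(e) {
    unlink(written)
    unlink(file.path(out_dir, "manifest.json"))
    stop(errorCondition(
      paste0("pipeline failed at stage '", stage, "': ", conditionMessage(e)),
      class = "searchshare_pipeline_error", stage = stage
    ))
  })
  invisible(result)
}

#' Command-line entry point
#'
#' Minimal subcommand interface: `run --config <file.json>` executes
#' [run_pipeline()]; `simulate --config <file.json>` generates a synthetic
#' panel and writes panel, designation and ground-truth-share CSVs. Exit
#' codes: 0 success, 2 validation error, 3 I/O error, 4 statistical
#' degeneracy (empty group / too few observations).
#'
#' @param argv character vector of arguments (default: the command line).
#' @return integer exit status, invisibly.
#' @export
searchshare_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: searchshare run|simulate --config <file.json>")
    2L
  }
  if (length(argv) < 1L) return(invisible(usage()))
  cmd <- argv[1]
  cfg_i <- which(argv == "--config")
  if (!length(cfg_i) || cfg_i + 1L > length(argv)) return(invisible(usage()))
  cfg_path <- argv[cfg_i + 1L]
  if (!file.exists(cfg_path)) {
    message("config file not found: ", cfg_path)
    return(invisible(3L))
  }
  status <- tryCatch({
    config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    if (cmd == "run") {
      run_pipeline(config)
    } else if (cmd == "simulate") {
      sc <- do.call(simulation_config, config$simulate)
      sim <- generate_panel(sc)
      out_dir <- config$out_dir
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_panel(sim$panel, file.path(out_dir, "panel.csv"))
      write_designations(sim$designations,
                         file.path(out_dir, "designations.csv"))
      truth <- data.table(
        stratum = rownames(sim$truth$shares_pre),
        as.data.table(sim$truth$shares_pre))
      fwrite(truth, file.path(out_dir, "true_shares_pre.csv"))
      invisible(NULL)
    } else {
      return(usage())
    }
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    msg <- conditionMessage(e)
    if (grepl("empty group|at least 2 observations|at least 2 biweekly",
              msg)) 4L
    else if (grepl("cannot open|not found|No such file", msg)) 3L
    else 2L
  })
  invisible(status)
}
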