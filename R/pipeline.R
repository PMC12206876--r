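# End-to-end orchestration: configuration, the full pipeline run, and
# structured file outputs for each stage.

#' Build and validate a pipeline run configuration
#'
#' Either `input_dir` (a directory holding DEMO/DRUG/REAC/THER[/INDI] ASCII
#' tables) or `synth` (a [synth_config()], simulated at run time) must be
#' supplied. Validation happens before any data are read; the resolved
#' configuration is serialised into the output directory on every run.
#'
#' @param input_dir Directory with FAERS-style quarterly files.
#' @param synth Optional [synth_config()] replacing file input.
#' @param index_drug Canonical index-drug label.
#' @param synonyms_file,hierarchy_file Optional CSV paths (see
#'   [read_synonyms()], [read_hierarchy()]).
#' @param indication_filter Optional PT list restricting the index cohort by
#'   primary-suspect indication (off by default).
#' @param policy A [threshold_policy()].
#' @param ebgm_method `"mgps"` or `"ic"` (see [signal_table()]).
#' @param allowlist Partner drugs for the sensitivity analysis.
#' @param subgroups Subgroup dimensions to run (`"sex"`, `"age"`).
#' @param outdir Output directory (`NULL` for in-memory results only).
#' @param seed Seed for any stochastic step (synthetic input).
#' @export
pv_config <- function(input_dir = NULL, synth = NULL,
                      index_drug = "CARBOPLATIN",
                      synonyms_file = NULL, hierarchy_file = NULL,
                      indication_filter = NULL,
                      policy = threshold_policy(),
                      ebgm_method = c("mgps", "ic"),
                      allowlist = c("GEMCITABINE", "PEMETREXED", "DOCETAXEL",
                                    "PACLITAXEL", "VINORELBINE",
                                    "PEMBROLIZUMAB", "ATEZOLIZUMAB",
                                    "AMIVANTAMAB"),
                      subgroups = c("sex", "age"),
                      outdir = NULL, seed = 1L) {
  ebgm_method <- match.arg(ebgm_method)
  if (is.null(input_dir) && is.null(synth)) {
    stop("config error: one of input_dir or synth is required")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("config error: input_dir does not exist: ", input_dir)
  }
  for (f in c(synonyms_file, hierarchy_file)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("config error: file not found: ", f)
    }
  }
  if (!is.null(synth)) stopifnot(inherits(synth, "synth_config"))
  stopifnot(inherits(policy, "threshold_policy"))
  structure(list(input_dir = input_dir, synth = synth,
                 index_drug = toupper(index_drug),
                 synonyms_file = synonyms_file,
                 hierarchy_file = hierarchy_file,
                 indication_filter = indication_filter,
                 policy = policy, ebgm_method = ebgm_method,
                 allowlist = toupper(allowlist), subgroups = subgroups,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pv_config")
}

#' Run the signal-detection pipeline end to end
#'
#' Steps: `ingest` (read or simulate, deduplicate, assemble, split
#' index/background, with a count log at each stage), `signals` (PT- and
#' SOC-level gated tables), `tto` (Weibull time-to-onset fit), `subgroup`
#' (per-stratum signal tables) and `sensitivity` (allowlist-restricted
#' re-analysis). When the configuration has an `outdir`, each stage writes
#' CSV/JSON outputs plus the resolved configuration and the run log.
#'
#' @param config A [pv_config()].
#' @param steps Which stages to run (`"ingest"` is always implied).
#' @return List with elements `reports`, `cohort`, `log` and, per requested
#'   step, `signals_pt`, `signals_soc`, `tto`, `subgroup`, `sensitivity`.
#' @export
pv_run <- function(config,
                   steps = c("signals", "tto", "subgroup", "sensitivity")) {
  stopifnot(inherits(config, "pv_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  hierarchy <- NULL
  truth <- NULL
  if (!is.null(config$synth)) {
    synth_cfg <- config$synth
    synth_cfg$seed <- config$seed
    gen <- generate_corpus(synth_cfg,
                           dir = if (is.null(outdir)) NULL
                           else file.path(outdir, "synth"))
    raw <- gen$raw
    truth <- gen$truth
    hierarchy <- gen$hierarchy
  } else {
    files <- list(
      demo = file.path(config$input_dir, "DEMO.txt"),
      drug = file.path(config$input_dir, "DRUG.txt"),
      reac = file.path(config$input_dir, "REAC.txt"),
      ther = file.path(config$input_dir, "THER.txt"))
    indi_path <- file.path(config$input_dir, "INDI.txt")
    if (file.exists(indi_path)) files$indi <- indi_path
    raw <- read_faers_quarter(files)
  }
  if (!is.null(config$hierarchy_file)) {
    hierarchy <- read_hierarchy(config$hierarchy_file)
  }
  synonyms <- if (!is.null(config$synonyms_file)) {
    read_synonyms(config$synonyms_file)
  } else NULL

  n_raw <- nrow(raw$demo)
  dedup <- deduplicate_reports(raw)
  reports <- assemble_reports(dedup, synonyms = synonyms,
                              hierarchy = hierarchy)
  cohort <- select_index_cohort(reports, config$index_drug,
                                indication_filter = config$indication_filter,
                                indi = dedup$indi)
  run_log <- list(
    n_raw_demo_rows = n_raw,
    n_duplicates_removed = attr(dedup, "n_removed") %||% 0L,
    assemble = attr(reports, "log"),
    n_index_reports = n_reports(cohort$index),
    n_background_reports = n_reports(cohort$background),
    n_index_event_pairs = nrow(unique(cohort$index$events[c("primaryid", "pt")]))
  )

  out <- list(reports = reports, cohort = cohort, log = run_log,
              truth = truth)

  if ("signals" %in% steps) {
    out$signals_pt <- signal_table(cohort$index, cohort$background,
                                   level = "pt", hierarchy = hierarchy,
                                   policy = config$policy,
                                   ebgm_method = config$ebgm_method)
    out$signals_soc <- if (!is.null(hierarchy)) {
      signal_table(cohort$index, cohort$background, level = "soc",
                   hierarchy = hierarchy, policy = config$policy,
                   ebgm_method = config$ebgm_method)
    } else NULL
    out$descriptive <- summarize_cohort(cohort$index)
  }
  if ("tto" %in% steps) {
    tto <- extract_tto(cohort$index, config$index_drug)
    out$tto_sample <- tto
    out$tto <- if (tto$n_with_tto >= 10) fit_weibull(tto) else NULL
  }
  if ("subgroup" %in% steps) {
    out$subgroup <- list()
    for (dim in config$subgroups) {
      parts <- stratify_reports(reports, config$index_drug,
                                subgroup_spec(dim))
      out$subgroup[[dim]] <- run_stratified_signals(
        parts, level = "pt", hierarchy = hierarchy,
        policy = config$policy, ebgm_method = config$ebgm_method)
    }
  }
  if ("sensitivity" %in% steps) {
    restricted <- sensitivity_filter(cohort$index, config$index_drug,
                                     config$allowlist)
    out$log$n_sensitivity_reports <- n_reports(restricted)
    out$sensitivity <- if (n_reports(restricted) > 0) {
      signal_table(restricted, cohort$background, level = "pt",
                   hierarchy = hierarchy, policy = config$policy,
                   ebgm_method = config$ebgm_method)
    } else NULL
  }

  if (!is.null(outdir)) .pv_write_outputs(out, config)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pv_write_outputs <- function(out, config) {
  outdir <- config$outdir
  cfg <- config
  cfg$policy <- unclass(cfg$policy)
  cfg$synth <- if (!is.null(cfg$synth)) unclass(cfg$synth) else NULL
  jsonlite::write_json(lapply(cfg, function(x) x),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  jsonlite::write_json(out$log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  if (!is.null(out$signals_pt)) {
    wcsv(out$signals_pt, "signals_pt.csv")
    wcsv(format_signal_table(out$signals_pt), "signals_pt_formatted.csv")
  }
  if (!is.null(out$signals_soc)) wcsv(out$signals_soc, "signals_soc.csv")
  if (!is.null(out$descriptive)) {
    wcsv(cohort_summary_table(out$descriptive), "descriptive.csv")
  }
  if (!is.null(out$tto)) {
    fit <- out$tto
    jsonlite::write_json(list(
      n = fit$n, n_total_reports = fit$n_total_reports %||% NA,
      median_days = fit$median_days %||% NA,
      iqr = c(fit$iqr_low %||% NA, fit$iqr_high %||% NA),
      scale = fit$scale, scale_ci = c(fit$scale_ci_low, fit$scale_ci_high),
      shape = fit$shape, shape_ci = c(fit$shape_ci_low, fit$shape_ci_high),
      hazard_type = fit$hazard_type),
      file.path(outdir, "tto_weibull.json"), auto_unbox = TRUE, digits = NA)
    wcsv(tto_density_table(fit, out$tto_sample$values), "tto_density.csv")
  }
  if (!is.null(out$subgroup)) {
    for (dim in names(out$subgroup)) {
      wcsv(bind_stratified_signals(out$subgroup[[dim]]),
           paste0("subgroup_", dim, ".csv"))
    }
  }
  if (!is.null(out$sensitivity)) wcsv(out$sensitivity, "sensitivity.csv")
  invisible(NULL)
}

#' Write assembled reports as JSON lines
#'
#' One JSON object per report (demographics, drugs, events), a stable
#' interchange format for downstream tooling.
#'
#' @param reports A `safety_reports`.
#' @param path Output file path.
#' @export
write_reports_jsonl <- function(reports, path) {
  demo <- reports$demo
  con <- file(path, open = "wt")
  on.exit(close(con))
  drugs_by <- split(reports$drugs[c("name", "role", "therapy_start")],
                    reports$drugs$primaryid)
  events_by <- split(reports$events$pt, reports$events$primaryid)
  for (i in seq_len(nrow(demo))) {
    pid <- demo$primaryid[i]
    rec <- c(as.list(demo[i, , drop = FALSE]),
             list(drugs = drugs_by[[pid]], events = events_by[[pid]]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", na = "null"), con)
  }
  invisible(path)
}
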