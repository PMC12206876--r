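# Subgroup (sex, age) and sensitivity re-analysis of the signal pipeline.

#' Define a subgroup specification
#'
#' @param dimension `"sex"` or `"age"`.
#' @param age_preset For age: `"table1"` uses the four demographic bins
#'   (`<18`, `18-64.9`, `65-84.9`, `>85`); `"ge65"` merges the two upper
#'   bins into a single `>=65` level against `18-64.9` and `<18`.
#' @return Object of class `subgroup_spec`: the dimension and a named list
#'   of level-membership predicates over the demographic table.
#' @export
subgroup_spec <- function(dimension = c("sex", "age"),
                          age_preset = c("table1", "ge65")) {
  dimension <- match.arg(dimension)
  age_preset <- match.arg(age_preset)
  levels <- if (dimension == "sex") {
    list("M" = function(demo) !is.na(demo$sex) & demo$sex == "M",
         "F" = function(demo) !is.na(demo$sex) & demo$sex == "F")
  } else if (age_preset == "table1") {
    lv <- c("<18", "18-64.9", "65-84.9", ">85")
    stats::setNames(lapply(lv, function(l) {
      force(l)
      function(demo) !is.na(demo$age_group) & demo$age_group == l
    }), lv)
  } else {
    list("<18" = function(demo) !is.na(demo$age_group) & demo$age_group == "<18",
         "18-64.9" = function(demo) !is.na(demo$age_group) &
           demo$age_group == "18-64.9",
         ">=65" = function(demo) !is.na(demo$age_group) &
           demo$age_group %in% c("65-84.9", ">85"))
  }
  structure(list(dimension = dimension, levels = levels),
            class = "subgroup_spec")
}

#' Partition a corpus into subgroup strata
#'
#' Each level receives its own index/background partition; reports with a
#' missing value on the stratifying dimension are excluded from every level
#' (and counted). By default the comparator is within-stratum: the
#' background of a level contains only same-level reports.
#'
#' @param reports Full `safety_reports` corpus.
#' @param index_drug Canonical index-drug label.
#' @param spec A [subgroup_spec()].
#' @param within_stratum_background Restrict the background to the same
#'   stratum (default) rather than the global background.
#' @return Named list: per level, a list with `index` and `background`
#'   `safety_reports` (levels with an empty index cohort are dropped with a
#'   warning); attribute `n_missing` counts excluded reports.
#' @export
stratify_reports <- function(reports, index_drug, spec,
                             within_stratum_background = TRUE) {
  stopifnot(inherits(reports, "safety_reports"),
            inherits(spec, "subgroup_spec"))
  demo <- reports$demo
  member <- vapply(spec$levels, function(f) f(demo), logical(nrow(demo)))
  if (is.null(dim(member))) member <- matrix(member, nrow = nrow(demo))
  n_missing <- sum(rowSums(member) == 0L)
  d <- reports$drugs
  idx_ids <- unique(d$primaryid[d$name == index_drug & !is.na(d$role) &
                                  d$role == "PS"])
  out <- list()
  for (j in seq_along(spec$levels)) {
    lev <- names(spec$levels)[j]
    ids <- demo$primaryid[member[, j]]
    lev_idx <- intersect(ids, idx_ids)
    if (length(lev_idx) == 0L) {
      warning("stratum '", lev, "' has an empty index cohort; skipped")
      next
    }
    bg_ids <- if (within_stratum_background) setdiff(ids, lev_idx)
    else setdiff(demo$primaryid, lev_idx)
    if (length(bg_ids) == 0L) {
      warning("stratum '", lev, "' has no comparator reports; skipped")
      next
    }
    out[[lev]] <- list(index = subset_reports(reports, lev_idx),
                       background = subset_reports(reports, bg_ids))
  }
  attr(out, "n_missing") <- n_missing
  out
}

#' Restrict an index cohort to allowlisted co-medications
#'
#' Retains reports whose drug entries other than the index drug all carry
#' names in the allowlist (reports with no other drug are retained). This
#' realises the "excluding reports with additional concomitant medications"
#' sensitivity analysis while keeping the named combination partners.
#'
#' @param reports Index-cohort `safety_reports` (drug names normalised).
#' @param index_drug Canonical index-drug label.
#' @param allowlist Character vector of permitted co-medication labels; must
#'   not contain the index drug.
#' @return The retained `safety_reports`; attribute `n_excluded` counts
#'   dropped reports.
#' @export
sensitivity_filter <- function(reports, index_drug, allowlist) {
  stopifnot(inherits(reports, "safety_reports"))
  allowlist <- toupper(allowlist)
  if (index_drug %in% allowlist) {
    stop("the index drug must not be in the allowlist")
  }
  d <- reports$drugs
  other <- d[d$name != index_drug, , drop = FALSE]
  bad_ids <- unique(other$primaryid[!other$name %in% allowlist])
  keep <- setdiff(reports$demo$primaryid, bad_ids)
  out <- subset_reports(reports, keep)
  attr(out, "n_excluded") <- n_reports(reports) - length(keep)
  out
}

#' Run the full signal pipeline within each stratum
#'
#' Applies [signal_table()] (all four statistics plus gating, identical
#' policy across levels) to every partition produced by
#' [stratify_reports()].
#'
#' @param partitions Named list of `list(index, background)` partitions.
#' @param ... Passed to [signal_table()] (`level`, `hierarchy`, `policy`,
#'   `ebgm_method`, ...).
#' @return Named list of gated signal tables, keyed by level.
#' @export
run_stratified_signals <- function(partitions, ...) {
  out <- lapply(partitions, function(p) {
    signal_table(p$index, p$background, ...)
  })
  out
}

#' Bind per-level signal tables into one long table
#'
#' @param results Named list from [run_stratified_signals()].
#' @return One data frame with a leading `stratum` column.
#' @export
bind_stratified_signals <- function(results) {
  do.call(rbind, lapply(names(results), function(lev) {
    cbind(stratum = lev, results[[lev]], stringsAsFactors = FALSE)
  }))
}
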