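# Ingestion of FAERS-style quarterly ASCII extracts: parsing, case-level
# deduplication, and assembly of normalised per-case safety reports.

.FAERS_REQUIRED_COLS <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "reporter_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

#' Read one FAERS-style quarter of ASCII tables
#'
#' Parses the '$'-delimited DEMO/DRUG/REAC/THER/INDI tables of a FAERS-style
#' extract. All fields are kept as character strings; dates stay in their raw
#' 8/6/4-digit form so that partial dates remain distinguishable from full
#' ones (see [date_completeness()]). Unknown columns are preserved but
#' ignored downstream.
#'
#' @param paths Named list or character vector with elements `demo`, `drug`,
#'   `reac`, `ther` and optionally `indi`, each a file path.
#' @param sep Field delimiter; FAERS quarterly files use `"$"`.
#' @return An object of class `faers_raw`: a list of data frames `demo`,
#'   `drug`, `reac`, `ther`, `indi` with lower-case column names.
#' @export
read_faers_quarter <- function(paths, sep = "$") {
  paths <- as.list(paths)
  need <- c("demo", "drug", "reac", "ther")
  missing_tab <- setdiff(need, names(paths))
  if (length(missing_tab) > 0L) {
    stop("missing input tables: ", paste(missing_tab, collapse = ", "))
  }
  out <- list()
  for (tab in c("demo", "drug", "reac", "ther", "indi")) {
    if (is.null(paths[[tab]])) {
      out[[tab]] <- .empty_faers_table(tab)
      next
    }
    out[[tab]] <- .read_faers_table(paths[[tab]], tab, sep)
  }
  structure(out, class = "faers_raw")
}

.read_faers_table <- function(path, tab, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- .FAERS_REQUIRED_COLS[[tab]]
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    warning("empty ", toupper(tab), " file: ", path)
    return(.empty_faers_table(tab))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE, fill = TRUE,
                          fileEncoding = "latin1")
  names(df) <- tolower(names(df))
  # REAC files sometimes name the event column pt_term
  if (tab == "reac" && !"pt" %in% names(df) && "pt_term" %in% names(df)) {
    names(df)[names(df) == "pt_term"] <- "pt"
  }
  absent <- setdiff(required, names(df))
  if (length(absent) > 0L) {
    stop("format error in ", toupper(tab), " file '", path,
         "': missing required column(s) ", paste(absent, collapse = ", "))
  }
  df
}

.empty_faers_table <- function(tab) {
  cols <- .FAERS_REQUIRED_COLS[[tab]]
  df <- as.data.frame(matrix(character(0), nrow = 0, ncol = length(cols)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Classify completeness of a raw FAERS date string
#'
#' FAERS dates are written as 8 (YYYYMMDD), 6 (YYYYMM) or 4 (YYYY) digit
#' strings. Only full 8-digit dates support calendar arithmetic.
#'
#' @param x Character vector of raw date strings.
#' @return Character vector: `"full"`, `"partial"` or `"missing"`.
#' @export
date_completeness <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("missing", length(x))
  digits <- grepl("^[0-9]+$", x)
  out[digits & nchar(x) %in% c(4L, 6L)] <- "partial"
  full <- digits & nchar(x) == 8L
  if (any(full)) {
    valid <- !is.na(as.Date(x[full], format = "%Y%m%d"))
    out[full] <- ifelse(valid, "full", "partial")
  }
  out
}

#' Deduplicate FAERS cases
#'
#' Collapses multiple versions of the same case: among rows sharing a CASEID
#' only the one with the most recent FDA receive date (FDA_DT) survives; on
#' ties of CASEID and FDA_DT the highest PRIMARYID is retained. Child tables
#' (DRUG/REAC/THER/INDI) are restricted to surviving PRIMARYIDs. Idempotent.
#'
#' @param raw A `faers_raw` object.
#' @return A deduplicated `faers_raw`; attribute `n_removed` counts dropped
#'   demo rows.
#' @export
deduplicate_reports <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- raw$demo
  if (nrow(demo) == 0L) return(raw)
  if (any(!nzchar(trimws(demo$caseid))) || any(!nzchar(trimws(demo$primaryid)))) {
    stop("deduplication requires non-missing caseid and primaryid")
  }
  fda <- suppressWarnings(as.numeric(demo$fda_dt))
  if (anyNA(fda)) {
    warning("missing fda_dt on ", sum(is.na(fda)),
            " demo row(s); falling back to primaryid ordering")
    fda[is.na(fda)] <- -Inf
  }
  pid <- suppressWarnings(as.numeric(demo$primaryid))
  ord <- order(demo$caseid, fda, pid)
  demo_sorted <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo_sorted$caseid, fromLast = TRUE)
  survivors <- demo_sorted[keep, , drop = FALSE]
  n_removed <- nrow(demo) - nrow(survivors)
  ids <- survivors$primaryid
  out <- list(
    demo = survivors,
    drug = raw$drug[raw$drug$primaryid %in% ids, , drop = FALSE],
    reac = raw$reac[raw$reac$primaryid %in% ids, , drop = FALSE],
    ther = raw$ther[raw$ther$primaryid %in% ids, , drop = FALSE],
    indi = raw$indi[raw$indi$primaryid %in% ids, , drop = FALSE]
  )
  structure(out, class = "faers_raw", n_removed = n_removed)
}

#' Normalise a drug name
#'
#' Upper-cases, strips punctuation, squeezes whitespace, then resolves exact
#' matches against a synonym table. No fuzzy matching.
#'
#' @param x Character vector of raw drug names.
#' @param synonyms Optional two-column data frame (`term`, `canonical`) or a
#'   named character vector mapping normalised term to canonical label.
#' @export
normalize_drug_name <- function(x, synonyms = NULL) {
  y <- toupper(trimws(x))
  y <- gsub("[[:punct:]]+", " ", y)
  y <- gsub("[[:space:]]+", " ", y)
  y <- trimws(y)
  if (!is.null(synonyms)) {
    if (is.data.frame(synonyms)) {
      map <- stats::setNames(toupper(trimws(synonyms[[2]])),
                             toupper(trimws(synonyms[[1]])))
    } else {
      map <- stats::setNames(toupper(synonyms), toupper(names(synonyms)))
    }
    hit <- y %in% names(map)
    y[hit] <- unname(map[y[hit]])
  }
  y
}

# Age-unit conversion factors to years (FAERS age_cod convention).
.AGE_UNIT_FACTOR <- c(YR = 1, MON = 1 / 12, WK = 1 / 52.143,
                      DY = 1 / 365.25, DEC = 10, HR = 1 / 8766)

#' Convert FAERS age/age_cod to years
#'
#' @param age Character or numeric vector of ages.
#' @param age_cod Unit codes (`YR`, `MON`, `WK`, `DY`, `DEC`, `HR`). A
#'   missing or unknown code with age present is treated as years, with a
#'   warning.
#' @return Numeric vector of ages in years (`NA` where age missing/invalid).
#' @export
age_to_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  fac <- .AGE_UNIT_FACTOR[cod]
  unknown <- !is.na(a) & (is.na(fac) | !nzchar(cod))
  if (any(unknown, na.rm = TRUE)) {
    warning(sum(unknown), " age value(s) with missing/unknown unit code; ",
            "treated as years")
    fac[unknown] <- 1
  }
  out <- a * as.numeric(fac)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Assign age-group labels
#'
#' Half-open bins `[0,18)`, `[18,65)`, `[65,85)`, `[85,Inf)` labelled
#' `"<18"`, `"18-64.9"`, `"65-84.9"`, `">85"`.
#'
#' @param age_years Numeric vector of ages in years.
#' @export
age_group_label <- function(age_years) {
  as.character(cut(age_years, breaks = c(0, 18, 65, 85, Inf),
                   labels = c("<18", "18-64.9", "65-84.9", ">85"),
                   right = FALSE, include.lowest = TRUE))
}

#' Classify the reporter occupation code
#'
#' `MD`, `PH`, `HP`, `RN`, `OT` map to `"healthcare-professional"`; `CN`,
#' `LW` to `"non-healthcare-professional"`; anything else is missing.
#'
#' @param occp_cod Character vector of occupation codes.
#' @export
reporter_class <- function(occp_cod) {
  cod <- toupper(trimws(as.character(occp_cod)))
  out <- rep(NA_character_, length(cod))
  out[cod %in% c("MD", "PH", "HP", "RN", "OT")] <- "healthcare-professional"
  out[cod %in% c("CN", "LW")] <- "non-healthcare-professional"
  out
}

#' Read a PT-to-SOC event hierarchy table
#'
#' @param path CSV with two columns: preferred term, system organ class.
#' @return Object of class `event_hierarchy` (a data frame `pt`, `soc`,
#'   upper-cased PT labels, one SOC per PT).
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_hierarchy(df[[1]], df[[2]])
}

#' Construct an event hierarchy from PT and SOC vectors
#'
#' @param pt,soc Character vectors of equal length; each PT must map to a
#'   single SOC (primary-SOC convention).
#' @export
event_hierarchy <- function(pt, soc) {
  df <- unique(data.frame(pt = toupper(trimws(pt)), soc = trimws(soc),
                          stringsAsFactors = FALSE))
  if (anyDuplicated(df$pt)) {
    stop("event hierarchy maps some PT to more than one SOC")
  }
  structure(df, class = c("event_hierarchy", "data.frame"))
}

#' Map PT labels to SOC labels through a hierarchy
#'
#' PTs absent from the hierarchy are routed to the `"UNMAPPED"` bucket
#' (never dropped).
#'
#' @param pt Character vector of PT labels.
#' @param hierarchy An `event_hierarchy`.
#' @export
map_pt_to_soc <- function(pt, hierarchy) {
  idx <- match(toupper(trimws(pt)), hierarchy$pt)
  out <- hierarchy$soc[idx]
  out[is.na(idx)] <- "UNMAPPED"
  out
}

#' Assemble normalised safety reports from deduplicated raw tables
#'
#' Builds the columnar per-case representation used by all downstream
#' modules: one demographic row per case, a drug table with roles and
#' therapy-start dates resolved from THER by drug sequence, and a
#' report-by-PT event table (duplicate PTs within a report collapsed to a
#' set). Every exclusion or unmapped term is counted in the attached log,
#' never silently dropped.
#'
#' @param raw A deduplicated `faers_raw`.
#' @param synonyms Optional drug-synonym table (see [normalize_drug_name()]).
#' @param hierarchy Optional `event_hierarchy`; when supplied each event row
#'   also carries its SOC (`"UNMAPPED"` when absent from the hierarchy).
#' @return Object of class `safety_reports`: list with data frames `demo`
#'   (primaryid, caseid, fda_dt, event_dt, sex, age_years, age_group,
#'   reporter_class, country, report_year), `drugs` (primaryid, name, role,
#'   therapy_start) and `events` (primaryid, pt, soc), plus a `log`
#'   attribute of exclusion counts.
#' @export
assemble_reports <- function(raw, synonyms = NULL, hierarchy = NULL) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- raw$demo
  sex <- toupper(trimws(demo$sex))
  sex[!sex %in% c("M", "F")] <- NA_character_
  age_years <- age_to_years(demo$age, demo$age_cod)
  fda <- trimws(demo$fda_dt)
  report_year <- ifelse(grepl("^[0-9]{4}", fda),
                        as.integer(substr(fda, 1, 4)), NA_integer_)
  country <- toupper(trimws(demo$reporter_country))
  country[!nzchar(country)] <- NA_character_
  demo_out <- data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = fda,
    event_dt = trimws(demo$event_dt),
    sex = sex,
    age_years = age_years,
    age_group = age_group_label(age_years),
    reporter_class = reporter_class(demo$occp_cod),
    country = country,
    report_year = report_year,
    stringsAsFactors = FALSE
  )

  drug <- raw$drug
  role <- toupper(trimws(drug$role_cod))
  role[!role %in% c("PS", "SS", "C", "I")] <- NA_character_
  ther <- raw$ther
  ther_key <- paste(ther$primaryid, trimws(ther$dsg_drug_seq))
  drug_key <- paste(drug$primaryid, trimws(drug$drug_seq))
  start <- trimws(ther$start_dt)[match(drug_key, ther_key)]
  drugs_out <- data.frame(
    primaryid = drug$primaryid,
    name = normalize_drug_name(drug$drugname, synonyms),
    role = role,
    therapy_start = start,
    stringsAsFactors = FALSE
  )

  reac <- raw$reac
  ev <- data.frame(primaryid = reac$primaryid,
                   pt = toupper(trimws(reac$pt)),
                   stringsAsFactors = FALSE)
  ev <- ev[nzchar(ev$pt), , drop = FALSE]
  n_raw_pairs <- nrow(ev)
  ev <- unique(ev)
  n_collapsed <- n_raw_pairs - nrow(ev)
  if (!is.null(hierarchy)) {
    ev$soc <- map_pt_to_soc(ev$pt, hierarchy)
  } else {
    ev$soc <- NA_character_
  }
  n_unmapped <- sum(ev$soc == "UNMAPPED", na.rm = TRUE)

  # conservation: keep only events/drugs whose case exists
  orphan_ev <- !ev$primaryid %in% demo_out$primaryid
  if (any(orphan_ev)) warning(sum(orphan_ev), " event row(s) without a demo row dropped")
  ev <- ev[!orphan_ev, , drop = FALSE]

  no_event <- !demo_out$primaryid %in% ev$primaryid
  if (any(no_event)) {
    warning(sum(no_event), " report(s) without any coded event excluded")
  }
  demo_out <- demo_out[!no_event, , drop = FALSE]
  drugs_out <- drugs_out[drugs_out$primaryid %in% demo_out$primaryid, , drop = FALSE]

  structure(
    list(demo = demo_out, drugs = drugs_out, events = ev),
    class = "safety_reports",
    log = list(n_reports = nrow(demo_out),
               n_event_pairs = nrow(ev),
               n_duplicate_pts_collapsed = n_collapsed,
               n_unmapped_pts = n_unmapped,
               n_reports_no_event = sum(no_event))
  )
}

#' @export
print.safety_reports <- function(x, ...) {
  cat("<safety_reports> ", nrow(x$demo), " reports, ",
      nrow(x$events), " report-PT pairs, ",
      nrow(x$drugs), " drug entries\n", sep = "")
  invisible(x)
}

#' Number of reports in a `safety_reports` object
#' @param x A `safety_reports`.
#' @export
n_reports <- function(x) nrow(x$demo)

#' Subset a `safety_reports` object by PRIMARYID
#'
#' @param x A `safety_reports`.
#' @param primaryids Character vector of case identifiers to keep.
#' @export
subset_reports <- function(x, primaryids) {
  structure(
    list(demo = x$demo[x$demo$primaryid %in% primaryids, , drop = FALSE],
         drugs = x$drugs[x$drugs$primaryid %in% primaryids, , drop = FALSE],
         events = x$events[x$events$primaryid %in% primaryids, , drop = FALSE]),
    class = "safety_reports"
  )
}

#' Split a corpus into index and background cohorts
#'
#' The index cohort holds reports with the index drug in the primary-suspect
#' (PS) role, optionally restricted to reports whose PS-drug indication is in
#' `indication_filter`; all remaining reports form the background. The two
#' partitions cover the corpus.
#'
#' @param reports A `safety_reports` corpus.
#' @param index_drug Canonical (normalised) drug label.
#' @param indication_filter Optional character vector of indication PTs; when
#'   supplied, requires the raw INDI rows via `indi`.
#' @param indi Optional INDI data frame (primaryid, indi_drug_seq, indi_pt)
#'   used only with `indication_filter`.
#' @return List with `safety_reports` elements `index` and `background`.
#' @export
select_index_cohort <- function(reports, index_drug, indication_filter = NULL,
                                indi = NULL) {
  stopifnot(inherits(reports, "safety_reports"))
  d <- reports$drugs
  idx_ids <- unique(d$primaryid[d$name == index_drug & !is.na(d$role) &
                                  d$role == "PS"])
  if (!is.null(indication_filter)) {
    if (is.null(indi)) stop("indication_filter requires the INDI table")
    ind <- toupper(trimws(indi$indi_pt))
    ok_ids <- unique(indi$primaryid[ind %in% toupper(indication_filter)])
    idx_ids <- intersect(idx_ids, ok_ids)
  }
  if (length(idx_ids) == 0L) {
    stop("index cohort is empty: no report has ", index_drug,
         " as primary suspect", if (!is.null(indication_filter))
           " with a matching indication" else "")
  }
  bg_ids <- setdiff(reports$demo$primaryid, idx_ids)
  list(index = subset_reports(reports, idx_ids),
       background = subset_reports(reports, bg_ids))
}

#' Read a drug-synonym table
#'
#' @param path CSV with two columns: reported term, canonical label.
#' @export
read_synonyms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df[[2]], normalize_drug_name(df[[1]]))
}
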