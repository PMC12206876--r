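# Hand-built fixtures shared across the suite. Everything is constructed in
# code; no binary data.

# Assemble a faers_raw from partial tables, filling unspecified ones empty.
make_raw <- function(demo = NULL, drug = NULL, reac = NULL, ther = NULL,
                     indi = NULL) {
  blank <- pvsignal:::.empty_faers_table
  fill <- function(x, tab) {
    if (is.null(x)) return(blank(tab))
    x[] <- lapply(x, as.character)
    x
  }
  structure(list(demo = fill(demo, "demo"), drug = fill(drug, "drug"),
                 reac = fill(reac, "reac"), ther = fill(ther, "ther"),
                 indi = fill(indi, "indi")),
            class = "faers_raw")
}

demo_row <- function(primaryid, caseid = primaryid, fda_dt = "20230101",
                     event_dt = "", age = "", age_cod = "", sex = "",
                     occp_cod = "", reporter_country = "") {
  data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
             event_dt = event_dt, age = age, age_cod = age_cod, sex = sex,
             occp_cod = occp_cod, reporter_country = reporter_country,
             stringsAsFactors = FALSE)
}

# Four-report corpus: index reports carry {E1,E2} and {E1}; background
# reports carry {E1} and {E2,E3}. Pair-level table for E1 is then
# a=2, b=1, c=1, d=2, N=6.
four_report_corpus <- function() {
  demo <- do.call(rbind, lapply(1:4, function(i) demo_row(as.character(i))))
  drug <- data.frame(
    primaryid = as.character(1:4), drug_seq = "1",
    role_cod = c("PS", "PS", "PS", "PS"),
    drugname = c("INDEXDRUG", "INDEXDRUG", "OTHER A", "OTHER B"),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c("1", "1", "2", "3", "4", "4"),
    pt = c("E1", "E2", "E1", "E1", "E2", "E3"),
    stringsAsFactors = FALSE)
  assemble_reports(make_raw(demo = demo, drug = drug, reac = reac))
}

# Random 2x2 tables with strictly positive cells, for property checks.
random_tables <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(a = sample(1:200, n, TRUE), b = sample(1:2000, n, TRUE),
             c = sample(1:2000, n, TRUE), d = sample(1:20000, n, TRUE))
}

# Assembled-format demographic row (the columns assemble_reports produces).
assembled_demo_row <- function(primaryid, caseid = primaryid,
                               fda_dt = "20230101", event_dt = "",
                               sex = NA_character_, age_years = NA_real_,
                               reporter_class = NA_character_,
                               country = NA_character_,
                               report_year = 2023L) {
  data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
             event_dt = event_dt, sex = sex, age_years = age_years,
             age_group = age_group_label(age_years),
             reporter_class = reporter_class, country = country,
             report_year = report_year, stringsAsFactors = FALSE)
}

# Direct construction of a safety_reports object (bypassing raw tables).
make_reports <- function(demo, drugs = NULL, events) {
  if (is.null(drugs)) {
    drugs <- data.frame(primaryid = character(0), name = character(0),
                        role = character(0), therapy_start = character(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(demo = demo, drugs = drugs, events = events),
            class = "safety_reports")
}
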