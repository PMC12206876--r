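# Parsing, deduplication and report assembly.

test_that("quarterly ASCII tables parse with the '$' dialect", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$reporter_country",
               "1$100$20230101$20230215$65$YR$M$MD$US",
               "2$101$20230301$202302$70$YR$F$CN$DE",
               "3$102$20230401$$$$$$"),
             file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname",
               "1$1$PS$CARBOPLATIN"), file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", "1$Anaemia"), file.path(dir, "REAC.txt"))
  writeLines(c("primaryid$dsg_drug_seq$start_dt",
               "1$1$20230120"), file.path(dir, "THER.txt"))
  raw <- read_faers_quarter(list(
    demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"), ther = file.path(dir, "THER.txt")))
  expect_s3_class(raw, "faers_raw")
  expect_equal(nrow(raw$demo), 3L)
  # dates stay raw strings; completeness derived from digit count
  expect_equal(date_completeness(raw$demo$event_dt),
               c("full", "partial", "missing"))

  # a required column missing is a format error naming file and column
  writeLines(c("primaryid$drug_seq$drugname", "1$1$X"),
             file.path(dir, "DRUG.txt"))
  expect_error(read_faers_quarter(list(
    demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"), ther = file.path(dir, "THER.txt"))),
    "role_cod")

  # an empty file yields an empty table with a warning
  writeLines(character(0), file.path(dir, "REAC.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname", "1$1$PS$X"),
             file.path(dir, "DRUG.txt"))
  expect_warning(raw2 <- read_faers_quarter(list(
    demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"), ther = file.path(dir, "THER.txt"))),
    "empty")
  expect_equal(nrow(raw2$reac), 0L)
})

test_that("deduplication keeps the latest FDA_DT, then the highest PRIMARYID", {
  # most recent receive date wins regardless of primaryid ordering
  raw <- make_raw(demo = rbind(
    demo_row("1001", caseid = "100", fda_dt = "20230101"),
    demo_row("1000", caseid = "100", fda_dt = "20230601")))
  dd <- deduplicate_reports(raw)
  expect_equal(dd$demo$primaryid, "1000")

  # on an FDA_DT tie the higher primaryid survives
  raw <- make_raw(demo = rbind(
    demo_row("5", caseid = "7", fda_dt = "20230101"),
    demo_row("9", caseid = "7", fda_dt = "20230101")))
  expect_equal(deduplicate_reports(raw)$demo$primaryid, "9")

  # a unique case passes through unchanged, and dedup is idempotent
  raw <- make_raw(demo = demo_row("42", caseid = "8"),
                  reac = data.frame(primaryid = "42", pt = "E1"))
  once <- deduplicate_reports(raw)
  expect_equal(once$demo, raw$demo)
  twice <- deduplicate_reports(once)
  expect_equal(attr(twice, "n_removed"), 0L)
  expect_equal(twice$demo, once$demo)

  # missing fda_dt falls back to primaryid ordering with a warning
  raw <- make_raw(demo = rbind(
    demo_row("3", caseid = "1", fda_dt = ""),
    demo_row("8", caseid = "1", fda_dt = "")))
  expect_warning(dd <- deduplicate_reports(raw), "fda_dt")
  expect_equal(dd$demo$primaryid, "8")
})

test_that("within each duplicate cluster the survivor maximises (fda_dt, primaryid)", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 60
    demo <- demo_row(as.character(sample(1000:9999, n)),
                     caseid = as.character(sample(1:15, n, TRUE)),
                     fda_dt = format(as.Date("2020-01-01") +
                                       sample(0:1000, n, TRUE), "%Y%m%d"))
    dd <- deduplicate_reports(make_raw(demo = demo))
    expect_false(anyDuplicated(dd$demo$caseid) > 0)
    split_fda <- split(seq_len(n), demo$caseid)
    for (cid in names(split_fda)) {
      rows <- demo[split_fda[[cid]], ]
      best <- rows[order(rows$fda_dt, as.numeric(rows$primaryid),
                         decreasing = TRUE)[1], ]
      expect_true(best$primaryid %in% dd$demo$primaryid)
    }
    # idempotence on every generated cluster set
    expect_identical(deduplicate_reports(dd)$demo, dd$demo)
  }
})

test_that("assembly normalises drugs, ages, reporters and terms", {
  demo <- rbind(
    demo_row("1", fda_dt = "20230415", age = "780", age_cod = "MON",
             sex = "f", occp_cod = "CN", reporter_country = "US"),
    demo_row("2", fda_dt = "20181101", age = "58", age_cod = "YR",
             sex = "M", occp_cod = "MD"))
  drug <- data.frame(primaryid = c("1", "2"), drug_seq = "1",
                     role_cod = "PS",
                     drugname = c("  paraplatin ", "CARBOPLATIN."),
                     stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1", "1", "1", "2"),
                     pt = c("Anaemia", "ANAEMIA", "Nausea", "WEIRD TERM"),
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = "1", dsg_drug_seq = "1",
                     start_dt = "20230120", stringsAsFactors = FALSE)
  hier <- event_hierarchy(c("ANAEMIA", "NAUSEA"),
                          c("Blood disorders", "GI disorders"))
  rep <- assemble_reports(make_raw(demo, drug, reac, ther),
                          synonyms = c(PARAPLATIN = "CARBOPLATIN"),
                          hierarchy = hier)

  expect_setequal(rep$drugs$name, "CARBOPLATIN")  # synonym + punctuation
  expect_equal(rep$demo$age_years, c(65, 58))     # 780 months -> 65 years
  expect_equal(rep$demo$age_group, c("65-84.9", "18-64.9"))
  expect_equal(rep$demo$reporter_class,
               c("non-healthcare-professional", "healthcare-professional"))
  expect_equal(rep$demo$sex, c("F", "M"))
  expect_equal(rep$demo$report_year, c(2023L, 2018L))
  expect_equal(rep$drugs$therapy_start[rep$drugs$primaryid == "1"],
               "20230120")

  # duplicate PTs collapse to a set; unmapped PTs are bucketed, not dropped
  ev1 <- rep$events[rep$events$primaryid == "1", ]
  expect_setequal(ev1$pt, c("ANAEMIA", "NAUSEA"))
  expect_equal(rep$events$soc[rep$events$pt == "WEIRD TERM"], "UNMAPPED")
  log <- attr(rep, "log")
  expect_equal(log$n_duplicate_pts_collapsed, 1L)
  expect_equal(log$n_unmapped_pts, 1L)
  expect_equal(log$n_event_pairs, nrow(rep$events))
})

test_that("age unit conversion follows the FAERS unit table", {
  expect_equal(age_to_years(c("780", "65", "10", "7305"),
                            c("MON", "YR", "DEC", "DY")),
               c(65, 65, 100, 20), tolerance = 1e-6)
  expect_warning(out <- age_to_years("50", ""), "unknown")
  expect_equal(out, 50)
  expect_true(is.na(age_to_years("-4", "YR")))  # negative ages invalid
})

test_that("index cohort selection partitions the corpus by PS role", {
  demo <- do.call(rbind, lapply(1:3, function(i) demo_row(as.character(i))))
  drug <- data.frame(
    primaryid = c("1", "2", "3"), drug_seq = "1",
    role_cod = c("PS", "C", "PS"),
    drugname = c("CARBOPLATIN", "CARBOPLATIN", "CISPLATIN"),
    stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1", "2", "3"), pt = "E1",
                     stringsAsFactors = FALSE)
  rep <- assemble_reports(make_raw(demo, drug, reac))
  co <- select_index_cohort(rep, "CARBOPLATIN")
  expect_equal(co$index$demo$primaryid, "1")         # PS role only
  expect_setequal(co$background$demo$primaryid, c("2", "3"))
  # union is the corpus, intersection empty
  expect_setequal(c(co$index$demo$primaryid, co$background$demo$primaryid),
                  rep$demo$primaryid)
  expect_length(intersect(co$index$demo$primaryid,
                          co$background$demo$primaryid), 0)
  expect_error(select_index_cohort(rep, "NOSUCHDRUG"), "empty")

  # indication filter routes non-matching PS reports to the background
  indi <- data.frame(primaryid = "1", indi_drug_seq = "1",
                     indi_pt = "SMALL CELL LUNG CANCER",
                     stringsAsFactors = FALSE)
  expect_error(
    select_index_cohort(rep, "CARBOPLATIN",
                        indication_filter = "NON-SMALL CELL LUNG CANCER",
                        indi = indi),
    "empty")
  indi$indi_pt <- "NON-SMALL CELL LUNG CANCER"
  co2 <- select_index_cohort(rep, "CARBOPLATIN",
                             indication_filter = "NON-SMALL CELL LUNG CANCER",
                             indi = indi)
  expect_equal(co2$index$demo$primaryid, "1")
})
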