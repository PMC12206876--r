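# Synthetic FAERS-like corpus generator with ground-truth sidecar.
#
# Emulates the structure a spontaneous-report analysis assumes: per-case
# demographics with missingness, one primary-suspect drug plus concomitant
# drugs, multiple coded events per report (independent per-PT sampling given
# the drug), duplicate case versions collapsible by the dedup rule, and
# therapy-start/onset dates whose difference follows a Weibull law.

#' Configuration for a synthetic spontaneous-report corpus
#'
#' Defaults emulate the corpus shape of a carboplatin-style analysis: about
#' three coded events per report, sex mix and missingness as in typical
#' oncology cohorts, onset law Weibull(scale 51.72 d, shape 0.78). Event
#' probabilities default to a Zipf-like background over the PT vocabulary.
#' Identical configurations (including `seed`) yield byte-identical output.
#'
#' @param n_reports Number of unique cases.
#' @param n_pt,n_soc Vocabulary size: PTs, and SOCs they map to (round-robin).
#' @param background_event_probs Optional probability vector over PTs
#'   (normalised internally); default Zipf (`p_k` proportional to `1/k`).
#' @param drug_pool Background primary-suspect drug labels.
#' @param index_drug Canonical index-drug label.
#' @param p_index Probability a report has the index drug as primary suspect.
#' @param planted_signals `NULL` or a data frame with columns `pt`, `rr` and
#'   optionally `sex` (`"M"`/`"F"`/`NA`), `age_min`, `age_max`: the PT's
#'   inclusion probability in matching index reports is multiplied by `rr`
#'   (per-report renormalised so the expected event count is unchanged).
#' @param events_per_report_mean Target mean number of distinct PTs/report.
#' @param duplicate_rate Probability a case also emits a superseded earlier
#'   version (same CASEID, lower PRIMARYID, earlier-or-equal FDA_DT).
#' @param missing_rates Named list of per-field missingness probabilities
#'   (`sex`, `age`, `event_dt`, `start_dt`, `country`, `occp`) plus
#'   `event_dt_partial`, the probability of a year-month-only onset date.
#' @param demo_model Named list: `p_male` (among observed), `age_mean`,
#'   `age_sd`, `countries` and `occp` categorical probability vectors.
#' @param tto_law Named vector `c(scale=, shape=)` of the Weibull onset law.
#' @param allowlist_partners Partner co-medications for sensitivity analyses.
#' @param partner_rate Probability an index report carries one partner drug.
#' @param other_conmed_rate Probability of one non-partner concomitant drug.
#' @param seed Integer seed; every random draw flows from it.
#' @export
synth_config <- function(n_reports = 20000,
                         n_pt = 200, n_soc = 20,
                         background_event_probs = NULL,
                         drug_pool = sprintf("BACKGROUND DRUG %02d", 1:30),
                         index_drug = "CARBOPLATIN",
                         p_index = 0.25,
                         planted_signals = NULL,
                         events_per_report_mean = 3.1,
                         duplicate_rate = 0.05,
                         missing_rates = list(),
                         demo_model = list(),
                         tto_law = c(scale = 51.72, shape = 0.78),
                         allowlist_partners = c("GEMCITABINE", "PEMETREXED",
                                                "DOCETAXEL", "PACLITAXEL",
                                                "VINORELBINE", "PEMBROLIZUMAB",
                                                "ATEZOLIZUMAB", "AMIVANTAMAB"),
                         partner_rate = 0.5,
                         other_conmed_rate = 0.25,
                         seed = 1L) {
  mr <- utils::modifyList(list(sex = 0.229, age = 0.297, event_dt = 0.45,
                               event_dt_partial = 0.03, start_dt = 0.10,
                               country = 0.03, occp = 0.02), missing_rates)
  dm <- utils::modifyList(
    list(p_male = 0.604, age_mean = 66, age_sd = 13.3,
         countries = c(US = 0.233, DE = 0.218, JP = 0.091, GB = 0.070,
                       FR = 0.063, OTHER = 0.325),
         occp = c(MD = 0.45, PH = 0.20, HP = 0.15, RN = 0.11,
                  CN = 0.07, LW = 0.02)),
    demo_model)
  pts <- sprintf("PT %03d", seq_len(n_pt))
  if (is.null(background_event_probs)) {
    background_event_probs <- 1 / seq_len(n_pt)
  }
  if (length(background_event_probs) != n_pt ||
      any(background_event_probs < 0) || sum(background_event_probs) <= 0) {
    stop("invalid background_event_probs")
  }
  background_event_probs <- background_event_probs / sum(background_event_probs)
  if (!is.null(planted_signals)) {
    planted_signals <- as.data.frame(planted_signals)
    if (!all(c("pt", "rr") %in% names(planted_signals)) ||
        any(planted_signals$rr <= 0)) {
      stop("planted_signals needs columns pt, rr with rr > 0")
    }
    for (col in c("sex", "age_min", "age_max")) {
      if (is.null(planted_signals[[col]])) planted_signals[[col]] <- NA
    }
    if (!all(planted_signals$pt %in% pts)) {
      stop("planted_signals refer to PTs outside the vocabulary")
    }
  }
  structure(list(
    n_reports = n_reports, pts = pts, n_soc = n_soc,
    background_event_probs = background_event_probs,
    drug_pool = toupper(drug_pool), index_drug = toupper(index_drug),
    p_index = p_index, planted_signals = planted_signals,
    events_per_report_mean = events_per_report_mean,
    duplicate_rate = duplicate_rate, missing_rates = mr, demo_model = dm,
    tto_law = tto_law, allowlist_partners = toupper(allowlist_partners),
    partner_rate = partner_rate, other_conmed_rate = other_conmed_rate,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' PT-to-SOC hierarchy of a synthetic vocabulary
#'
#' PTs map round-robin onto `n_soc` system organ classes.
#'
#' @param config A [synth_config()].
#' @export
synth_hierarchy <- function(config) {
  soc <- sprintf("SOC %02d", (seq_along(config$pts) - 1L) %% config$n_soc + 1L)
  event_hierarchy(config$pts, soc)
}

#' Generate a synthetic FAERS-like corpus
#'
#' Draws a corpus per the configuration and returns it as parsed raw tables
#' plus a ground-truth sidecar. When `dir` is given, the DEMO/DRUG/REAC/THER
#' tables are also written as '$'-delimited ASCII files (the dialect
#' [read_faers_quarter()] reads) together with `truth.json`.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory.
#' @return Invisibly, a list with `raw` (a `faers_raw`), `truth` (list:
#'   index survivor primaryids, planted signals, duplicate caseids, per-case
#'   true strata) and `hierarchy`.
#' @export
generate_corpus <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_reports
  pts <- config$pts
  K <- length(pts)
  bg <- config$background_event_probs
  mr <- config$missing_rates
  dm <- config$demo_model

  is_index <- stats::runif(n) < config$p_index
  sex_true <- ifelse(stats::runif(n) < dm$p_male, "M", "F")
  age_true <- pmin(pmax(stats::rnorm(n, dm$age_mean, dm$age_sd), 1), 100)

  # per-PT relative-risk multipliers for index reports, with per-report
  # renormalisation so the expected event count stays constant
  rr_mat_extra <- rep(0, n)  # sum_k bg_k (rr_k - 1) applicable to report
  plant <- config$planted_signals
  applicable <- NULL
  if (!is.null(plant) && nrow(plant) > 0) {
    applicable <- matrix(FALSE, n, nrow(plant))
    for (s in seq_len(nrow(plant))) {
      ok <- is_index
      if (!is.na(plant$sex[s])) ok <- ok & sex_true == plant$sex[s]
      if (!is.na(plant$age_min[s])) ok <- ok & age_true >= plant$age_min[s]
      if (!is.na(plant$age_max[s])) ok <- ok & age_true < plant$age_max[s]
      applicable[, s] <- ok
      k <- match(plant$pt[s], pts)
      rr_mat_extra <- rr_mat_extra + bg[k] * (plant$rr[s] - 1) * ok
    }
  }
  renorm <- 1 / (1 + rr_mat_extra)

  mu <- config$events_per_report_mean
  pair_rid <- integer(0)
  pair_pt <- integer(0)
  for (k in seq_len(K)) {
    p <- rep(bg[k] * mu, n)
    if (!is.null(plant)) {
      hit_s <- which(plant$pt == pts[k])
      for (s in hit_s) p <- p * ifelse(applicable[, s], plant$rr[s], 1)
    }
    p <- pmin(p * renorm, 0.95)
    hit <- which(stats::runif(n) < p)
    pair_rid <- c(pair_rid, hit)
    pair_pt <- c(pair_pt, rep(k, length(hit)))
  }
  # ensure every report carries at least one event
  empty <- setdiff(seq_len(n), unique(pair_rid))
  if (length(empty) > 0) {
    pair_rid <- c(pair_rid, empty)
    pair_pt <- c(pair_pt, sample.int(K, length(empty), replace = TRUE,
                                     prob = bg))
  }
  ord <- order(pair_rid, pair_pt)
  pair_rid <- pair_rid[ord]; pair_pt <- pair_pt[ord]

  # identifiers: survivor primaryid ends in 5, a superseded version in 1
  base_id <- 1000000 + seq_len(n)
  caseid <- as.character(base_id)
  pid <- as.character(base_id * 10 + 5)

  day0 <- as.Date("2004-01-01")
  day1 <- as.Date("2024-09-30")
  fda_date <- day0 + sample.int(as.integer(day1 - day0), n, replace = TRUE)
  start_date <- fda_date - sample.int(120, n, replace = TRUE)
  tto_true <- ceiling(stats::rweibull(n, shape = config$tto_law[["shape"]],
                                      scale = config$tto_law[["scale"]]))
  event_date <- start_date + tto_true
  # a few onsets precede therapy start, exercising the exclusion rule
  backwards <- stats::runif(n) < 0.02
  event_date[backwards] <- start_date[backwards] - sample.int(10, sum(backwards),
                                                              replace = TRUE)

  fmt <- function(d) format(d, "%Y%m%d")
  event_dt <- fmt(event_date)
  partial <- stats::runif(n) < mr$event_dt_partial
  event_dt[partial] <- substr(event_dt[partial], 1, 6)
  event_dt[stats::runif(n) < mr$event_dt] <- ""
  start_dt <- fmt(start_date)
  start_dt[stats::runif(n) < mr$start_dt] <- ""

  sex <- sex_true
  sex[stats::runif(n) < mr$sex] <- ""
  age <- as.character(round(age_true))
  age_cod <- rep("YR", n)
  as_months <- stats::runif(n) < 0.03
  age[as_months] <- as.character(round(age_true[as_months] * 12))
  age_cod[as_months] <- "MON"
  miss_age <- stats::runif(n) < mr$age
  age[miss_age] <- ""
  age_cod[miss_age] <- ""
  country <- sample(names(dm$countries), n, replace = TRUE,
                    prob = dm$countries)
  country[stats::runif(n) < mr$country] <- ""
  occp <- sample(names(dm$occp), n, replace = TRUE, prob = dm$occp)
  occp[stats::runif(n) < mr$occp] <- ""

  demo <- data.frame(primaryid = pid, caseid = caseid, fda_dt = fmt(fda_date),
                     event_dt = event_dt, age = age, age_cod = age_cod,
                     sex = sex, occp_cod = occp, reporter_country = country,
                     stringsAsFactors = FALSE)

  ps_name <- ifelse(is_index, config$index_drug,
                    sample(config$drug_pool, n, replace = TRUE))
  drug <- data.frame(primaryid = pid, drug_seq = "1", role_cod = "PS",
                     drugname = ps_name, stringsAsFactors = FALSE)
  has_partner <- is_index & stats::runif(n) < config$partner_rate
  if (any(has_partner)) {
    drug <- rbind(drug, data.frame(
      primaryid = pid[has_partner], drug_seq = "2", role_cod = "C",
      drugname = sample(config$allowlist_partners, sum(has_partner),
                        replace = TRUE), stringsAsFactors = FALSE))
  }
  has_other <- stats::runif(n) < config$other_conmed_rate
  if (any(has_other)) {
    drug <- rbind(drug, data.frame(
      primaryid = pid[has_other], drug_seq = "3", role_cod = "C",
      drugname = sample(config$drug_pool, sum(has_other), replace = TRUE),
      stringsAsFactors = FALSE))
  }

  reac <- data.frame(primaryid = pid[pair_rid], pt = pts[pair_pt],
                     stringsAsFactors = FALSE)
  # FAERS REAC rows may repeat a term within a report
  rep_rows <- which(stats::runif(nrow(reac)) < 0.02)
  if (length(rep_rows) > 0) reac <- rbind(reac, reac[rep_rows, , drop = FALSE])

  ther <- data.frame(primaryid = pid, dsg_drug_seq = "1", start_dt = start_dt,
                     stringsAsFactors = FALSE)
  ther <- ther[nzchar(ther$start_dt), , drop = FALSE]

  # superseded earlier case versions sharing the CASEID
  dup <- which(stats::runif(n) < config$duplicate_rate)
  if (length(dup) > 0) {
    old_pid <- as.character(base_id[dup] * 10 + 1)
    same_day <- stats::runif(length(dup)) < 0.5
    old_fda <- fda_date[dup] - ifelse(same_day, 0L,
                                      sample.int(200, length(dup),
                                                 replace = TRUE))
    old_demo <- demo[dup, , drop = FALSE]
    old_demo$primaryid <- old_pid
    old_demo$fda_dt <- fmt(old_fda)
    demo <- rbind(demo, old_demo)
    remap <- function(df) {
      sub <- df[df$primaryid %in% pid[dup], , drop = FALSE]
      sub$primaryid <- old_pid[match(sub$primaryid, pid[dup])]
      rbind(df, sub)
    }
    drug <- remap(drug); reac <- remap(reac); ther <- remap(ther)
  }

  rownames(demo) <- rownames(drug) <- rownames(reac) <- rownames(ther) <- NULL
  raw <- structure(list(demo = demo, drug = drug, reac = reac, ther = ther,
                        indi = .empty_faers_table("indi")),
                   class = "faers_raw")
  truth <- list(
    seed = config$seed,
    n_reports = n,
    index_primaryids = pid[is_index],
    index_caseids = caseid[is_index],
    planted = if (is.null(plant)) list() else plant,
    duplicate_caseids = caseid[dup],
    duplicate_primaryids_superseded = if (length(dup)) as.character(base_id[dup] * 10 + 1) else character(0),
    sex_true = stats::setNames(sex_true, pid),
    tto_true = stats::setNames(tto_true, pid)
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    wr <- function(df, name) {
      utils::write.table(df, file.path(dir, name), sep = "$", quote = FALSE,
                         row.names = FALSE, col.names = TRUE, eol = "\n")
    }
    wr(demo, "DEMO.txt"); wr(drug, "DRUG.txt"); wr(reac, "REAC.txt")
    wr(ther, "THER.txt")
    truth_json <- truth
    truth_json$sex_true <- NULL
    truth_json$tto_true <- NULL
    truth_json$planted <- if (is.null(plant)) list() else plant
    jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(raw = raw, truth = truth, hierarchy = synth_hierarchy(config)))
}

#' Evaluate gated signals against the generator's ground truth
#'
#' Compares the `positive` flags of a PT-level signal table with the planted
#' PT set: sensitivity is the detected fraction of planted terms (overall
#' and per relative-risk value); the false-positive rate is the positive
#' fraction among non-planted terms meeting the policy's support floor.
#'
#' @param signals A gated PT-level signal table.
#' @param truth Ground-truth sidecar from [generate_corpus()] (or the parsed
#'   `truth.json`).
#' @param min_a Support floor used for the FPR denominator.
#' @export
truth_eval <- function(signals, truth, min_a = 3) {
  planted <- truth$planted
  planted_pts <- if (length(planted) && nrow(as.data.frame(planted)) > 0) {
    as.data.frame(planted)$pt
  } else character(0)
  pos <- signals$term[signals$positive]
  eligible_null <- signals$term[!signals$term %in% planted_pts &
                                  signals$a >= min_a]
  fpr <- if (length(eligible_null)) mean(eligible_null %in% pos) else NA_real_
  if (length(planted_pts) == 0) {
    return(list(sensitivity = NA_real_, fpr = fpr, per_signal = NULL))
  }
  pl <- as.data.frame(planted)
  pl$detected <- pl$pt %in% pos
  pl$a <- signals$a[match(pl$pt, signals$term)]
  list(sensitivity = mean(pl$detected), fpr = fpr, per_signal = pl)
}
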