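# Descriptive (Table 1-style) summary of the index cohort.

#' Summarise the clinical characteristics of a cohort
#'
#' Counts and display percentages (one decimal, full precision retained) by
#' sex, age bin, reporter class, top-k reporting countries and top-k
#' reporting years, plus the age median/IQR over reports with observed age.
#' Event counts use the (report, PT) pair unit, so `n_events >= n_reports`.
#'
#' @param reports An assembled `safety_reports` cohort.
#' @param k How many top countries/years to list.
#' @return Object of class `cohort_summary`: list with `n_reports`,
#'   `n_events`, `age_median`, `age_iqr`, and data frames `sex`, `age_group`,
#'   `reporter`, `countries`, `years` (`category`, `count`, `pct`,
#'   `pct_display`).
#' @export
summarize_cohort <- function(reports, k = 5) {
  stopifnot(inherits(reports, "safety_reports"))
  demo <- reports$demo
  n <- nrow(demo)
  if (n == 0L) warning("empty cohort; all-zero summary")

  cat_table <- function(x, levels = NULL, top_k = NULL) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- "missing"
    tab <- table(x)
    if (!is.null(levels)) {
      tab <- tab[match(c(levels, "missing"), names(tab))]
      names(tab) <- c(levels, "missing")
      tab[is.na(tab)] <- 0
    } else if (length(tab) > 0) {
      # sort by count descending, ties lexicographic
      tab <- tab[order(-as.numeric(tab), names(tab))]
      if (!is.null(top_k)) {
        tab <- tab[setdiff(names(tab), "missing")]
        tab <- utils::head(tab, top_k)
      }
    }
    pct <- if (n > 0) 100 * as.numeric(tab) / n else rep(0, length(tab))
    data.frame(category = names(tab), count = as.numeric(tab), pct = pct,
               pct_display = round(pct, 1), stringsAsFactors = FALSE,
               row.names = NULL)
  }

  ages <- demo$age_years[!is.na(demo$age_years)]
  qs <- if (length(ages)) stats::quantile(ages, c(0.25, 0.5, 0.75),
                                          names = FALSE)
  else rep(NA_real_, 3)

  structure(list(
    n_reports = n,
    n_events = nrow(unique(reports$events[c("primaryid", "pt")])),
    sex = cat_table(demo$sex, levels = c("M", "F")),
    age_group = cat_table(demo$age_group,
                          levels = c("<18", "18-64.9", "65-84.9", ">85")),
    reporter = cat_table(demo$reporter_class,
                         levels = c("healthcare-professional",
                                    "non-healthcare-professional")),
    countries = cat_table(demo$country, top_k = k),
    years = cat_table(demo$report_year, top_k = k),
    age_median = qs[2], age_iqr = c(qs[1], qs[3]),
    n_age_missing = sum(is.na(demo$age_years))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort: ", x$n_reports, " reports, ", x$n_events, " adverse events\n",
      sep = "")
  cat(sprintf("Age median (IQR): %s (%s, %s); %d missing\n",
              format(x$age_median), format(x$age_iqr[1]),
              format(x$age_iqr[2]), x$n_age_missing))
  for (nm in c("sex", "age_group", "reporter", "countries", "years")) {
    cat("\n", nm, ":\n", sep = "")
    df <- x[[nm]]
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-28s %6d  %5.1f%%\n", df$category[i], df$count[i],
                  df$pct_display[i]))
    }
  }
  invisible(x)
}

#' Flatten a cohort summary to a long data frame (CSV-ready)
#'
#' @param summary A `cohort_summary`.
#' @export
cohort_summary_table <- function(summary) {
  rows <- lapply(c("sex", "age_group", "reporter", "countries", "years"),
                 function(nm) cbind(dimension = nm, summary[[nm]]))
  out <- do.call(rbind, rows)
  rbind(data.frame(dimension = "total", category = "reports",
                   count = summary$n_reports, pct = 100, pct_display = 100),
        data.frame(dimension = "total", category = "events",
                   count = summary$n_events, pct = NA, pct_display = NA),
        out)
}
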