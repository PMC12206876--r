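# Disproportionality engine: 2x2 contingency tables at PT and SOC level and
# the frequentist/Bayesian statistics computed on them.
#
# The counting unit throughout is the (report, term) pair: a report with k
# distinct PTs contributes k pairs at PT level, and one pair per distinct
# SOC its PTs map to at SOC level. For a term t,
#   a = index-drug pairs with t, b = index-drug pairs with other terms,
#   c = background pairs with t, d = background pairs with other terms.

#' Build 2x2 contingency tables for every term at a hierarchy level
#'
#' @param index,background `safety_reports` cohorts (index drug as primary
#'   suspect vs the rest of the corpus).
#' @param level `"pt"` or `"soc"`. SOC tables require events carrying a SOC
#'   (assembled with a hierarchy) or an explicit `hierarchy` argument.
#' @param hierarchy Optional `event_hierarchy` used to (re)map PTs to SOCs.
#' @return Data frame with one row per term observed anywhere in the corpus:
#'   `term`, `level`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency_tables <- function(index, background, level = c("pt", "soc"),
                                     hierarchy = NULL) {
  level <- match.arg(level)
  if (n_reports(index) == 0L) stop("index cohort is empty")
  pairs_idx <- .term_pairs(index, level, hierarchy)
  pairs_bg <- .term_pairs(background, level, hierarchy)
  terms <- sort(unique(c(pairs_idx$term, pairs_bg$term)))
  a <- as.numeric(table(factor(pairs_idx$term, levels = terms)))
  c_ <- as.numeric(table(factor(pairs_bg$term, levels = terms)))
  tot_idx <- nrow(pairs_idx)
  tot_bg <- nrow(pairs_bg)
  data.frame(term = terms, level = level,
             a = a, b = tot_idx - a, c = c_, d = tot_bg - c_,
             n = tot_idx + tot_bg,
             stringsAsFactors = FALSE)
}

# distinct (report, term) pairs of a cohort at the requested level
.term_pairs <- function(reports, level, hierarchy = NULL) {
  ev <- reports$events
  if (level == "pt") {
    return(unique(data.frame(primaryid = ev$primaryid, term = ev$pt,
                             stringsAsFactors = FALSE)))
  }
  soc <- if (!is.null(hierarchy)) map_pt_to_soc(ev$pt, hierarchy) else ev$soc
  if (is.null(soc) || all(is.na(soc))) {
    stop("SOC-level tables need events assembled with an event hierarchy")
  }
  unique(data.frame(primaryid = ev$primaryid, term = soc,
                    stringsAsFactors = FALSE))
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a d)/(b c)` with the interval computed on the log scale,
#' `exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell triggers
#' the Haldane–Anscombe 0.5 continuity correction applied to all four cells,
#' flagged in the result.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param conf_level Confidence level for the Wald interval.
#' @return Data frame `ror`, `ror_low`, `ror_high`, `corrected`.
#' @export
ror_stat <- function(a, b, c, d, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  corrected <- (a == 0 | b == 0 | c == 0 | d == 0)
  a2 <- a + 0.5 * corrected
  b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected
  d2 <- d + 0.5 * corrected
  ror <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  data.frame(ror = ror,
             ror_low = exp(log(ror) - z * se),
             ror_high = exp(log(ror) + z * se),
             corrected = corrected)
}

#' Proportional reporting ratio with Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square statistic is the Pearson
#' form `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, optionally with the Yates
#' continuity correction. When `c = 0` the ratio is infinite (flagged) and
#' the chi-square falls back to 0.5-corrected cells.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param yates Apply the Yates continuity correction to the chi-square.
#' @return Data frame `prr`, `chi2`, `prr_undefined`.
#' @export
prr_stat <- function(a, b, c, d, yates = FALSE) {
  if (any(a + b <= 0) || any(c + d <= 0)) {
    stop("prr_stat requires a+b > 0 and c+d > 0")
  }
  undef <- c == 0
  prr <- (a / (a + b)) / (c / (c + d))
  prr[undef & a > 0] <- Inf
  prr[undef & a == 0] <- NaN
  chi2 <- .pearson_chi2(a + 0.5 * undef, b + 0.5 * undef,
                        c + 0.5 * undef, d + 0.5 * undef, yates = yates)
  data.frame(prr = prr, chi2 = chi2, prr_undefined = undef)
}

.pearson_chi2 <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(0, num - n / 2)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' BCPNN information component with lower credibility bound
#'
#' The shrunk observed-to-expected log2 ratio: with expected count
#' `E = (a+b)(a+c)/N`, `IC = log2((a + 0.5)/(E + 0.5))`, and the lower 2.5%
#' credibility bound via the Norén approximation
#' `IC025 = IC - 3.3 (a+0.5)^-1/2 - 2.0 (a+0.5)^-3/2`.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @return Data frame `ic`, `ic025`, `expected`.
#' @export
ic_stat <- function(a, b, c, d) {
  n <- a + b + c + d
  if (any(n <= 0)) stop("ic_stat undefined for an empty table")
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  data.frame(ic = ic, ic025 = ic025_approx(ic, a), expected = e)
}

#' Lower credibility bound of the information component
#'
#' Norén's asymptotic approximation to the 2.5th posterior percentile,
#' `IC - 3.3 (a+0.5)^(-1/2) - 2.0 (a+0.5)^(-3/2)`, as a function of the
#' point IC and the observed count.
#'
#' @param ic Information component (bits).
#' @param a Observed drug-event pair count.
#' @export
ic025_approx <- function(ic, a) {
  ic - 3.3 * (a + 0.5)^(-0.5) - 2.0 * (a + 0.5)^(-1.5)
}

#' Signal-gating threshold policy
#'
#' The default reproduces the standard published positivity criteria for the
#' four methods, combined disjunctively ("at least one method positive"):
#' ROR lower 95% bound > 1; PRR >= 2 with chi-square >= 4 and a >= 3;
#' IC025 > 0; EBGM05 > 2; all subject to the support floor `min_a`.
#'
#' @param min_a Minimum observed count for any flag to fire.
#' @param ror_low_gt Threshold on the ROR lower confidence bound.
#' @param prr_ge,chi2_ge Joint PRR thresholds.
#' @param ic025_gt Threshold on IC025.
#' @param ebgm05_gt Threshold on EBGM05.
#' @param combination `"any"` (disjunction, the default gate) or `"all"`.
#' @export
threshold_policy <- function(min_a = 3, ror_low_gt = 1, prr_ge = 2,
                             chi2_ge = 4, ic025_gt = 0, ebgm05_gt = 2,
                             combination = c("any", "all")) {
  structure(list(min_a = min_a, ror_low_gt = ror_low_gt, prr_ge = prr_ge,
                 chi2_ge = chi2_ge, ic025_gt = ic025_gt,
                 ebgm05_gt = ebgm05_gt,
                 combination = match.arg(combination)),
            class = "threshold_policy")
}

#' Apply a threshold policy to a signal table
#'
#' Sets the per-method flags and the overall `positive` column, and sorts
#' rows by observed count `a` descending (ties broken by term) for top-N
#' frequency reporting.
#'
#' @param rows Data frame from [signal_table()] (or with the same columns).
#' @param policy A [threshold_policy()].
#' @export
gate_signals <- function(rows, policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  support <- rows$a >= policy$min_a
  rows$flag_ror <- support & !is.na(rows$ror_low) & rows$ror_low > policy$ror_low_gt
  rows$flag_prr <- support & !is.na(rows$prr) & rows$prr >= policy$prr_ge &
    rows$chi2 >= policy$chi2_ge
  rows$flag_ic <- support & !is.na(rows$ic025) & rows$ic025 > policy$ic025_gt
  rows$flag_ebgm <- support & !is.na(rows$ebgm05) & rows$ebgm05 > policy$ebgm05_gt
  f <- cbind(rows$flag_ror, rows$flag_prr, rows$flag_ic, rows$flag_ebgm)
  rows$positive <- if (policy$combination == "any") {
    apply(f, 1, any)
  } else {
    apply(f, 1, all)
  }
  rows[order(-rows$a, rows$term), , drop = FALSE]
}

#' Compute the full signal table for one cohort partition
#'
#' Builds the contingency tables at the requested level and computes all
#' four disproportionality statistics per term (ROR with Wald CI, PRR with
#' chi-square, BCPNN IC with IC025, and MGPS EBGM with EBGM05), then applies
#' the gating policy.
#'
#' @inheritParams build_contingency_tables
#' @param policy A [threshold_policy()].
#' @param ebgm_method `"mgps"` for the full empirical-Bayes gamma-Poisson
#'   shrinker (prior fitted across all tables at this level) or `"ic"` for
#'   the simplified transform `EBGM = 2^IC`, `EBGM05 = 2^IC025`.
#' @param prior Optional pre-fitted [gps_prior()]; fitted from the tables
#'   when `NULL` and `ebgm_method = "mgps"`.
#' @param conf_level Confidence level for the ROR interval.
#' @param yates Yates correction for the PRR chi-square.
#' @return Data frame (one row per term) with columns `term`, `level`, `a`,
#'   `b`, `c`, `d`, `n`, the statistics, per-method flags and `positive`,
#'   sorted by `a` descending.
#' @export
signal_table <- function(index, background, level = c("pt", "soc"),
                         hierarchy = NULL, policy = threshold_policy(),
                         ebgm_method = c("mgps", "ic"), prior = NULL,
                         conf_level = 0.95, yates = FALSE) {
  level <- match.arg(level)
  ebgm_method <- match.arg(ebgm_method)
  tab <- build_contingency_tables(index, background, level, hierarchy)
  compute_signal_stats(tab, policy = policy, ebgm_method = ebgm_method,
                       prior = prior, conf_level = conf_level, yates = yates)
}

#' Compute statistics and gates on pre-built contingency tables
#'
#' @param tab Data frame from [build_contingency_tables()].
#' @inheritParams signal_table
#' @export
compute_signal_stats <- function(tab, policy = threshold_policy(),
                                 ebgm_method = c("mgps", "ic"), prior = NULL,
                                 conf_level = 0.95, yates = FALSE) {
  ebgm_method <- match.arg(ebgm_method)
  out <- cbind(tab,
               ror_stat(tab$a, tab$b, tab$c, tab$d, conf_level),
               prr_stat(tab$a, tab$b, tab$c, tab$d, yates),
               ic_stat(tab$a, tab$b, tab$c, tab$d))
  if (ebgm_method == "ic") {
    out$ebgm <- 2^out$ic
    out$ebgm05 <- 2^out$ic025
  } else {
    if (is.null(prior)) {
      prior <- fit_gps_prior(out$a, out$expected)
    }
    post <- gps_posterior(out$a, out$expected, prior)
    out$ebgm <- post$ebgm
    out$ebgm05 <- post$ebgm05
  }
  gate_signals(out, policy)
}

#' Format a signal table in the two-decimal publication style
#'
#' Renders `ROR (low-high)`, `PRR (chi2)`, `EBGM (EBGM05)`, `IC (IC025)`
#' string columns alongside term and count, mirroring the usual
#' disproportionality table layout.
#'
#' @param rows A gated signal table.
#' @param digits Decimal places for display.
#' @export
format_signal_table <- function(rows, digits = 2) {
  f <- function(x) formatC(x, digits = digits, format = "f")
  data.frame(
    term = rows$term,
    case_numbers = rows$a,
    ror = sprintf("%s (%s-%s)", f(rows$ror), f(rows$ror_low), f(rows$ror_high)),
    prr = sprintf("%s (%s)", f(rows$prr), f(rows$chi2)),
    ebgm = sprintf("%s (%s)", f(rows$ebgm), f(rows$ebgm05)),
    ic = sprintf("%s (%s)", f(rows$ic), f(rows$ic025)),
    positive = rows$positive,
    stringsAsFactors = FALSE
  )
}
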