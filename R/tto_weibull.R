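# Time-to-onset extraction and Weibull modelling.
#
# TTO is the interval in days from initiation of index-drug therapy (earliest
# primary-suspect start date in THER) to adverse-event onset (event date in
# DEMO). Only fully dated (8-digit) records with a strictly positive interval
# enter the sample; a Weibull law is fitted by maximum likelihood and the
# shape classifies the hazard as early-failure (< 1), random (~1) or
# wear-out (> 1).

#' Extract time-to-onset values from an index cohort
#'
#' For each report, TTO = event date minus the earliest primary-suspect
#' therapy start date of the index drug, in days. Reports with missing or
#' partial dates, or with a non-positive interval (onset on or before the
#' start day), are excluded and counted by reason.
#'
#' @param reports An index-cohort `safety_reports`.
#' @param index_drug Canonical index-drug label; when `NULL`, the earliest
#'   start date over all primary-suspect entries is used.
#' @return Object of class `tto_sample`: list with `values` (positive days),
#'   `n_total_reports`, `n_with_tto`, `median_days`, `iqr_low`, `iqr_high`
#'   and an `exclusions` count table.
#' @export
extract_tto <- function(reports, index_drug = NULL) {
  stopifnot(inherits(reports, "safety_reports"))
  d <- reports$drugs
  ps <- d[!is.na(d$role) & d$role == "PS", , drop = FALSE]
  if (!is.null(index_drug)) ps <- ps[ps$name == index_drug, , drop = FALSE]
  ps <- ps[!is.na(ps$therapy_start) &
             date_completeness(ps$therapy_start) == "full", , drop = FALSE]
  start_num <- as.numeric(as.Date(ps$therapy_start, format = "%Y%m%d"))
  earliest <- tapply(start_num, ps$primaryid, min)

  demo <- reports$demo
  n_total <- nrow(demo)
  ev_ok <- date_completeness(demo$event_dt) == "full"
  has_start <- demo$primaryid %in% names(earliest)

  excl <- c(no_therapy_start = sum(!has_start),
            partial_or_missing_event_date = sum(has_start & !ev_ok),
            non_positive_interval = 0L)
  use <- has_start & ev_ok
  tto <- as.numeric(as.Date(demo$event_dt[use], format = "%Y%m%d")) -
    as.numeric(earliest[demo$primaryid[use]])
  nonpos <- tto <= 0
  excl["non_positive_interval"] <- sum(nonpos)
  tto <- tto[!nonpos]

  qs <- if (length(tto)) stats::quantile(tto, c(0.25, 0.5, 0.75), names = FALSE)
  else rep(NA_real_, 3)
  structure(list(values = unname(tto),
                 n_total_reports = n_total,
                 n_with_tto = length(tto),
                 median_days = qs[2], iqr_low = qs[1], iqr_high = qs[3],
                 exclusions = excl),
            class = "tto_sample")
}

#' @export
print.tto_sample <- function(x, ...) {
  cat("<tto_sample> ", x$n_with_tto, " of ", x$n_total_reports,
      " reports with computable onset; median ", x$median_days,
      " d (IQR ", x$iqr_low, "-", x$iqr_high, ")\n", sep = "")
  invisible(x)
}

#' Fit a Weibull law to time-to-onset values by maximum likelihood
#'
#' Maximum-likelihood estimation of the Weibull shape and scale by
#' quasi-Newton optimisation on the log-parameter scale; 95% confidence
#' intervals come from the observed information matrix (delta method on the
#' log scale), so the fit is deterministic given the sample. The hazard type
#' follows [classify_hazard()].
#'
#' @param x A `tto_sample` or a numeric vector of positive durations (days).
#' @param conf_level Confidence level for the intervals.
#' @param fix_shape Optional fixed shape; when supplied only the scale is
#'   estimated (shape = 1 reduces to the exponential, whose ML scale is the
#'   sample mean).
#' @return Object of class `weibull_fit`: list with `scale`, `shape`, their
#'   CI bounds, `n`, `median_days`/`iqr_*` (when fitted from a
#'   `tto_sample`), `hazard_type` and `loglik`.
#' @export
fit_weibull <- function(x, conf_level = 0.95, fix_shape = NULL) {
  sample_meta <- NULL
  if (inherits(x, "tto_sample")) {
    sample_meta <- x
    x <- x$values
  }
  x <- as.numeric(x)
  if (length(x) < 10) stop("need at least 10 observed onset times")
  if (any(x <= 0)) stop("onset times must be strictly positive")
  if (stats::sd(x) == 0) {
    stop("degenerate sample: all onset times identical; Weibull fit undefined")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (!is.null(fix_shape)) {
    k <- fix_shape
    scale <- mean(x^k)^(1 / k)
    # observed information for log-scale with shape fixed: n * k^2
    se_ls <- 1 / (k * sqrt(length(x)))
    ll <- sum(stats::dweibull(x, k, scale, log = TRUE))
    return(structure(list(scale = scale, shape = k,
                          scale_ci_low = scale * exp(-z * se_ls),
                          scale_ci_high = scale * exp(z * se_ls),
                          shape_ci_low = k, shape_ci_high = k,
                          n = length(x), loglik = ll,
                          hazard_type = if (k < 1) "early-failure"
                          else if (k > 1) "wear-out" else "random",
                          converged = TRUE),
                     class = "weibull_fit"))
  }

  nll <- function(th) {
    ll <- suppressWarnings(
      sum(stats::dweibull(x, shape = exp(th[1]), scale = exp(th[2]),
                          log = TRUE)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # moment-style start: shape from the log-value spread, scale from the mean
  k0 <- max(0.1, min(20, 1.2 / stats::sd(log(x))))
  th0 <- c(log(k0), log(mean(x)))
  fit <- stats::optim(th0, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  shape <- exp(fit$par[1]); scale <- exp(fit$par[2])
  vc <- tryCatch(solve(fit$hessian), error = function(e) matrix(NA, 2, 2))
  se_lk <- sqrt(vc[1, 1]); se_ls <- sqrt(vc[2, 2])

  out <- structure(list(
    scale = scale, shape = shape,
    scale_ci_low = scale * exp(-z * se_ls),
    scale_ci_high = scale * exp(z * se_ls),
    shape_ci_low = shape * exp(-z * se_lk),
    shape_ci_high = shape * exp(z * se_lk),
    n = length(x), loglik = -fit$value,
    converged = fit$convergence == 0
  ), class = "weibull_fit")
  out$hazard_type <- classify_hazard(out)
  if (!is.null(sample_meta)) {
    out$n_total_reports <- sample_meta$n_total_reports
    out$median_days <- sample_meta$median_days
    out$iqr_low <- sample_meta$iqr_low
    out$iqr_high <- sample_meta$iqr_high
  }
  out
}

#' Classify the hazard type from a Weibull shape confidence interval
#'
#' Shape CI entirely below 1: early-failure (decreasing hazard); entirely
#' above 1: wear-out (increasing hazard); otherwise random (the CI spans 1).
#'
#' @param fit A `weibull_fit`, or a list with `shape_ci_low` and
#'   `shape_ci_high`.
#' @export
classify_hazard <- function(fit) {
  if (fit$shape_ci_high < 1) "early-failure"
  else if (fit$shape_ci_low > 1) "wear-out"
  else "random"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n = %d; scale %.2f (%.2f-%.2f); shape %.2f (%.2f-%.2f); %s\n",
    x$n, x$scale, x$scale_ci_low, x$scale_ci_high,
    x$shape, x$shape_ci_low, x$shape_ci_high, x$hazard_type))
  invisible(x)
}

#' Median of the fitted Weibull law
#'
#' Closed form `scale * log(2)^(1/shape)`.
#'
#' @param fit A `weibull_fit`.
#' @export
weibull_median <- function(fit) {
  fit$scale * log(2)^(1 / fit$shape)
}

#' Plot-ready onset histogram and fitted density table
#'
#' @param fit A `weibull_fit`.
#' @param values The onset values the fit was computed from.
#' @param breaks Histogram break specification (passed to [hist()]).
#' @return Data frame with `mid`, `count`, `density_observed`,
#'   `density_fitted`.
#' @export
tto_density_table <- function(fit, values, breaks = "Sturges") {
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts, density_observed = h$density,
             density_fitted = stats::dweibull(h$mids, fit$shape, fit$scale))
}
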