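# Gamma-Poisson shrinker (GPS/MGPS over drug-event pairs).
#
# Model: observed count a ~ Poisson(lambda * E), lambda ~ mixture of two
# gammas with shapes alpha1, alpha2 and rates beta1, beta2 and weight w.
# The marginal of a is a two-component negative-binomial mixture; the prior
# is fitted by maximum marginal likelihood across all tables, and each
# table's EBGM is the posterior geometric mean exp(E[ln lambda | a]).

#' Construct a gamma-mixture prior for the gamma-Poisson shrinker
#'
#' Defaults are the canonical MGPS starting point.
#'
#' @param alpha1,beta1 Shape/rate of the first gamma component.
#' @param alpha2,beta2 Shape/rate of the second gamma component.
#' @param w Mixture weight of the first component, in `[0, 1]`.
#' @export
gps_prior <- function(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                      w = 1 / 3) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, w >= 0, w <= 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w),
            class = "gps_prior")
}

# log marginal likelihood of counts a with expected counts e under the prior
.gps_loglik <- function(par, a, e) {
  m1 <- stats::dnbinom(a, size = par$alpha1,
                       prob = par$beta1 / (par$beta1 + e))
  m2 <- stats::dnbinom(a, size = par$alpha2,
                       prob = par$beta2 / (par$beta2 + e))
  sum(log(pmax(par$w * m1 + (1 - par$w) * m2, 1e-300)))
}

#' Fit the gamma-mixture prior by maximum marginal likelihood
#'
#' Maximises the negative-binomial mixture marginal of the observed counts
#' given expected counts, by bounded quasi-Newton optimisation in
#' log-parameter space (logit space for the weight), which enforces
#' positivity. Deterministic given `init` and optimiser settings.
#'
#' @param a Observed counts, one per drug-event table.
#' @param e Expected counts `E = (a+b)(a+c)/N`, same length.
#' @param init A [gps_prior()] used as the starting point.
#' @param components `2` for the mixture (default) or `1` to fit a single
#'   gamma component (weight fixed at 1).
#' @param maxit Maximum optimiser iterations; `0` returns `init` unchanged.
#' @return A [gps_prior()] with attributes `converged` (logical) and
#'   `loglik`.
#' @export
fit_gps_prior <- function(a, e, init = gps_prior(), components = 2,
                          maxit = 500) {
  stopifnot(length(a) == length(e), length(a) >= 2)
  keep <- is.finite(e) & e > 0
  a <- a[keep]; e <- e[keep]
  if (length(a) < 2) stop("need at least 2 tables with positive expected counts")
  if (maxit == 0) {
    attr(init, "converged") <- TRUE
    attr(init, "loglik") <- .gps_loglik(init, a, e)
    return(init)
  }
  if (components == 1) {
    theta0 <- log(c(init$alpha1, init$beta1))
    nll <- function(th) {
      p <- list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                alpha2 = exp(th[1]), beta2 = exp(th[2]), w = 1)
      -.gps_loglik(p, a, e)
    }
  } else {
    theta0 <- c(log(c(init$alpha1, init$beta1, init$alpha2, init$beta2)),
                stats::qlogis(min(max(init$w, 1e-6), 1 - 1e-6)))
    nll <- function(th) {
      p <- list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                alpha2 = exp(th[3]), beta2 = exp(th[4]),
                w = stats::plogis(th[5]))
      -.gps_loglik(p, a, e)
    }
  }
  fit <- stats::optim(theta0, nll, method = "L-BFGS-B",
                      lower = rep(-12, length(theta0)),
                      upper = rep(12, length(theta0)),
                      control = list(maxit = maxit))
  th <- fit$par
  out <- if (components == 1) {
    gps_prior(exp(th[1]), exp(th[2]), exp(th[1]), exp(th[2]), w = 1)
  } else {
    gps_prior(exp(th[1]), exp(th[2]), exp(th[3]), exp(th[4]),
              w = stats::plogis(th[5]))
  }
  attr(out, "converged") <- fit$convergence == 0
  attr(out, "loglik") <- -fit$value
  if (fit$convergence != 0) {
    warning("GPS prior optimisation did not converge; returning best iterate")
  }
  out
}

#' Posterior summaries of the gamma-Poisson shrinker
#'
#' Conjugate update: component j becomes Gamma(alpha_j + a, beta_j + E) with
#' posterior weight q proportional to the prior weight times the
#' negative-binomial marginal. EBGM is the posterior geometric mean
#' `exp(q [psi(s1) - ln r1] + (1-q) [psi(s2) - ln r2])` (psi the digamma
#' function); EBGM05 solves the posterior mixture CDF = 0.05 by bracketed
#' root finding.
#'
#' @param a Observed counts (vectorised).
#' @param e Expected counts (vectorised).
#' @param prior A [gps_prior()].
#' @return Data frame `q`, `shape1`, `rate1`, `shape2`, `rate2`, `ebgm`,
#'   `ebgm05`.
#' @export
gps_posterior <- function(a, e, prior) {
  stopifnot(inherits(prior, "gps_prior"))
  m1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + e))
  m2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + e))
  q <- prior$w * m1 / pmax(prior$w * m1 + (1 - prior$w) * m2, 1e-300)
  q[prior$w == 1] <- 1
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + e
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + e
  ebgm <- exp(q * (digamma(s1) - log(r1)) + (1 - q) * (digamma(s2) - log(r2)))
  ebgm05 <- mapply(.gps_mixture_quantile, q, s1, r1, s2, r2,
                   MoreArgs = list(p = 0.05))
  data.frame(q = q, shape1 = s1, rate1 = r1, shape2 = s2, rate2 = r2,
             ebgm = ebgm, ebgm05 = ebgm05)
}

# p-quantile of q*Gamma(s1, r1) + (1-q)*Gamma(s2, r2) by bracketed root find
.gps_mixture_quantile <- function(q, s1, r1, s2, r2, p = 0.05, tol = 1e-10) {
  cdf <- function(x) q * stats::pgamma(x, s1, r1) +
    (1 - q) * stats::pgamma(x, s2, r2)
  q1 <- stats::qgamma(p, s1, r1)
  q2 <- stats::qgamma(p, s2, r2)
  # the mixture quantile lies between the component quantiles; pad the
  # bracket slightly against qgamma/pgamma round-off at the endpoints
  lo <- min(q1, q2) * (1 - 1e-8); hi <- max(q1, q2) * (1 + 1e-8)
  if (cdf(lo) >= p) return(lo / (1 - 1e-8))
  if (cdf(hi) <= p) return(hi / (1 + 1e-8))
  stats::uniroot(function(x) cdf(x) - p, c(lo, hi), tol = tol,
                 extendInt = "no")$root
}

# Brute-force quadrature oracle: E[ln lambda | a] and the 5th posterior
# percentile by numerical integration of the unnormalised posterior on a
# log-spaced grid. Test-suite verification only; not exported.
.ebgm_quadrature <- function(a, e, prior, n_grid = 20000L,
                             lambda_range = NULL) {
  if (is.null(lambda_range)) {
    # bracket essentially all posterior mass via the component quantiles
    s <- c(prior$alpha1 + a, prior$alpha2 + a)
    r <- c(prior$beta1 + e, prior$beta2 + e)
    lambda_range <- c(0.5 * min(stats::qgamma(1e-10, s, r)),
                      2.0 * max(stats::qgamma(1 - 1e-12, s, r)))
    lambda_range[1] <- max(lambda_range[1], 1e-12)
  }
  span <- log(lambda_range[2]) - log(lambda_range[1])
  # cap the log-step so heavy-tailed posteriors (small gamma shapes) keep a
  # fine grid over their long left tail
  n_grid <- max(n_grid, ceiling(span / 5e-4))
  lx <- seq(log(lambda_range[1]), log(lambda_range[2]), length.out = n_grid)
  lam <- exp(lx)
  log_prior <- log(prior$w * stats::dgamma(lam, prior$alpha1, prior$beta1) +
                     (1 - prior$w) * stats::dgamma(lam, prior$alpha2, prior$beta2))
  log_post <- log_prior + stats::dpois(a, lam * e, log = TRUE)
  # density in log-lambda coordinates: f(lam) * lam
  lw <- log_post + lx
  lw <- lw - max(lw)
  w <- exp(lw)
  # trapezoid rule on the uniform log grid
  h <- lx[2] - lx[1]
  seg <- (w[-1L] + w[-n_grid]) / 2 * h      # mass of each interval
  z <- sum(seg)
  mean_log <- sum((w[-1L] * lx[-1L] + w[-n_grid] * lx[-n_grid]) / 2 * h) / z
  cdf <- c(0, cumsum(seg)) / z
  i <- which(cdf >= 0.05)[1]
  # linear interpolation of the CDF for the percentile
  if (i == 1L) {
    p05 <- lam[1]
  } else {
    frac <- (0.05 - cdf[i - 1L]) / (cdf[i] - cdf[i - 1L])
    p05 <- exp(lx[i - 1L] + frac * (lx[i] - lx[i - 1L]))
  }
  list(ebgm = exp(mean_log), ebgm05 = p05)
}
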