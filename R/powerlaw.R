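## Discrete power-law fitting of degree distributions.
##
## Degree tails of protein interactomes are commonly summarized by a
## scale-free exponent. The fit here is the standard discrete
## maximum-likelihood estimator with the lower cutoff `xmin` selected by
## Kolmogorov-Smirnov distance minimization; log-log regression is offered
## only as a diagnostic, never the headline fit.

## Hurwitz zeta sum_{i=0}^{Inf} (q + i)^(-s), s > 1, by truncated sum plus
## an Euler-Maclaurin tail correction.
hurwitz_zeta <- function(s, q, n_direct = 2000L) {
  stopifnot(s > 1, q > 0)
  i <- seq.int(0L, n_direct - 1L)
  head_sum <- sum((q + i)^(-s))
  a <- q + n_direct
  tail <- a^(1 - s) / (s - 1) + 0.5 * a^(-s) + (s / 12) * a^(-s - 1)
  head_sum + tail
}

powerlaw_loglik <- function(alpha, x, xmin) {
  n <- length(x)
  -n * log(hurwitz_zeta(alpha, xmin)) - alpha * sum(log(x))
}

## Discrete power-law CDF values P(X <= x) for x = xmin..xmax.
powerlaw_cdf <- function(alpha, xmin, xmax) {
  z <- hurwitz_zeta(alpha, xmin)
  pmf <- (seq.int(xmin, xmax))^(-alpha) / z
  cumsum(pmf)
}

#' Fit a discrete power law to a degree sequence
#'
#' Maximum-likelihood estimation of the exponent `alpha` of
#' `p(x) ~ x^(-alpha)`, `x >= xmin`, with `xmin` chosen (unless fixed) to
#' minimize the Kolmogorov-Smirnov distance between the empirical and fitted
#' tail distributions.
#'
#' @param x positive integer observations (e.g. node degrees); zeros are
#'   dropped.
#' @param xmin optional fixed lower cutoff; if `NULL`, selected by KS scan
#'   over the distinct observed values.
#' @param alpha_range search interval for the exponent.
#' @return a `powerlaw_fit` list: `exponent`, `xmin`, `n_tail` (observations
#'   >= xmin), `ks_distance`, `fit_method`.
#' @export
fit_power_law <- function(x, xmin = NULL, alpha_range = c(1.01, 8)) {
  x <- as.integer(round(x))
  x <- x[x >= 1L]
  if (length(x) < 10L) stop("need at least 10 positive observations")
  fit_at <- function(xm) {
    tail_x <- x[x >= xm]
    if (length(tail_x) < 10L || length(unique(tail_x)) < 2L) return(NULL)
    opt <- stats::optimize(function(a) powerlaw_loglik(a, tail_x, xm),
                           interval = alpha_range, maximum = TRUE, tol = 1e-6)
    alpha <- opt$maximum
    xmax <- max(tail_x)
    th_cdf <- powerlaw_cdf(alpha, xm, xmax)
    ## renormalize over the observed support to compare CDFs on xm..xmax
    th_cdf <- th_cdf / th_cdf[length(th_cdf)]
    emp_cdf <- cumsum(tabulate(tail_x - xm + 1L, nbins = xmax - xm + 1L)) /
      length(tail_x)
    list(alpha = alpha, xmin = xm, n_tail = length(tail_x),
         ks = max(abs(emp_cdf - th_cdf)))
  }
  if (!is.null(xmin)) {
    f <- fit_at(as.integer(xmin))
    if (is.null(f)) stop("insufficient tail data at the requested xmin")
  } else {
    cands <- sort(unique(x))
    cands <- cands[cands <= stats::quantile(x, 0.9)]  # keep a usable tail
    fits <- Filter(Negate(is.null), lapply(cands, fit_at))
    if (length(fits) == 0L) stop("no viable xmin candidate")
    f <- fits[[which.min(vapply(fits, `[[`, 0, "ks"))]]
  }
  structure(list(exponent = f$alpha, xmin = f$xmin, n_tail = f$n_tail,
                 ks_distance = f$ks, fit_method = "discrete_mle_ks"),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("discrete power-law fit: alpha = %.3f, xmin = %d (n_tail = %d, KS = %.4f)\n",
              x$exponent, x$xmin, x$n_tail, x$ks_distance))
  invisible(x)
}

#' Fit the degree distribution of a network
#'
#' @param net an `interactome`.
#' @inheritParams fit_power_law
#' @return a `powerlaw_fit` (see [fit_power_law()]).
#' @export
fit_degree_distribution <- function(net, xmin = NULL) {
  stopifnot(inherits(net, "interactome"))
  deg <- compute_topology(net)$degree
  fit_power_law(deg, xmin = xmin)
}

#' Sample from a discrete power law
#'
#' Inverse-CDF sampling of `p(x) ~ x^(-alpha)` on `xmin..xmax` (the upper
#' truncation carries negligible mass for `alpha > 2` and large `xmax`).
#'
#' @param n sample size.
#' @param alpha exponent (> 1).
#' @param xmin lower cutoff (>= 1).
#' @param xmax support truncation point.
#' @return integer vector of samples.
#' @export
rpowerlaw <- function(n, alpha = 2.5, xmin = 2L, xmax = 100000L) {
  stopifnot(alpha > 1, xmin >= 1)
  support <- seq.int(xmin, xmax)
  pmf <- support^(-alpha)
  pmf <- pmf / sum(pmf)
  cdf <- cumsum(pmf)
  support[findInterval(stats::runif(n), cdf) + 1L]
}
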