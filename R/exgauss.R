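# Ex-Gaussian model of fixation durations.
#
# Fixation durations in reading are right-skewed and are conventionally
# modelled as an ex-Gaussian: the convolution of a Gaussian (mu, sigma) and
# an exponential with mean tau = 1/lambda. The exponential tail tau is the
# screening parameter; mu and sigma are fitted but are not used downstream.

#' Ex-Gaussian probability density
#'
#' Density of the exponentially modified Gaussian,
#' \deqn{f(x) = (\lambda/2)\, e^{(\lambda/2)(2\mu + \lambda\sigma^2 - 2x)}
#'   \,\mathrm{erfc}\!\left(\frac{\mu + \lambda\sigma^2 - x}{\sqrt{2}\sigma}\right),}
#' evaluated in log space for numerical stability (erfc is expressed through
#' the Gaussian CDF).
#'
#' @param x Quantiles (ms).
#' @param mu,sigma Gaussian component mean and SD (ms); `sigma > 0`.
#' @param lambda Exponential rate (1/ms); `tau = 1/lambda`.
#' @param log Return log density.
#' @return Density values (nonnegative).
#' @export
exgauss_pdf <- function(x, mu, sigma, lambda, log = FALSE) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  # log f = log(lambda) + lambda*(mu - x) + lambda^2 sigma^2/2
  #         + log Phi((x - mu - lambda sigma^2)/sigma)
  lf <- log(lambda) + lambda * (mu - x) + lambda^2 * sigma^2 / 2 +
    stats::pnorm((x - mu - lambda * sigma^2) / sigma, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' Draw ex-Gaussian variates
#'
#' @param n Number of draws.
#' @inheritParams exgauss_pdf
#' @param tau Exponential mean (ms), `tau = 1/lambda`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

# moment estimates: mean = mu + tau, var = sigma^2 + tau^2,
# skewness = 2 tau^3 / (sigma^2 + tau^2)^(3/2)
.exgauss_moments <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  g1 <- mean((x - m)^3) / s^3
  tau <- s * (pmax(g1, 1e-3) / 2)^(1 / 3)
  tau <- min(max(tau, 0.05 * s), 3 * s)
  sigma <- sqrt(max(s^2 - tau^2, (0.05 * s)^2))
  c(mu = m - tau, sigma = sigma, tau = tau)
}

#' Maximum-likelihood ex-Gaussian fit
#'
#' Fits (mu, sigma, tau) to a sample of durations by maximising the
#' ex-Gaussian log-likelihood with a quasi-Newton search on
#' (mu, log sigma, log tau), initialised from the moment estimates
#' (mean = mu + tau, var = sigma^2 + tau^2, skewness fixes tau). If the
#' optimiser fails to improve on the moment start, the moment estimates are
#' returned and flagged.
#'
#' @param durations Positive durations in ms; at least 10 values with
#'   nonzero spread.
#' @return Object of class `exgauss_fit`: list with mu, sigma, tau, lambda,
#'   loglik, n, converged, method ("mle" or "moments").
#' @examples
#' set.seed(1)
#' fit <- fit_exgaussian(rexgauss(500, 150, 30, 180))
#' fit$tau
#' @export
fit_exgaussian <- function(durations) {
  x <- durations[is.finite(durations)]
  if (length(x) < 10) stop("need at least 10 durations")
  if (stats::sd(x) < 1e-8) stop("degenerate durations: zero variance")
  start <- .exgauss_moments(x)
  nll <- function(p) {
    -sum(exgauss_pdf(x, p[1], exp(p[2]), 1 / exp(p[3]), log = TRUE))
  }
  p0 <- c(start["mu"], log(start["sigma"]), log(start["tau"]))
  s <- stats::sd(x)
  # box constraints keep the search inside the numerically stable region
  # (unbounded sigma drives the likelihood into catastrophic cancellation)
  lower <- c(min(x) - 2 * s, log(s / 50), log(s / 50))
  upper <- c(max(x), log(4 * s), log(6 * s))
  fit <- tryCatch(
    stats::optim(pmin(pmax(p0, lower), upper), nll, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$value) && fit$value <= nll(p0) + 1e-8) {
    out <- list(mu = unname(fit$par[1]), sigma = unname(exp(fit$par[2])),
                tau = unname(exp(fit$par[3])), loglik = -fit$value,
                n = length(x), converged = fit$convergence == 0,
                method = "mle")
  } else {
    out <- list(mu = unname(start["mu"]), sigma = unname(start["sigma"]),
                tau = unname(start["tau"]), loglik = -nll(p0),
                n = length(x), converged = FALSE, method = "moments")
  }
  out$lambda <- 1 / out$tau
  class(out) <- "exgauss_fit"
  out
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf("Ex-Gaussian fit (%s, n=%d): mu=%.1f ms, sigma=%.1f ms, tau=%.1f ms, logLik=%.1f\n",
              x$method, x$n, x$mu, x$sigma, x$tau, x$loglik))
  invisible(x)
}
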