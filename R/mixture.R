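#' Fit a two-component Gaussian mixture to the marker
#'
#' Maximum-likelihood EM fit of \eqn{\pi_1 N(\mu_1, \sigma_1^2) + \pi_2
#' N(\mu_2, \sigma_2^2)} to the raw marker values. The first start splits the
#' sample at its median (component means and SDs from the two halves,
#' weights 1/2); the remaining `n_starts - 1` starts draw random means from
#' the data under the given seed. The best start by final log-likelihood is
#' returned, with components relabeled so that `mu1 < mu2`.
#'
#' A variance floor of `1e-4 * sd(marker)` on each component SD prevents
#' collapse onto a single observation. Convergence is declared when the
#' relative log-likelihood change drops below `tol` (default 1e-8), with at
#' most `max_iter` iterations per start.
#'
#' @param dataset A [marker_dataset()] or numeric vector (n >= 10,
#'   non-constant).
#' @param n_starts Number of EM starts (>= 1), default 10.
#' @param seed Integer seed for the random restarts; the caller's RNG state
#'   is restored afterwards.
#' @param max_iter,tol EM stopping rule.
#' @return An object of class `mixture_fit`: `pi1`, `pi2`, `mu1`, `mu2`,
#'   `sigma1`, `sigma2`, `loglik`, `loglik_trace` (of the winning start),
#'   `n_iter`, `converged`, `n`.
#' @examples
#' x <- gen_bimodal_marker(400, mu = c(0, 4), seed = 1)
#' fit <- fit_mixture(x, seed = 1)
#' mixture_cutoff(fit)
#' @seealso [mixture_cutoff()] for the density-crossing cutoff.
#' @export
fit_mixture <- function(dataset, n_starts = 10, seed = NULL,
                        max_iter = 500, tol = 1e-8) {
  x <- if (inherits(dataset, "marker_dataset")) dataset$marker else dataset
  x <- x[!is.na(x)]
  if (length(x) < 10) stop("mixture fit needs at least 10 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("marker is constant: mixture fit undefined", call. = FALSE)
  stopifnot(n_starts >= 1)

  sigma_floor <- 1e-4 * stats::sd(x)

  starts <- list(median_split_start(x))
  if (n_starts > 1) {
    rand <- with_preserved_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) random_start(x, sigma_floor))
    })
    starts <- c(starts, rand)
  }

  fits <- lapply(starts, function(th) {
    em_two_gaussians(x, th, sigma_floor, max_iter, tol)
  })
  logliks <- vapply(fits, function(f) f$loglik, numeric(1))
  best <- fits[[which.max(logliks)]]

  if (!any(vapply(fits, function(f) f$converged, logical(1)))) {
    warning("EM did not converge in any start; returning the best attempt",
            call. = FALSE)
  }

  # relabel so component 1 has the smaller mean
  if (best$mu[1] > best$mu[2]) {
    best$pi <- rev(best$pi); best$mu <- rev(best$mu); best$sigma <- rev(best$sigma)
  }
  structure(
    list(pi1 = best$pi[1], pi2 = best$pi[2],
         mu1 = best$mu[1], mu2 = best$mu[2],
         sigma1 = best$sigma[1], sigma2 = best$sigma[2],
         loglik = best$loglik, loglik_trace = best$trace,
         n_iter = best$n_iter, converged = best$converged,
         n = length(x)),
    class = "mixture_fit"
  )
}

median_split_start <- function(x) {
  m <- stats::median(x)
  lo <- x[x <= m]; hi <- x[x > m]
  if (length(hi) == 0) { hi <- max(x); lo <- x[x < max(x)] }
  list(pi = c(0.5, 0.5),
       mu = c(mean(lo), mean(hi)),
       sigma = c(max(stats::sd(lo), 1e-8), max(stats::sd(hi), 1e-8)))
}

random_start <- function(x, sigma_floor) {
  mu <- sample(x, 2)
  list(pi = c(p <- stats::runif(1, 0.2, 0.8), 1 - p),
       mu = sort(mu) + stats::rnorm(2, 0, stats::sd(x) / 10),
       sigma = rep(max(stats::sd(x) / 2, sigma_floor), 2))
}

# Plain EM for a univariate 2-component Gaussian mixture. Log-likelihood is
# guaranteed non-decreasing; the trace is kept so tests can assert it.
em_two_gaussians <- function(x, theta, sigma_floor, max_iter, tol) {
  n <- length(x)
  pi_ <- theta$pi; mu <- theta$mu; sigma <- pmax(theta$sigma, sigma_floor)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    d1 <- pi_[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- pi_[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    g1 <- d1 / tot
    g2 <- 1 - g1
    n1 <- sum(g1); n2 <- sum(g2)
    pi_ <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
    sigma <- c(sqrt(sum(g1 * (x - mu[1])^2) / n1),
               sqrt(sum(g2 * (x - mu[2])^2) / n2))
    sigma <- pmax(sigma, sigma_floor)
  }
  list(pi = pi_, mu = mu, sigma = sigma, loglik = trace[length(trace)],
       trace = trace, n_iter = iter, converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> 2-component Gaussian mixture, n =", x$n, "\n")
  cat(sprintf("  component 1: pi = %.3f, mu = %.4g, sigma = %.4g\n",
              x$pi1, x$mu1, x$sigma1))
  cat(sprintf("  component 2: pi = %.3f, mu = %.4g, sigma = %.4g\n",
              x$pi2, x$mu2, x$sigma2))
  cat(sprintf("  loglik = %.4f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Density-crossing cutoff of a fitted mixture
#'
#' Solves \eqn{\pi_1 \phi(x; \mu_1, \sigma_1) = \pi_2 \phi(x; \mu_2,
#' \sigma_2)} for the cutoff where the two weighted component densities
#' coincide. With unequal variances this is a quadratic with up to two real
#' roots; the root inside the open interval `(mu1, mu2)` is returned. With
#' equal variances the closed form
#' \eqn{x = (\mu_1 + \mu_2)/2 + \sigma^2 \log(\pi_1/\pi_2) / (\mu_2 - \mu_1)}
#' applies. If no root lies between the component means (possible when the
#' fitted components overlap heavily), the real root closest to that interval
#' is returned with a warning.
#'
#' @param fit A converged [fit_mixture()] result.
#' @return The cutoff value (numeric scalar), with attribute `"in_interval"`.
#' @export
mixture_cutoff <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) {
    stop("mixture fit did not converge; no reliable density crossing", call. = FALSE)
  }
  roots <- density_crossings(fit$pi1, fit$mu1, fit$sigma1,
                             fit$pi2, fit$mu2, fit$sigma2)
  if (length(roots) == 0) {
    stop("weighted component densities never coincide (degenerate fit)", call. = FALSE)
  }
  inside <- roots[roots > fit$mu1 & roots < fit$mu2]
  if (length(inside) > 0) {
    res <- inside[which.min(abs(inside - (fit$mu1 + fit$mu2) / 2))]
    attr(res, "in_interval") <- TRUE
    return(res)
  }
  dist <- pmax(fit$mu1 - roots, roots - fit$mu2, 0)
  res <- roots[which.min(dist)]
  warning("no density crossing between the component means; ",
          "returning the closest crossing at ", format(res), call. = FALSE)
  attr(res, "in_interval") <- FALSE
  res
}

# Real solutions of pi1*dnorm(x, mu1, s1) == pi2*dnorm(x, mu2, s2).
density_crossings <- function(pi1, mu1, s1, pi2, mu2, s2) {
  # log pi1 - log s1 - (x-mu1)^2/(2 s1^2) = log pi2 - log s2 - (x-mu2)^2/(2 s2^2)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- mu1 / s1^2 - mu2 / s2^2
  c0 <- mu2^2 / (2 * s2^2) - mu1^2 / (2 * s1^2) +
    log(pi1) - log(pi2) + log(s2) - log(s1)
  if (abs(a) < 1e-14 * (1 / s1^2 + 1 / s2^2)) {
    if (b == 0) return(numeric(0))
    return(-c0 / b)
  }
  disc <- b^2 - 4 * a * c0
  if (disc < 0) return(numeric(0))
  sq <- sqrt(disc)
  sort((-b + c(-1, 1) * sq) / (2 * a))
}

#' Mixture density at given points
#'
#' Evaluates the fitted weighted mixture density (and its two weighted
#' components) on a grid; used by the histogram overlay plot and handy for
#' diagnostics.
#'
#' @param fit A [fit_mixture()] result.
#' @param x Numeric vector of evaluation points.
#' @return A [tibble::tibble] with columns `x`, `component1`, `component2`,
#'   `mixture`.
#' @export
mixture_density <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  c1 <- fit$pi1 * stats::dnorm(x, fit$mu1, fit$sigma1)
  c2 <- fit$pi2 * stats::dnorm(x, fit$mu2, fit$sigma2)
  tibble::tibble(x = x, component1 = c1, component2 = c2, mixture = c1 + c2)
}
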