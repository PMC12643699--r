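#' Fit the MGPS gamma-mixture prior by empirical Bayes
#'
#' The multi-item gamma Poisson shrinker (MGPS) models each pair's observed
#' count as \eqn{a \sim Poisson(\lambda E)}, where \eqn{E = (a+b)(a+c)/N} is
#' the count expected under independence and the reporting-rate ratio
#' \eqn{\lambda} is drawn from a two-component gamma mixture
#' \deqn{\lambda \sim w \, Gamma(\alpha_1, \beta_1) +
#'       (1-w) \, Gamma(\alpha_2, \beta_2)}
#' (shape/rate parametrization). Integrating \eqn{\lambda} out, each count is
#' marginally a mixture of negative binomials; the five hyperparameters are
#' chosen to maximize that marginal likelihood over all supplied tables.
#'
#' Optimization is quasi-Newton (BFGS) on the unconstrained scale
#' (log for the four gamma parameters, logit for the weight), with three
#' starts: the documented default \eqn{(\alpha_1, \beta_1, \alpha_2, \beta_2,
#' w) = (0.2, 0.1, 2.0, 4.0, 1/3)} plus two deterministic perturbations of
#' it. The best converged optimum is returned.
#'
#' @param tables a tibble with cell columns `a`, `b`, `c`, `d` (the expected
#'   count is derived as `(a+b)(a+c)/N`), or directly with columns `a` and
#'   `E`; at least 20 rows with positive expected count are required.
#' @param init numeric vector of length 5, the starting hyperparameters
#'   `(alpha1, beta1, alpha2, beta2, w)`.
#' @return an object of class `gamma_mixture_prior`: a list with the five
#'   hyperparameters, `converged`, `marginal_loglik`, `n_tables` and the
#'   `init` used.
#' @seealso [ebgm_score()] to score tables under the fitted prior.
#' @export
fit_gamma_mixture <- function(tables, init = c(0.2, 0.1, 2.0, 4.0, 1 / 3)) {
  if (all(c("a", "E") %in% names(tables))) {
    E <- tables$E
  } else {
    stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
    N <- tables$a + tables$b + tables$c + tables$d
    E <- (tables$a + tables$b) * (tables$a + tables$c) / N
  }
  keep <- is.finite(E) & E > 0
  a <- tables$a[keep]
  E <- E[keep]
  if (length(a) < 20) {
    abort_faersignal("insufficient pairs: need >= 20 tables with positive expected count",
                     "faersignal_insufficient_pairs")
  }
  if (all(a == 0)) {
    abort_faersignal("degenerate counts: all observed counts are zero",
                     "faersignal_degenerate_counts")
  }

  negll <- function(theta) {
    p <- mgps_untransform(theta)
    ll <- suppressWarnings(
      sum(mgps_marginal_loglik(a, E, p$alpha1, p$beta1, p$alpha2, p$beta2,
                               p$w))
    )
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  theta0 <- mgps_transform(init)
  # three deterministic starts: the default and two perturbations of it
  starts <- list(
    theta0,
    theta0 + c(0.5, -0.5, 0.5, -0.5, 0.5),
    theta0 + c(-0.5, 0.5, -0.5, 0.5, -0.5)
  )
  fits <- lapply(starts, function(s) {
    tryCatch(
      stats::optim(s, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    abort_faersignal("gamma mixture fit failed from all starts",
                     "faersignal_fit_failed")
  }
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  p <- mgps_untransform(best$par)
  structure(
    list(
      alpha1 = p$alpha1, beta1 = p$beta1,
      alpha2 = p$alpha2, beta2 = p$beta2, w = p$w,
      converged = best$convergence == 0,
      marginal_loglik = -best$value,
      n_tables = length(a),
      init = init
    ),
    class = "gamma_mixture_prior"
  )
}

mgps_transform <- function(p) {
  c(log(p[1:4]), stats::qlogis(p[5]))
}

mgps_untransform <- function(theta) {
  list(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
       alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
       w = stats::plogis(theta[5]))
}

#' Marginal log-likelihood of counts under a gamma-mixture Poisson model
#'
#' Per-cell log density of the negative-binomial mixture obtained by
#' integrating the Poisson rate ratio over the gamma mixture prior. Exposed
#' so a fitted prior can be compared against generating parameters.
#'
#' @param a observed counts.
#' @param E expected counts under independence.
#' @param alpha1,beta1,alpha2,beta2,w mixture hyperparameters (shape/rate).
#' @return numeric vector of per-cell log densities.
#' @export
mgps_marginal_loglik <- function(a, E, alpha1, beta1, alpha2, beta2, w) {
  l1 <- stats::dnbinom(a, size = alpha1, prob = beta1 / (beta1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = alpha2, prob = beta2 / (beta2 + E), log = TRUE)
  hi <- pmax(l1, l2)
  hi + log(w * exp(l1 - hi) + (1 - w) * exp(l2 - hi))
}

#' Empirical Bayes geometric mean (EBGM) and its lower bound
#'
#' Under the MGPS model the posterior of the rate ratio \eqn{\lambda} given
#' an observed count `a` is again a two-component gamma mixture, with
#' components \eqn{Gamma(\alpha_j + a,\; \beta_j + E)} and weights
#' proportional to the prior weight times the marginal negative-binomial
#' likelihood of `a` under component j. The EBGM is the geometric mean of
#' the posterior, \eqn{2^{E[\log_2 \lambda \mid a]}}, and EBGM05 is the 5th
#' posterior percentile, located by bisection on the posterior CDF to an
#' absolute tolerance of 1e-8.
#'
#' @param a,b,c,d cell counts (vectors, recycled).
#' @param prior a `gamma_mixture_prior` from [fit_gamma_mixture()], or any
#'   list with elements `alpha1, beta1, alpha2, beta2, w`.
#' @param percentile the lower posterior percentile reported (default 0.05).
#' @return a tibble with columns `ebgm` and `ebgm05`.
#' @examples
#' # degenerate unit prior: posterior is Gamma(1 + a, 1 + E)
#' prior <- list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1, w = 0.5)
#' ebgm_score(20, 80, 100, 1900, prior = prior)
#' @export
ebgm_score <- function(a, b, c, d, prior, percentile = 0.05) {
  n <- max(length(a), length(b), length(c), length(d))
  cells <- vctrs_recycle(a, b, c, d, n = n)
  a <- cells[[1]]; b <- cells[[2]]; c <- cells[[3]]; d <- cells[[4]]
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  # E = 0 (drug or event absent) still gives a proper posterior because the
  # prior rates are positive; only undefined E is rejected
  E[!is.finite(E) | E < 0] <- NA_real_

  l1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  lw1 <- log(prior$w) + l1
  lw2 <- log(1 - prior$w) + l2
  m <- pmax(lw1, lw2)
  q1 <- exp(lw1 - m) / (exp(lw1 - m) + exp(lw2 - m))
  q2 <- 1 - q1

  sh1 <- prior$alpha1 + a
  sh2 <- prior$alpha2 + a
  rt1 <- prior$beta1 + E
  rt2 <- prior$beta2 + E

  # E[log lambda | a] under the posterior mixture
  elog <- q1 * (digamma(sh1) - log(rt1)) + q2 * (digamma(sh2) - log(rt2))
  ebgm <- exp(elog)

  ebgm05 <- vapply(seq_len(n), function(i) {
    if (is.na(E[i])) return(NA_real_)
    posterior_mixture_quantile(percentile, q1[i], sh1[i], rt1[i],
                               q2[i], sh2[i], rt2[i])
  }, numeric(1))

  tibble::tibble(ebgm = ebgm, ebgm05 = ebgm05)
}

# Bisection on the mixture CDF to absolute tolerance 1e-8 on the quantile.
posterior_mixture_quantile <- function(p, q1, sh1, rt1, q2, sh2, rt2,
                                       tol = 1e-8) {
  cdf <- function(x) {
    q1 * stats::pgamma(x, shape = sh1, rate = rt1) +
      q2 * stats::pgamma(x, shape = sh2, rate = rt2)
  }
  lo <- 0
  hi <- max(stats::qgamma(p, shape = sh1, rate = rt1),
            stats::qgamma(p, shape = sh2, rate = rt2))
  if (hi <= 0) hi <- 1
  while (cdf(hi) < p) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.gamma_mixture_prior <- function(x, ...) {
  cat("MGPS gamma-mixture prior (empirical Bayes fit)\n")
  cat(sprintf("  component 1: Gamma(shape = %.4g, rate = %.4g)\n",
              x$alpha1, x$beta1))
  cat(sprintf("  component 2: Gamma(shape = %.4g, rate = %.4g)\n",
              x$alpha2, x$beta2))
  cat(sprintf("  weight on component 1: %.4g\n", x$w))
  cat(sprintf("  marginal log-likelihood: %.4f over %d tables (%s)\n",
              x$marginal_loglik, x$n_tables,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.gamma_mixture_prior <- function(x, ...) {
  tibble::tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "w"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$w)
  )
}

#' @importFrom generics glance
#' @export
glance.gamma_mixture_prior <- function(x, ...) {
  tibble::tibble(
    logLik = x$marginal_loglik,
    n_tables = x$n_tables,
    converged = isTRUE(x$converged)
  )
}
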