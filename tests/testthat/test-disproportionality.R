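# direct single-table formula evaluations used as the independent oracle
oracle_ror <- function(a, b, c, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  r <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(r, exp(log(r) - z * se), exp(log(r) + z * se))
}
oracle_prr_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  c((a / (a + b)) / (c / (c + d)),
    N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)))
}
oracle_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  ic <- log2((a + 0.5) / (E + 0.5))
  c(ic, ic - 3.3 * (a + 0.5)^(-0.5) - 2.4 / (a + 0.5))
}

test_that("hand-derived values on the reference table are reproduced", {
  expect_equal(ror_score(20, 80, 100, 1900)$ror, 4.75)
  s <- ror_score(10, 10, 10, 10)
  expect_equal(s$ror, 1)
  expect_lt(s$ror_lo, 1); expect_gt(s$ror_hi, 1)

  p <- prr_chi2_score(20, 80, 100, 1900)
  expect_equal(p$prr, 4)
  expect_equal(p$chi2, 39.7727, tolerance = 1e-4)
  p0 <- prr_chi2_score(10, 10, 10, 10)
  expect_equal(p0$prr, 1); expect_equal(p0$chi2, 0)

  i <- ic_score(20, 80, 100, 1900)
  expect_equal(i$ic, 1.722, tolerance = 1e-3)
  expect_equal(i$ic025, 0.876, tolerance = 1e-3)
  # a equal to its expectation gives IC exactly zero
  expect_equal(ic_score(10, 10, 10, 10)$ic, 0)
  # an empty a-cell with a large expectation is a negative IC
  expect_lt(ic_score(0, 100, 100, 100)$ic, 0)
})

test_that("zero cells: continuity correction on for ROR, off yields undefined", {
  s <- ror_score(2, 1, 2, 0)
  ref <- oracle_ror(2, 1, 2, 0)
  expect_equal(s$ror, ref[1])
  expect_equal(s$ror_lo, ref[2])
  expect_false(s$ror_undefined)
  s_off <- ror_score(2, 1, 2, 0, correction = FALSE)
  expect_true(is.na(s_off$ror))
  expect_true(s_off$ror_undefined)
  # PRR with an empty c cell is undefined-flagged
  expect_true(prr_chi2_score(5, 5, 0, 10)$prr_undefined)
})

test_that("vectorized statistics match the brute-force oracle to 1e-10", {
  set.seed(2024)
  n <- 1000
  a <- sample(0:10000, n, replace = TRUE)
  b <- sample(0:10000, n, replace = TRUE)
  c <- sample(1:10000, n, replace = TRUE)
  d <- sample(1:10000, n, replace = TRUE)
  r <- ror_score(a, b, c, d)
  p <- prr_chi2_score(a, b, c, d)
  i <- ic_score(a, b, c, d)
  for (j in seq_len(n)) {
    rr <- oracle_ror(a[j], b[j], c[j], d[j])
    expect_equal(r$ror[j], rr[1], tolerance = 1e-10)
    expect_equal(r$ror_lo[j], rr[2], tolerance = 1e-10)
    expect_equal(r$ror_hi[j], rr[3], tolerance = 1e-10)
    pp <- oracle_prr_chi2(a[j], b[j], c[j], d[j])
    if (a[j] + b[j] > 0) expect_equal(p$prr[j], pp[1], tolerance = 1e-10)
    expect_equal(p$chi2[j], pp[2], tolerance = 1e-10)
    ii <- oracle_ic(a[j], b[j], c[j], d[j])
    expect_equal(i$ic[j], ii[1], tolerance = 1e-10)
    expect_equal(i$ic025[j], ii[2], tolerance = 1e-10)
  }
})

test_that("statistics are nondecreasing in a while a is small against the margins", {
  # ROR and PRR are monotone in a for any fixed b, c, d. IC and EBGM
  # recompute the expected count from the margins, which grows
  # quadratically in a, so their monotonicity holds in the regime
  # a << sqrt(b c) that real pair tables live in.
  prior <- list(alpha1 = 0.5, beta1 = 0.3, alpha2 = 2, beta2 = 2, w = 0.4)
  a <- c(1, 5, 20, 100, 400)
  r <- ror_score(a, 50, 80, 5000)$ror
  p <- prr_chi2_score(a, 50, 80, 5000)$prr
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
  i <- ic_score(a, 5000, 8000, 1e6)$ic
  e <- ebgm_score(a, 5000, 8000, 1e6, prior = prior)$ebgm
  expect_true(all(diff(i) > 0))
  expect_true(all(diff(e) > 0))
})

test_that("EBGM matches the digamma closed form under the unit prior", {
  prior <- list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1, w = 0.5)
  # a = 20, E = 5.7143: posterior Gamma(21, 1 + E)
  s <- ebgm_score(20, 80, 100, 1900, prior = prior)
  E <- (20 + 80) * (20 + 100) / 2100
  expect_equal(s$ebgm, exp(digamma(21)) / (1 + E), tolerance = 1e-8)
  expect_equal(s$ebgm, 3.054, tolerance = 1e-3)
  # a = 0, E = 0: posterior Gamma(1, 1)
  s0 <- ebgm_score(0, 0, 0, 100, prior = prior)
  expect_equal(s0$ebgm, exp(digamma(1)), tolerance = 1e-8)
  expect_equal(s0$ebgm, 0.561, tolerance = 1e-3)
})

test_that("EBGM05 agrees with numeric quadrature of the posterior density", {
  prior <- list(alpha1 = 0.7, beta1 = 0.4, alpha2 = 2.5, beta2 = 2.2, w = 0.35)
  set.seed(5)
  cells <- tibble::tibble(
    a = sample(0:500, 12), b = sample(10:5000, 12),
    c = sample(10:5000, 12), d = sample(100:50000, 12)
  )
  s <- ebgm_score(cells$a, cells$b, cells$c, cells$d, prior = prior)
  for (j in seq_len(nrow(cells))) {
    N <- sum(cells[j, ])
    E <- (cells$a[j] + cells$b[j]) * (cells$a[j] + cells$c[j]) / N
    l1 <- dnbinom(cells$a[j], size = prior$alpha1,
                  prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
    l2 <- dnbinom(cells$a[j], size = prior$alpha2,
                  prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
    q1 <- 1 / (1 + exp(log(1 - prior$w) + l2 - log(prior$w) - l1))
    dens <- function(x) {
      q1 * dgamma(x, prior$alpha1 + cells$a[j], rate = prior$beta1 + E) +
        (1 - q1) * dgamma(x, prior$alpha2 + cells$a[j], rate = prior$beta2 + E)
    }
    # quadrature oracle: integrate the density up to the reported quantile
    mass <- integrate(dens, 0, s$ebgm05[j], rel.tol = 1e-10)$value
    expect_equal(mass, 0.05, tolerance = 1e-6)
    expect_lt(s$ebgm05[j], s$ebgm[j])
  }
})

test_that("shrinkage vanishes as a grows with a/E fixed", {
  prior <- list(alpha1 = 0.5, beta1 = 0.3, alpha2 = 2, beta2 = 2, w = 0.4)
  r_true <- 3
  # cells (a, 0, a, 4a) give E = a/3 exactly
  errs <- sapply(c(10, 100, 10000), function(a) {
    e <- ebgm_score(a, 0, a, 4 * a, prior = prior)$ebgm
    abs(e - r_true)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / r_true, 0.01)
})

test_that("large counts converge: ic to log2(r), ebgm to r", {
  prior <- list(alpha1 = 1, beta1 = 1, alpha2 = 2, beta2 = 2, w = 0.5)
  for (a in c(500, 2000)) {
    # cells (a, 0, a, 6a): E = a 2a / 8a = a/4, so r = 4
    ic <- ic_score(a, 0, a, 6 * a)$ic
    eb <- ebgm_score(a, 0, a, 6 * a, prior = prior)$ebgm
    expect_lt(abs(ic - log2(4)) / log2(4), 0.05)
    expect_lt(abs(eb - 4) / 4, 0.05)
  }
})

test_that("the gamma-mixture fit records its start, guards its preconditions", {
  set.seed(10)
  tb <- tibble::tibble(a = rpois(200, 5), b = 50, c = 50, d = 2000)
  fit <- fit_gamma_mixture(tb)
  expect_s3_class(fit, "gamma_mixture_prior")
  expect_equal(fit$init, c(0.2, 0.1, 2.0, 4.0, 1 / 3))
  expect_true(all(unlist(fit[c("alpha1", "beta1", "alpha2", "beta2")]) > 0))
  expect_true(fit$w > 0 && fit$w < 1)
  # optimum is at least as good as the documented starting point
  E <- (tb$a + tb$b) * (tb$a + tb$c) / (tb$a + tb$b + tb$c + tb$d)
  ll0 <- sum(mgps_marginal_loglik(tb$a, E, 0.2, 0.1, 2.0, 4.0, 1 / 3))
  expect_gte(fit$marginal_loglik, ll0)

  expect_error(fit_gamma_mixture(tb[1:5, ]), "insufficient",
               class = "faersignal_insufficient_pairs")
  tb0 <- tibble::tibble(a = rep(0, 30), b = 10, c = 10, d = 100)
  expect_error(fit_gamma_mixture(tb0), "degenerate",
               class = "faersignal_degenerate_counts")
})

test_that("refit of simulated mixture counts reaches the truth's likelihood", {
  set.seed(31)
  true <- list(alpha1 = 0.8, beta1 = 0.6, alpha2 = 3, beta2 = 3, w = 0.3)
  ncell <- 1500
  E <- rgamma(ncell, 2, 0.5) + 0.05
  comp <- runif(ncell) < true$w
  lam <- ifelse(comp, rgamma(ncell, true$alpha1, true$beta1),
                rgamma(ncell, true$alpha2, true$beta2))
  a <- rpois(ncell, lam * E)
  fit <- fit_gamma_mixture(tibble::tibble(a = a, E = E))
  ll_true <- sum(mgps_marginal_loglik(a, E, true$alpha1, true$beta1,
                                      true$alpha2, true$beta2, true$w))
  expect_gte(fit$marginal_loglik, ll_true - 2)
  expect_true(fit$converged)
  expect_equal(nrow(generics::tidy(fit)), 5)
  expect_true(generics::glance(fit)$converged)
})

test_that("threshold rules are strict where stated and vacuous when undefined", {
  base <- tibble::tibble(a = 100, ror_lo = 1.0, prr = 1, chi2 = 0,
                         ic025 = -1, ebgm05 = 0.5)
  flags <- classify_signal(base)
  expect_false(flags$ror_pos)  # ror_lo == 1 exactly: strict inequality
  expect_false(flags$any_of_four)

  dyspnoea <- tibble::tibble(a = 2965, ror_lo = 3.29, prr = 3.34,
                             chi2 = 4878.94, ic025 = 1.68, ebgm05 = 3.23)
  fd <- classify_signal(dyspnoea)
  expect_true(fd$ror_pos)
  expect_true(fd$any_of_four)

  undef <- tibble::tibble(a = 2, ror_lo = NA_real_, prr = NA_real_,
                          chi2 = NA_real_, ic025 = NA_real_,
                          ebgm05 = NA_real_)
  fu <- classify_signal(undef)
  expect_false(fu$any_of_four)

  # a below the count threshold never flags, however large the ratio
  small <- tibble::tibble(a = 2, ror_lo = 50, prr = 50, chi2 = 500,
                          ic025 = -1, ebgm05 = 50)
  fs <- classify_signal(small)
  expect_false(fs$ror_pos); expect_false(fs$prr_pos); expect_false(fs$mgps_pos)
})
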