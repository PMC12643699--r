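#' Disproportionality statistics for drug-event 2x2 tables
#'
#' Each spontaneous report either mentions a given drug or not, and either
#' mentions a given adverse event or not, giving the 2x2 table
#' \preformatted{
#'                event   other events
#'   drug           a          b
#'   other drugs    c          d
#' }
#' `ror_score()`, `prr_chi2_score()` and `ic_score()` compute the three
#' frequentist/closed-form statistics used for signal detection; the
#' empirical-Bayes EBGM lives in [ebgm_score()]. All are vectorized over the
#' cells.
#'
#' @section Formulas:
#' \itemize{
#'   \item ROR = ad/(bc), with Wald 95\% CI
#'     \eqn{\exp(\log ROR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}.
#'     When any cell is zero and `correction = TRUE` (the default) the
#'     Haldane-Anscombe 0.5 continuity correction is added to all four cells;
#'     with `correction = FALSE` a zero cell yields `NA` and the
#'     `ror_undefined` flag.
#'   \item PRR = (a/(a+b)) / (c/(c+d)); chi-squared is the Pearson statistic
#'     \eqn{N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, optionally Yates-corrected.
#'   \item IC (BCPNN, closed-form shrinkage variant):
#'     \eqn{IC = \log_2((a + 0.5)/(E + 0.5))} with expected count
#'     \eqn{E = (a+b)(a+c)/N}, and credible lower bound
#'     \eqn{IC_{025} = IC - 3.3 (a+0.5)^{-1/2} - 2.4 (a+0.5)^{-1}}.
#' }
#'
#' @param a,b,c,d non-negative numeric vectors of cell counts (recycled).
#' @param correction logical; apply the 0.5 continuity correction to the ROR
#'   when any cell is zero.
#' @param z normal quantile for the ROR confidence interval (1.96 = 95\%).
#' @param yates logical; apply the Yates continuity correction to chi-squared.
#' @return A tibble with one row per table:
#'   `ror_score()` gives `ror, ror_lo, ror_hi, ror_undefined`;
#'   `prr_chi2_score()` gives `prr, chi2, prr_undefined`;
#'   `ic_score()` gives `ic, ic025`.
#' @examples
#' ror_score(20, 80, 100, 1900)   # ror = 4.75
#' prr_chi2_score(20, 80, 100, 1900)
#' ic_score(20, 80, 100, 1900)
#' @export
ror_score <- function(a, b, c, d, correction = TRUE, z = 1.96) {
  n <- max(length(a), length(b), length(c), length(d))
  cells <- vctrs_recycle(a, b, c, d, n = n)
  a <- cells[[1]]; b <- cells[[2]]; c <- cells[[3]]; d <- cells[[4]]
  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  undefined <- zero & !correction
  if (correction && any(zero)) {
    a <- ifelse(zero, a + 0.5, a)
    b <- ifelse(zero, b + 0.5, b)
    c <- ifelse(zero, c + 0.5, c)
    d <- ifelse(zero, d + 0.5, d)
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lo <- exp(log(ror) - z * se)
  hi <- exp(log(ror) + z * se)
  ror[undefined] <- NA_real_
  lo[undefined] <- NA_real_
  hi[undefined] <- NA_real_
  tibble::tibble(ror = ror, ror_lo = lo, ror_hi = hi, ror_undefined = undefined)
}

#' @rdname ror_score
#' @export
prr_chi2_score <- function(a, b, c, d, yates = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  cells <- vctrs_recycle(a, b, c, d, n = n)
  a <- cells[[1]]; b <- cells[[2]]; c <- cells[[3]]; d <- cells[[4]]
  N <- a + b + c + d
  undefined <- (a + b) == 0 | (c + d) == 0 | c == 0
  prr <- (a / (a + b)) / (c / (c + d))
  disc <- abs(a * d - b * c)
  if (yates) disc <- pmax(disc - N / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, N * disc^2 / denom, NA_real_)
  prr[undefined] <- NA_real_
  tibble::tibble(prr = prr, chi2 = chi2, prr_undefined = undefined)
}

#' @rdname ror_score
#' @export
ic_score <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  cells <- vctrs_recycle(a, b, c, d, n = n)
  a <- cells[[1]]; b <- cells[[2]]; c <- cells[[3]]; d <- cells[[4]]
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  ic <- log2((a + 0.5) / (E + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2.4 * (a + 0.5)^(-1)
  tibble::tibble(ic = ic, ic025 = ic025)
}

# recycle scalars against the longest vector, erroring on incompatibility
vctrs_recycle <- function(..., n) {
  lapply(list(...), function(x) {
    if (length(x) == n) return(as.numeric(x))
    if (length(x) == 1) return(rep(as.numeric(x), n))
    stop("incompatible cell vector lengths", call. = FALSE)
  })
}

#' Signal threshold rules
#'
#' The default decision rules, one per algorithm. Each is applied by
#' [classify_signal()]; a pair is a "signal" when at least one algorithm
#' flags it.
#'
#' @param ror_min_a,prr_min_a,mgps_min_a minimum report count `a`.
#' @param ror_lo_gt ROR rule: lower CI bound must exceed this (strict).
#' @param prr_min,chi2_min PRR rule: PRR and chi-squared minima (inclusive).
#' @param ic025_gt BCPNN rule: IC025 must exceed this (strict).
#' @param ebgm05_min MGPS rule: EBGM05 minimum (inclusive).
#' @return a named list of thresholds.
#' @export
signal_thresholds <- function(ror_min_a = 3, ror_lo_gt = 1,
                              prr_min_a = 3, prr_min = 2, chi2_min = 4,
                              ic025_gt = 0,
                              mgps_min_a = 3, ebgm05_min = 2) {
  list(
    ror_min_a = ror_min_a, ror_lo_gt = ror_lo_gt,
    prr_min_a = prr_min_a, prr_min = prr_min, chi2_min = chi2_min,
    ic025_gt = ic025_gt,
    mgps_min_a = mgps_min_a, ebgm05_min = ebgm05_min
  )
}

#' Classify scored pairs against the four threshold rules
#'
#' Adds per-algorithm logical flags and their disjunction `any_of_four`.
#' An undefined statistic (e.g. ROR with a zero cell and no continuity
#' correction) never flags.
#'
#' @param scores a tibble as returned by [signal_scores()] (must contain
#'   `a`, `ror_lo`, `prr`, `chi2`, `ic025`, `ebgm05`).
#' @param thresholds a list from [signal_thresholds()].
#' @return `scores` with columns `ror_pos`, `prr_pos`, `bcpnn_pos`,
#'   `mgps_pos`, `any_of_four` appended.
#' @export
classify_signal <- function(scores, thresholds = signal_thresholds()) {
  th <- thresholds
  flag <- function(x) !is.na(x) & x
  scores |>
    dplyr::mutate(
      ror_pos = flag(.data$a >= th$ror_min_a & .data$ror_lo > th$ror_lo_gt),
      prr_pos = flag(.data$a >= th$prr_min_a & .data$prr >= th$prr_min &
                       .data$chi2 >= th$chi2_min),
      bcpnn_pos = flag(.data$ic025 > th$ic025_gt),
      mgps_pos = flag(.data$a >= th$mgps_min_a & .data$ebgm05 >= th$ebgm05_min),
      any_of_four = .data$ror_pos | .data$prr_pos | .data$bcpnn_pos |
        .data$mgps_pos
    )
}

#' Score every contingency table with all four algorithms
#'
#' Computes ROR (with 95\% CI), PRR (with Pearson chi-squared), the BCPNN
#' information component (with IC025) and the MGPS EBGM (with EBGM05) for
#' each row of a contingency-table tibble, then applies the threshold rules.
#' The MGPS prior is fitted across all supplied tables unless one is given;
#' it should always be fitted on the same granularity (PT or SOC) as the
#' tables being scored.
#'
#' @param tables a tibble with columns `a`, `b`, `c`, `d` (one row per
#'   drug-event pair), e.g. from [build_pair_tables()].
#' @param prior a `gamma_mixture_prior` from [fit_gamma_mixture()], or `NULL`
#'   to fit one on `tables`. If fitting fails or there are too few tables,
#'   EBGM columns are `NA` and the MGPS flag stays `FALSE`.
#' @param correction,z,yates passed to the individual statistics.
#' @param thresholds passed to [classify_signal()].
#' @return `tables` with score and flag columns appended; the fitted prior is
#'   attached as attribute `"prior"`.
#' @export
signal_scores <- function(tables, prior = NULL,
                          correction = TRUE, z = 1.96, yates = FALSE,
                          thresholds = signal_thresholds()) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  out <- dplyr::bind_cols(
    tables,
    ror_score(tables$a, tables$b, tables$c, tables$d,
              correction = correction, z = z),
    prr_chi2_score(tables$a, tables$b, tables$c, tables$d, yates = yates),
    ic_score(tables$a, tables$b, tables$c, tables$d)
  )
  if (is.null(prior) && nrow(tables) >= 20) {
    prior <- tryCatch(fit_gamma_mixture(tables), error = function(e) NULL)
  }
  if (!is.null(prior)) {
    eb <- ebgm_score(tables$a, tables$b, tables$c, tables$d, prior = prior)
    out$ebgm <- eb$ebgm
    out$ebgm05 <- eb$ebgm05
  } else {
    out$ebgm <- NA_real_
    out$ebgm05 <- NA_real_
  }
  out <- classify_signal(out, thresholds)
  attr(out, "prior") <- prior
  out
}
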