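#' Time-to-onset records for one drug
#'
#' Time-to-onset (TTO) is the number of days between the earliest
#' full-precision therapy start date for the drug within a report and the
#' report's adverse event date. Records are excluded, with per-reason
#' tallies, when either date is missing or only partially known (YYYYMM or
#' YYYY precision) or when the difference is negative.
#'
#' @param cases a `faers_cases` collection from [build_case_reports()].
#' @param drug standardized drug name to extract onsets for.
#' @return a tibble with columns `primaryid`, `drug`, `days`
#'   (non-negative integer). Exclusion tallies are attached as attribute
#'   `"excluded"` (named counts: `partial_date`, `missing`, `negative`) and
#'   also available via [tto_exclusions()].
#' @export
compute_tto <- function(cases, drug) {
  stopifnot(inherits(cases, "faers_cases"))
  starts <- cases$drugs |>
    dplyr::filter(.data$standard_name == drug)

  demo <- cases$demo |>
    dplyr::select("primaryid", "event_date", "event_precision")

  per_report <- starts |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      start = if (any(.data$start_precision == "day")) {
        min(.data$start_date[.data$start_precision == "day"])
      } else as.Date(NA),
      # a report whose only start dates are partial is excluded as partial,
      # one with no start date at all as missing
      start_reason = if (any(.data$start_precision == "day")) "ok"
        else if (any(.data$start_precision %in% c("month", "year"))) "partial_date"
        else "missing",
      .groups = "drop"
    ) |>
    dplyr::left_join(demo, by = "primaryid") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$start_reason != "ok" ~ .data$start_reason,
        .data$event_precision == "day" & !is.na(.data$event_date) &
          as.integer(.data$event_date - .data$start) < 0 ~ "negative",
        .data$event_precision == "day" & !is.na(.data$event_date) ~ "ok",
        .data$event_precision %in% c("month", "year") ~ "partial_date",
        TRUE ~ "missing"
      )
    )

  kept <- per_report |>
    dplyr::filter(.data$reason == "ok") |>
    dplyr::transmute(
      primaryid = .data$primaryid,
      drug = drug,
      days = as.integer(.data$event_date - .data$start)
    )

  excluded <- c(
    partial_date = sum(per_report$reason == "partial_date"),
    missing = sum(per_report$reason == "missing"),
    negative = sum(per_report$reason == "negative")
  )
  attr(kept, "excluded") <- excluded
  kept
}

#' @rdname compute_tto
#' @param records a tibble returned by [compute_tto()].
#' @export
tto_exclusions <- function(records) {
  attr(records, "excluded")
}

#' Summarize a time-to-onset sample
#'
#' Median and interquartile range by linear interpolation between order
#' statistics (`stats::quantile()` type 7).
#'
#' @param records a tibble from [compute_tto()] with a `days` column, or a
#'   bare numeric vector of onset days.
#' @return a one-row tibble: `n`, `median`, `q1`, `q3`.
#' @export
summarize_tto <- function(records) {
  days <- if (is.numeric(records)) records else records$days
  if (length(days) == 0) {
    abort_faersignal("empty sample: no time-to-onset records",
                     "faersignal_empty_sample")
  }
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = length(days), median = q[2], q1 = q[1], q3 = q[3])
}

#' Fit a two-parameter Weibull to onset times by maximum likelihood
#'
#' The Weibull density with shape \eqn{\beta} and scale \eqn{\alpha} has
#' log-likelihood
#' \deqn{\ell(\alpha, \beta) = n \log\beta - n\beta \log\alpha +
#'   (\beta - 1)\sum \log t_i - \sum (t_i/\alpha)^\beta .}
#' The scale is profiled out in closed form,
#' \eqn{\hat\alpha(\beta) = (\sum t_i^\beta / n)^{1/\beta}}, and the profile
#' score for \eqn{\beta} is solved by Newton iteration to a tolerance of
#' 1e-10. Wald 95\% confidence intervals come from the observed information
#' on \eqn{(\log\alpha, \log\beta)}, transformed back to the natural scale.
#' The sample is treated as complete (spontaneous reports carry only
#' observed onsets, so there is no censoring).
#'
#' Zero-day onsets (same-day events, common for infusion reactions) would
#' make the log-likelihood unbounded for \eqn{\beta < 1}; by default they
#' are mapped to half a day (`zero_handling = "half_day"`); set
#' `zero_handling = "exclude"` to drop them instead.
#'
#' @param records a tibble from [compute_tto()] or a numeric vector of
#'   non-negative onset days. At least 10 strictly positive values are
#'   required after zero handling.
#' @param zero_handling `"half_day"` (default) or `"exclude"`.
#' @param conf_level confidence level for the Wald intervals.
#' @return an object of class `weibull_fit`: shape and scale estimates with
#'   confidence intervals, `n`, `loglik` and the `failure_type` label from
#'   [classify_failure_type()].
#' @examples
#' set.seed(1)
#' fit <- fit_weibull(rweibull(500, shape = 0.7, scale = 50))
#' fit
#' generics::tidy(fit)
#' @export
fit_weibull <- function(records, zero_handling = c("half_day", "exclude"),
                        conf_level = 0.95) {
  zero_handling <- match.arg(zero_handling)
  t <- if (is.numeric(records)) as.numeric(records) else as.numeric(records$days)
  t <- t[!is.na(t)]
  if (any(t < 0)) {
    abort_faersignal("negative onset times are not allowed",
                     "faersignal_invalid_sample")
  }
  if (zero_handling == "half_day") t[t == 0] <- 0.5 else t <- t[t > 0]
  n <- length(t)
  if (n < 10) {
    abort_faersignal("insufficient sample: need >= 10 positive onset times",
                     "faersignal_insufficient_sample")
  }
  if (stats::sd(t) == 0) {
    abort_faersignal("degenerate sample: all onset times identical",
                     "faersignal_degenerate_sample")
  }

  # work on t scaled by its geometric mean: beta is scale-invariant and the
  # powers t^beta stay well conditioned
  s <- exp(mean(log(t)))
  u <- t / s
  lu <- log(u)

  profile_score <- function(beta) {
    ub <- u^beta
    1 / beta + mean(lu) - sum(ub * lu) / sum(ub)
  }
  profile_score_deriv <- function(beta) {
    ub <- u^beta
    sw <- sum(ub)
    s1 <- sum(ub * lu)
    s2 <- sum(ub * lu^2)
    -1 / beta^2 - (s2 * sw - s1^2) / sw^2
  }

  # moment start from the extreme-value representation: sd(log t) = pi/(beta sqrt 6)
  beta <- pi / (stats::sd(lu) * sqrt(6))
  for (iter in 1:100) {
    step <- profile_score(beta) / profile_score_deriv(beta)
    beta_new <- beta - step
    if (beta_new <= 0) beta_new <- beta / 2
    if (abs(beta_new - beta) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  alpha_u <- (sum(u^beta) / n)^(1 / beta)
  alpha <- s * alpha_u

  loglik <- weibull_loglik(t, alpha, beta)

  # observed information on (log alpha, log beta)
  nll <- function(theta) -weibull_loglik(t, exp(theta[1]), exp(theta[2]))
  H <- stats::optimHess(c(log(alpha), log(beta)), nll)
  ci <- tryCatch({
    V <- solve(H)
    se <- sqrt(diag(V))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    list(
      scale = exp(log(alpha) + c(-1, 1) * z * se[1]),
      shape = exp(log(beta) + c(-1, 1) * z * se[2])
    )
  }, error = function(e) list(scale = c(NA_real_, NA_real_),
                              shape = c(NA_real_, NA_real_)))

  fit <- structure(
    list(
      shape = beta, shape_lo = ci$shape[1], shape_hi = ci$shape[2],
      scale = alpha, scale_lo = ci$scale[1], scale_hi = ci$scale[2],
      n = n, loglik = loglik, conf_level = conf_level,
      data = t
    ),
    class = "weibull_fit"
  )
  fit$failure_type <- classify_failure_type(fit)
  fit
}

weibull_loglik <- function(t, alpha, beta) {
  n <- length(t)
  n * log(beta) - n * beta * log(alpha) + (beta - 1) * sum(log(t)) -
    sum((t / alpha)^beta)
}

#' Classify the hazard shape of a Weibull fit
#'
#' The Weibull shape parameter determines whether event incidence falls,
#' stays constant or rises with time on treatment: `"early"` failure when
#' the whole shape CI lies below 1, `"wear_out"` when it lies above 1,
#' `"random"` (exponential-like) when the CI contains 1, and
#' `"indeterminate"` when the CI is undefined.
#'
#' @param fit a `weibull_fit` from [fit_weibull()], or any list with
#'   `shape_lo` and `shape_hi`.
#' @return one of `"early"`, `"random"`, `"wear_out"`, `"indeterminate"`.
#' @export
classify_failure_type <- function(fit) {
  lo <- fit$shape_lo
  hi <- fit$shape_hi
  if (is.null(lo) || is.null(hi) || is.na(lo) || is.na(hi)) {
    return("indeterminate")
  }
  if (hi < 1) "early" else if (lo > 1) "wear_out" else "random"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull time-to-onset fit (n = %d, complete sample MLE)\n", x$n))
  cat(sprintf("  scale alpha = %.2f days (%.0f%% CI %.2f-%.2f)\n",
              x$scale, 100 * x$conf_level, x$scale_lo, x$scale_hi))
  cat(sprintf("  shape beta  = %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$shape, 100 * x$conf_level, x$shape_lo, x$shape_hi))
  cat(sprintf("  failure type: %s; log-likelihood %.2f\n",
              x$failure_type, x$loglik))
  invisible(x)
}

#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(
    term = c("scale", "shape"),
    estimate = c(x$scale, x$shape),
    conf.low = c(x$scale_lo, x$shape_lo),
    conf.high = c(x$scale_hi, x$shape_hi)
  )
}

#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    logLik = x$loglik,
    failure_type = x$failure_type,
    median = x$scale * log(2)^(1 / x$shape)
  )
}
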