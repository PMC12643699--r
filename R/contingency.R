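#' Build drug-event 2x2 contingency tables
#'
#' For each (drug, event) pair, counts reports at the report level:
#' `a` = reports mentioning the drug (in a suspect role) and the event,
#' `b` = drug without the event, `c` = event without the drug,
#' `d` = neither; `N = a + b + c + d` is the total number of cleaned
#' reports and is identical across all pairs. A report contributes at most
#' once per pair no matter how often a drug or PT repeats within it; at SOC
#' granularity a report counts once per SOC regardless of how many of its
#' PTs map there.
#'
#' The comparator is the full cleaned collection (all other reports,
#' including those of other study drugs); `exclude_drugs` removes reports
#' whose suspect set intersects the given names from the universe first.
#'
#' @param cases a `faers_cases` collection from [build_case_reports()].
#' @param target_drugs standardized drug names to build tables for;
#'   default: every drug appearing in a suspect role.
#' @param granularity `"PT"` (preferred term) or `"SOC"` (system organ
#'   class; requires reactions to carry a `soc` column from a dictionary).
#' @param suspect_roles role codes defining drug exposure
#'   (default `c("PS", "SS")`: primary and secondary suspect; set to
#'   `"PS"` for primary-suspect-only).
#' @param exclude_drugs drugs whose reports are removed from the comparator
#'   universe entirely.
#' @return a tibble with columns `drug`, `event`, `granularity`,
#'   `a`, `b`, `c`, `d`, `N`, one row per (target drug, observed event).
#' @export
build_pair_tables <- function(cases,
                              target_drugs = NULL,
                              granularity = c("PT", "SOC"),
                              suspect_roles = c("PS", "SS"),
                              exclude_drugs = character()) {
  stopifnot(inherits(cases, "faers_cases"))
  granularity <- match.arg(granularity)
  if (nrow(cases$demo) == 0) {
    abort_faersignal("no reports in the case collection",
                     "faersignal_no_reports")
  }

  exposure <- cases$drugs |>
    dplyr::filter(.data$role_cod %in% suspect_roles) |>
    dplyr::distinct(.data$primaryid, drug = .data$standard_name)

  universe <- cases$demo$primaryid
  if (length(exclude_drugs) > 0) {
    drop_ids <- exposure$primaryid[exposure$drug %in% exclude_drugs]
    universe <- setdiff(universe, drop_ids)
    exposure <- exposure |>
      dplyr::filter(!.data$drug %in% exclude_drugs,
                    .data$primaryid %in% universe)
  }
  N <- length(universe)

  event_col <- if (granularity == "PT") "pt" else "soc"
  events <- cases$reactions |>
    dplyr::filter(.data$primaryid %in% universe) |>
    dplyr::distinct(.data$primaryid, event = .data[[event_col]])

  if (is.null(target_drugs)) target_drugs <- sort(unique(exposure$drug))

  n_event <- events |> dplyr::count(.data$event, name = "n_e")

  purrr::map_dfr(target_drugs, function(D) {
    ids_d <- exposure$primaryid[exposure$drug == D]
    n_d <- length(ids_d)
    a_tbl <- events |>
      dplyr::filter(.data$primaryid %in% ids_d) |>
      dplyr::count(.data$event, name = "a")
    n_event |>
      dplyr::left_join(a_tbl, by = "event") |>
      dplyr::mutate(
        drug = D,
        granularity = granularity,
        a = dplyr::coalesce(.data$a, 0L),
        b = n_d - .data$a,
        c = .data$n_e - .data$a,
        d = N - n_d - .data$c,
        N = N
      ) |>
      dplyr::select("drug", "event", "granularity", "a", "b", "c", "d", "N")
  })
}
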