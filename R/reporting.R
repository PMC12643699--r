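#' Percentage of a count, rounded half-up
#'
#' The percentage arithmetic used throughout the demographic summary:
#' `100 * count / total`, rounded half away from zero at `digits` decimals
#' (the convention used in published report tables, so printed cells
#' recompute exactly from their counts).
#'
#' @param count,total numeric vectors.
#' @param digits decimal places (1 for sex/age blocks, 2 for weight).
#' @return numeric percentages.
#' @examples
#' report_percent(19699, 31007)  # 63.5
#' report_percent(2761, 7389)    # 37.4
#' @export
report_percent <- function(count, total, digits = 1) {
  round_half_up(100 * count / total, digits)
}

#' Demographic summary for one drug's reports
#'
#' Tabulates the reports carrying a drug in a suspect role: sex, age bins
#' (`<18` = [0,18), `18-65` = [18,65], `65-85` = (65,85], `>85` = (85,Inf);
#' the boundary ages 18 and 65 fall in `18-65` and 85 in `65-85`), weight
#' bins (`<50`, `50-69` = [50,70), `70-89` = [70,90), `>=90`), top-k
#' indications and top-k countries, each with counts and percentages of the
#' drug's total reports (half-up; 1 decimal for sex/age/indication/country,
#' 2 for weight).
#'
#' @param cases a `faers_cases` collection.
#' @param drug standardized drug name.
#' @param suspect_roles role codes defining exposure.
#' @param top_k how many indications/countries to list.
#' @return a tibble with columns `block`, `category`, `n`, `pct`; the
#'   drug's total report count, median age and age IQR are attached as
#'   attributes `"total"`, `"age_median"`, `"age_iqr"`.
#' @export
demographic_summary <- function(cases, drug, suspect_roles = c("PS", "SS"),
                                top_k = 5) {
  stopifnot(inherits(cases, "faers_cases"))
  ids <- cases$drugs |>
    dplyr::filter(.data$role_cod %in% suspect_roles,
                  .data$standard_name == drug) |>
    dplyr::pull("primaryid") |>
    unique()
  if (length(ids) == 0 && !drug %in% cases$drugs$standard_name) {
    abort_faersignal(sprintf("unknown drug: %s", drug),
                     "faersignal_unknown_drug")
  }
  demo <- cases$demo |> dplyr::filter(.data$primaryid %in% ids)
  total <- nrow(demo)

  block_tbl <- function(block, category, n, digits) {
    tibble::tibble(block = block, category = category, n = as.integer(n),
                   pct = if (total > 0) report_percent(n, total, digits)
                         else rep(0, length(n)))
  }

  sex_counts <- c(
    F = sum(demo$sex %in% "F"),
    M = sum(demo$sex %in% "M"),
    missing = sum(is.na(demo$sex))
  )
  sex <- block_tbl("sex", names(sex_counts), sex_counts, 1)

  age <- demo$age_years
  age_counts <- c(
    "<18" = sum(!is.na(age) & age < 18),
    "18-65" = sum(!is.na(age) & age >= 18 & age <= 65),
    "65-85" = sum(!is.na(age) & age > 65 & age <= 85),
    ">85" = sum(!is.na(age) & age > 85),
    missing = sum(is.na(age))
  )
  age_tbl <- block_tbl("age", names(age_counts), age_counts, 1)

  wt <- demo$weight_kg
  wt_counts <- c(
    "<50" = sum(!is.na(wt) & wt < 50),
    "50-69" = sum(!is.na(wt) & wt >= 50 & wt < 70),
    "70-89" = sum(!is.na(wt) & wt >= 70 & wt < 90),
    ">=90" = sum(!is.na(wt) & wt >= 90),
    missing = sum(is.na(wt))
  )
  wt_tbl <- block_tbl("weight", names(wt_counts), wt_counts, 2)

  top_block <- function(tbl, col, block) {
    if (nrow(tbl) == 0) {
      return(tibble::tibble(block = character(), category = character(),
                            n = integer(), pct = numeric()))
    }
    tbl |>
      dplyr::count(category = .data[[col]], sort = TRUE) |>
      dplyr::slice_head(n = top_k) |>
      dplyr::mutate(block = block,
                    pct = report_percent(.data$n, total, 1)) |>
      dplyr::select("block", "category", "n", "pct")
  }
  indi <- top_block(
    cases$indications |> dplyr::filter(.data$primaryid %in% ids),
    "pt", "indication")
  ctry <- top_block(
    demo |> dplyr::filter(!is.na(.data$country)), "country", "country")

  out <- dplyr::bind_rows(sex, age_tbl, wt_tbl, indi, ctry)
  attr(out, "total") <- total
  attr(out, "age_median") <- if (any(!is.na(age))) {
    stats::median(age, na.rm = TRUE)
  } else NA_real_
  attr(out, "age_iqr") <- if (any(!is.na(age))) {
    unname(stats::quantile(age, c(0.25, 0.75), na.rm = TRUE))
  } else c(NA_real_, NA_real_)
  out
}

#' Yearly report counts for one drug
#'
#' Counts reports by receipt year (`report_year`); years with no reports
#' inside the observed range are filled with zero.
#'
#' @param cases a `faers_cases` collection.
#' @param drug standardized drug name.
#' @param suspect_roles role codes defining exposure.
#' @return a tibble with columns `year`, `n` (empty if no dated reports).
#' @export
yearly_counts <- function(cases, drug, suspect_roles = c("PS", "SS")) {
  ids <- cases$drugs |>
    dplyr::filter(.data$role_cod %in% suspect_roles,
                  .data$standard_name == drug) |>
    dplyr::pull("primaryid") |>
    unique()
  years <- cases$demo |>
    dplyr::filter(.data$primaryid %in% ids, !is.na(.data$report_year)) |>
    dplyr::pull("report_year")
  if (length(years) == 0) {
    return(tibble::tibble(year = integer(), n = integer()))
  }
  tibble::tibble(year = years) |>
    dplyr::count(.data$year) |>
    tidyr::complete(year = seq(min(years), max(years)),
                    fill = list(n = 0L)) |>
    dplyr::arrange(.data$year)
}

#' Top events by report count
#'
#' Ranks scored pairs by their report count `a` (descending), ties broken
#' alphabetically by event name, and returns the first `n`.
#'
#' @param scores a scored-pair tibble with columns `event` and `a`.
#' @param n how many to return (all, if fewer are available).
#' @return the top rows of `scores`, re-ordered.
#' @export
top_events <- function(scores, n = 20) {
  scores |>
    dplyr::arrange(dplyr::desc(.data$a), .data$event) |>
    dplyr::slice_head(n = n)
}

#' Cross-drug overlap of qualifying signals
#'
#' For each drug, the qualifying set is the events flagged by the ROR rule
#' with at least `min_count` reports. All pairwise and triple intersections
#' and the union are computed exactly; the inclusion-exclusion identity
#' over the stored counts is an invariant of the result.
#'
#' @param scores a scored-pair tibble with columns `drug`, `event`, `a`,
#'   `ror_pos` (e.g. [signal_scores()] output over several drugs).
#' @param min_count minimum cumulative report count to qualify
#'   (default 100).
#' @return an object of class `overlap_result`: list with `sets` (named
#'   list of event vectors), `intersections` (tibble `combo`, `n`),
#'   `union_n` and `min_count`.
#' @export
overlap_sets <- function(scores, min_count = 100) {
  qual <- scores |>
    dplyr::filter(.data$ror_pos, .data$a >= min_count)
  sets <- split(qual$event, qual$drug)
  sets <- lapply(sets, unique)
  drugs <- names(sets)
  combos <- unlist(lapply(seq_along(drugs), function(k) {
    utils::combn(drugs, k, simplify = FALSE)
  }), recursive = FALSE)
  inter <- purrr::map_dfr(combos, function(cb) {
    tibble::tibble(
      combo = paste(cb, collapse = " & "),
      size = length(cb),
      n = length(Reduce(intersect, sets[cb]))
    )
  })
  structure(
    list(sets = sets,
         intersections = inter,
         union_n = length(unique(unlist(sets))),
         min_count = min_count),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Qualifying PT signal overlap (ROR-positive, a >= %d)\n",
              x$min_count))
  for (d in names(x$sets)) {
    cat(sprintf("  %s: %d signals\n", d, length(x$sets[[d]])))
  }
  print(x$intersections)
  cat(sprintf("  union: %d\n", x$union_n))
  invisible(x)
}

#' @export
tidy.overlap_result <- function(x, ...) {
  x$intersections
}

#' Flag signal-positive events absent from a known-term list
#'
#' Annotates scored pairs with a `candidate_novel` column: `TRUE` for
#' events flagged by at least one algorithm and absent from the supplied
#' list of labeled/known terms; with `known_terms = NULL` the column is
#' emitted all-`NA` (no claim either way).
#'
#' @param scores a scored-pair tibble with `event` and `any_of_four`.
#' @param known_terms character vector of known/labeled PTs, or `NULL`.
#' @return `scores` with `candidate_novel` appended.
#' @export
flag_candidate_novel <- function(scores, known_terms = NULL) {
  if (is.null(known_terms)) {
    scores$candidate_novel <- NA
    return(scores)
  }
  scores |>
    dplyr::mutate(candidate_novel = .data$any_of_four &
                    !.data$event %in% known_terms)
}

#' Run the whole pipeline on a synthetic dataset
#'
#' Executes simulate -> write -> parse -> clean -> contingency (PT and SOC)
#' -> scores -> per-drug TTO -> report surfaces, writing `table1.json`,
#' `yearly.csv`, `table2_soc.csv`, `table3_pt.csv`, `overlap.json`,
#' `tto.json`, `tto_hist.csv` and `manifest.json` into `out_dir`.
#' No timestamps are written, so a rerun with the same config is
#' byte-identical. Any stage failure aborts with the stage name.
#'
#' @param config a `faers_sim_config`; its `seed` drives all randomness.
#' @param out_dir output directory.
#' @param min_count,top_n reporting parameters (overlap qualification and
#'   top-event list length).
#' @param thresholds signal threshold rules.
#' @return invisibly, the manifest list (stages, row counts, config hash).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         min_count = 100, top_n = 20,
                         thresholds = signal_thresholds()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_faersignal(sprintf("pipeline stage `%s` failed: %s",
                               name, conditionMessage(e)),
                       "faersignal_pipeline_error")
    })
  }

  raw_dir <- file.path(out_dir, "faers_raw")
  sim <- stage("simulate", {
    s <- simulate_faers(config)
    write_faers_tables(s, raw_dir)
    s
  })
  dict <- config$events[, c("pt", "soc")]
  cases <- stage("etl", {
    raw <- read_faers_tables(raw_dir)
    build_case_reports(raw, synonym_map = NULL, dict = dict)
  })
  pt_tables <- stage("contingency", build_pair_tables(cases, granularity = "PT"))
  soc_tables <- stage("contingency",
                      build_pair_tables(cases, granularity = "SOC"))
  pt_scores <- stage("signals",
                     signal_scores(pt_tables, thresholds = thresholds))
  soc_scores <- stage("signals",
                      signal_scores(soc_tables, thresholds = thresholds))

  drugs <- config$drugs$drug
  tto_list <- stage("tto", lapply(drugs, function(d) {
    rec <- compute_tto(cases, d)
    fit <- tryCatch(fit_weibull(rec), error = function(e) NULL)
    summ <- tryCatch(summarize_tto(rec), error = function(e) NULL)
    list(
      drug = d,
      n = nrow(rec),
      median = if (!is.null(summ)) summ$median else NA,
      iqr = if (!is.null(summ)) c(summ$q1, summ$q3) else c(NA, NA),
      alpha = if (!is.null(fit)) fit$scale else NA,
      alpha_ci = if (!is.null(fit)) c(fit$scale_lo, fit$scale_hi) else c(NA, NA),
      beta = if (!is.null(fit)) fit$shape else NA,
      beta_ci = if (!is.null(fit)) c(fit$shape_lo, fit$shape_hi) else c(NA, NA),
      failure_type = if (!is.null(fit)) fit$failure_type else "indeterminate",
      excluded = as.list(tto_exclusions(rec))
    )
  }))
  tto_hist <- stage("tto", purrr::map_dfr(drugs, function(d) {
    rec <- compute_tto(cases, d)
    if (nrow(rec) == 0) return(tibble::tibble())
    tibble::tibble(drug = d,
                   bin = floor(rec$days / 30) * 30) |>
      dplyr::count(.data$drug, .data$bin, name = "n")
  }))

  report <- stage("report", {
    table1 <- lapply(drugs, function(d) {
      s <- demographic_summary(cases, d)
      list(drug = d, total = attr(s, "total"),
           age_median = attr(s, "age_median"),
           age_iqr = attr(s, "age_iqr"),
           blocks = s)
    })
    yearly <- purrr::map_dfr(drugs, function(d) {
      yearly_counts(cases, d) |> dplyr::mutate(drug = d, .before = 1)
    })
    overlap <- overlap_sets(pt_scores, min_count = min_count)
    top <- purrr::map_dfr(drugs, function(d) {
      top_events(pt_scores |> dplyr::filter(.data$drug == d), n = top_n)
    })
    jsonlite::write_json(table1, file.path(out_dir, "table1.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(yearly, file.path(out_dir, "yearly.csv"))
    readr::write_csv(soc_scores, file.path(out_dir, "table2_soc.csv"))
    readr::write_csv(top, file.path(out_dir, "table3_pt.csv"))
    readr::write_csv(pt_scores, file.path(out_dir, "scores_pt_full.csv"))
    jsonlite::write_json(
      list(sets = overlap$sets, intersections = overlap$intersections,
           union_n = overlap$union_n, min_count = overlap$min_count),
      file.path(out_dir, "overlap.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(tto_list, file.path(out_dir, "tto.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(tto_hist, file.path(out_dir, "tto_hist.csv"))
    TRUE
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = c("simulate", "etl", "contingency", "signals", "tto", "report"),
    rows = list(
      demo = nrow(sim$tables$demo),
      cases = nrow(cases$demo),
      pt_pairs = nrow(pt_tables),
      soc_pairs = nrow(soc_tables)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
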