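#' Configuration for the synthetic FAERS report generator
#'
#' Builds and validates the parameter set for [simulate_faers()]. The
#' defaults emulate a three-drug chemotherapy pharmacovigilance study:
#' paclitaxel, vincristine and irinotecan as suspect drugs, a vocabulary of
#' hematologic, gastrointestinal, neurological and general-disorder
#' preferred terms with background reporting rates, a handful of planted
#' drug-event signals at relative reporting rates between 3 and 9, per-drug
#' Weibull onset-time distributions with shape < 1 (early-failure hazards),
#' demographic mixtures with missingness, a 5\% duplicate-case rate and a
#' 5\% partial-date rate.
#'
#' @param n_reports number of distinct cases to generate.
#' @param drugs tibble with columns `drug` (name) and `exposure`
#'   (marginal probability that a report slot draws this drug; normalized).
#' @param events tibble with columns `pt`, `soc`, `background`
#'   (per-report probability of the event absent any signal).
#' @param planted_signals tibble with columns `drug`, `pt`, `relative_rate`
#'   (>= 0); pairs not listed have relative rate 1. A report's probability
#'   of an event is `background * max(relative_rate over its drugs)`,
#'   capped at 1.
#' @param tto tibble with columns `drug`, `shape`, `scale`: Weibull
#'   onset-time parameters in days, both strictly positive.
#' @param demographics list with elements `sex` (named probabilities over
#'   `F`, `M`, `missing`), `age` (list: `child_frac`, `child_range`,
#'   `adult_mean`, `adult_sd`, `missing_frac`), `weight` (list: `mean`,
#'   `sd`, `missing_frac`) and `countries` (named probabilities, may include
#'   `missing`).
#' @param duplicate_fraction fraction of cases re-emitted as a later
#'   version of the same caseid, in `[0, 1)`.
#' @param partial_date_fraction fraction of date fields written with
#'   month (YYYYMM) or year (YYYY) precision only, in `[0, 1)`.
#' @param date_range character vector of two dates (YYYY-MM-DD) bounding
#'   event dates.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return a validated list of class `faers_sim_config`.
#' @export
sim_config <- function(n_reports = 10000,
                       drugs = default_sim_drugs(),
                       events = default_sim_events(),
                       planted_signals = default_sim_signals(),
                       tto = default_sim_tto(),
                       demographics = default_sim_demographics(),
                       duplicate_fraction = 0.05,
                       partial_date_fraction = 0.05,
                       date_range = c("2004-01-01", "2024-12-31"),
                       seed = 1L) {
  cfg <- list(
    n_reports = n_reports, drugs = tibble::as_tibble(drugs),
    events = tibble::as_tibble(events),
    planted_signals = tibble::as_tibble(planted_signals),
    tto = tibble::as_tibble(tto), demographics = demographics,
    duplicate_fraction = duplicate_fraction,
    partial_date_fraction = partial_date_fraction,
    date_range = as.Date(date_range), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "faers_sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    abort_faersignal(sprintf("invalid config field `%s`: %s", field, why),
                     "faersignal_config_error")
  }
  if (!is.numeric(cfg$n_reports) || cfg$n_reports < 1) {
    bad("n_reports", "must be a positive integer")
  }
  if (!all(c("drug", "exposure") %in% names(cfg$drugs))) {
    bad("drugs", "needs columns drug, exposure")
  }
  if (any(cfg$drugs$exposure < 0) || all(cfg$drugs$exposure == 0)) {
    bad("drugs", "exposure probabilities must be non-negative, not all zero")
  }
  if (!all(c("pt", "soc", "background") %in% names(cfg$events))) {
    bad("events", "needs columns pt, soc, background")
  }
  if (any(cfg$events$background < 0 | cfg$events$background > 1)) {
    bad("events", "background probabilities must lie in [0, 1]")
  }
  ps <- cfg$planted_signals
  if (nrow(ps) > 0) {
    if (!all(c("drug", "pt", "relative_rate") %in% names(ps))) {
      bad("planted_signals", "needs columns drug, pt, relative_rate")
    }
    if (!all(ps$drug %in% cfg$drugs$drug)) {
      bad("planted_signals", "references undeclared drug")
    }
    if (!all(ps$pt %in% cfg$events$pt)) {
      bad("planted_signals", "references undeclared event")
    }
    if (any(ps$relative_rate < 0)) {
      bad("planted_signals", "relative_rate must be >= 0")
    }
  }
  if (!all(cfg$drugs$drug %in% cfg$tto$drug)) {
    bad("tto", "every drug needs Weibull onset parameters")
  }
  if (any(cfg$tto$shape <= 0) || any(cfg$tto$scale <= 0)) {
    bad("tto", "shape and scale must be strictly positive")
  }
  for (f in c("duplicate_fraction", "partial_date_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v >= 1) bad(f, "must lie in [0, 1)")
  }
  sexp <- cfg$demographics$sex
  if (is.null(sexp) || any(sexp < 0) || any(sexp > 1)) {
    bad("demographics", "sex probabilities must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_sim_drugs <- function() {
  tibble::tibble(
    drug = c("paclitaxel", "vincristine", "irinotecan"),
    exposure = c(0.45, 0.25, 0.30)
  )
}

#' @rdname sim_config
#' @export
default_sim_events <- function() {
  tibble::tribble(
    ~pt,                       ~soc,                                        ~background,
    "Neutropenia",             "Blood and lymphatic system disorders",      0.050,
    "Anaemia",                 "Blood and lymphatic system disorders",      0.045,
    "Febrile neutropenia",     "Blood and lymphatic system disorders",      0.030,
    "Thrombocytopenia",        "Blood and lymphatic system disorders",      0.035,
    "Leukopenia",              "Blood and lymphatic system disorders",      0.025,
    "Pancytopenia",            "Blood and lymphatic system disorders",      0.015,
    "Diarrhoea",               "Gastrointestinal disorders",                0.080,
    "Nausea",                  "Gastrointestinal disorders",                0.090,
    "Vomiting",                "Gastrointestinal disorders",                0.070,
    "Abdominal pain",          "Gastrointestinal disorders",                0.050,
    "Stomatitis",              "Gastrointestinal disorders",                0.020,
    "Neuropathy peripheral",   "Nervous system disorders",                  0.040,
    "Neurotoxicity",           "Nervous system disorders",                  0.012,
    "Dysarthria",              "Nervous system disorders",                  0.010,
    "Loss of consciousness",   "Nervous system disorders",                  0.015,
    "Dyspnoea",                "Respiratory, thoracic and mediastinal disorders", 0.060,
    "Pulmonary embolism",      "Respiratory, thoracic and mediastinal disorders", 0.015,
    "Pneumonitis",             "Respiratory, thoracic and mediastinal disorders", 0.012,
    "Erythema",                "Skin and subcutaneous tissue disorders",    0.030,
    "Hyperhidrosis",           "Skin and subcutaneous tissue disorders",    0.015,
    "Flushing",                "Vascular disorders",                        0.020,
    "Hypotension",             "Vascular disorders",                        0.030,
    "Sepsis",                  "Infections and infestations",               0.025,
    "Septic shock",            "Infections and infestations",               0.010,
    "Infection",               "Infections and infestations",               0.030,
    "Pyrexia",                 "General disorders and administration site conditions", 0.060,
    "Fatigue",                 "General disorders and administration site conditions", 0.070,
    "Death",                   "General disorders and administration site conditions", 0.040,
    "Dehydration",             "Metabolism and nutrition disorders",        0.020,
    "Hypokalaemia",            "Metabolism and nutrition disorders",        0.015,
    "Decreased appetite",      "Metabolism and nutrition disorders",        0.030,
    "Back pain",               "Musculoskeletal and connective tissue disorders", 0.025,
    "Hepatotoxicity",          "Hepatobiliary disorders",                   0.012,
    "Tachycardia",             "Cardiac disorders",                         0.020,
    "Chest discomfort",        "Cardiac disorders",                         0.015
  )
}

#' @rdname sim_config
#' @export
default_sim_signals <- function() {
  tibble::tribble(
    ~drug,         ~pt,                     ~relative_rate,
    "paclitaxel",  "Neutropenia",           6.9,
    "paclitaxel",  "Erythema",              5.0,
    "paclitaxel",  "Flushing",              8.8,
    "paclitaxel",  "Dyspnoea",              3.4,
    "paclitaxel",  "Neuropathy peripheral", 7.4,
    "vincristine", "Febrile neutropenia",   9.0,
    "vincristine", "Neuropathy peripheral", 9.0,
    "vincristine", "Pancytopenia",          9.0,
    "vincristine", "Neurotoxicity",         9.0,
    "irinotecan",  "Diarrhoea",             4.6,
    "irinotecan",  "Neutropenia",           6.0,
    "irinotecan",  "Dehydration",           3.5,
    "irinotecan",  "Hypokalaemia",          7.1
  )
}

#' @rdname sim_config
#' @export
default_sim_tto <- function() {
  tibble::tibble(
    drug = c("paclitaxel", "vincristine", "irinotecan"),
    shape = c(0.64, 0.54, 0.72),
    scale = c(61.23, 46.75, 52.99)
  )
}

#' @rdname sim_config
#' @export
default_sim_demographics <- function() {
  list(
    sex = c(F = 0.45, M = 0.38, missing = 0.17),
    age = list(child_frac = 0.08, child_range = c(1, 17),
               adult_mean = 60, adult_sd = 14, missing_frac = 0.22),
    weight = list(mean = 70, sd = 16, missing_frac = 0.55),
    countries = c(US = 0.35, FR = 0.12, JP = 0.08, IT = 0.07, CA = 0.05,
                  GB = 0.05, DE = 0.04, other = 0.14, missing = 0.10)
  )
}

#' Generate a synthetic FAERS dataset with known ground truth
#'
#' Draws `n_reports` spontaneous reports: each report carries 1-3 suspect
#' drugs (first role PS, others SS), reactions drawn per event with
#' probability `background * relative_rate` (capped at 1, the maximum
#' relative rate over the report's drugs), an event date uniform over the
#' configured range, and per-drug therapy start dates back-calculated from
#' Weibull onset draws floored to whole days. A configured fraction of date
#' fields is degraded to month or year precision, and a configured fraction
#' of cases is re-emitted as a later version of the same caseid (all five
#' tables) to exercise deduplication. Reports may have zero reactions; the
#' event-draw model is kept exactly binomial so planted counts have a
#' closed-form expectation.
#'
#' @param config a `faers_sim_config` from [sim_config()].
#' @return an object of class `faers_sim`: list with `tables` (named list
#'   of tibbles `demo`, `drug`, `reac`, `ther`, `indi`, all character
#'   columns in the FAERS quarterly ASCII dialect) and `truth` (the ground
#'   truth manifest: `pairs` with true relative rates for every drug-event
#'   combination, `tto` parameters, `duplicate_caseids`,
#'   `n_partial_dates`, `n_reports`, `seed`).
#' @export
simulate_faers <- function(config = sim_config()) {
  if (!inherits(config, "faers_sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  n <- as.integer(config$n_reports)
  drugs <- config$drugs
  events <- config$events
  nd <- nrow(drugs)
  ne <- nrow(events)

  primaryid <- sprintf("%d", 100000000 + seq_len(n))
  caseid <- sprintf("%d", 20000000 + seq_len(n))

  # --- drug sets: 1-3 slots per report, weighted by exposure, deduplicated
  k <- sample.int(3L, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  slots <- tibble::tibble(
    report = rep.int(seq_len(n), k),
    drug_idx = sample.int(nd, sum(k), replace = TRUE,
                          prob = drugs$exposure / sum(drugs$exposure))
  )
  drug_long <- slots[!duplicated(slots), ]
  drug_long <- drug_long |>
    dplyr::group_by(.data$report) |>
    dplyr::mutate(drug_seq = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(drug = drugs$drug[.data$drug_idx])

  # --- per-report, per-event relative rate = max over the report's drugs
  rel <- matrix(1, nrow = n, ncol = ne)
  ps <- config$planted_signals
  if (nrow(ps) > 0) {
    for (s in seq_len(nrow(ps))) {
      di <- match(ps$drug[s], drugs$drug)
      ei <- match(ps$pt[s], events$pt)
      rows <- unique(drug_long$report[drug_long$drug_idx == di])
      rel[rows, ei] <- pmax(rel[rows, ei], ps$relative_rate[s])
    }
  }
  prob <- sweep(rel, 2, events$background, `*`)
  prob[prob > 1] <- 1
  hit <- matrix(stats::runif(n * ne), n, ne) < prob
  reac_idx <- which(hit, arr.ind = TRUE)
  reac_long <- tibble::tibble(report = reac_idx[, 1], pt = events$pt[reac_idx[, 2]])

  # --- dates and onsets: event date uniform; each drug's therapy start is
  # event date minus a Weibull onset draw floored to whole days
  d0 <- as.integer(config$date_range[1])
  d1 <- as.integer(config$date_range[2])
  event_date <- as.Date(sample.int(d1 - d0 + 1L, n, replace = TRUE) + d0 - 1L,
                        origin = "1970-01-01")
  tto_par <- config$tto[match(drugs$drug[drug_long$drug_idx], config$tto$drug), ]
  onset_days <- floor(stats::rweibull(nrow(drug_long),
                                      shape = tto_par$shape,
                                      scale = tto_par$scale))
  drug_long$start_date <- event_date[drug_long$report] - onset_days
  fda_date <- event_date + stats::rpois(n, 45)

  # --- demographics
  dem <- config$demographics
  sex <- sample(names(dem$sex), n, replace = TRUE, prob = dem$sex)
  sex[sex == "missing"] <- ""
  is_child <- stats::runif(n) < dem$age$child_frac
  age_years <- ifelse(
    is_child,
    stats::runif(n, dem$age$child_range[1], dem$age$child_range[2]),
    pmin(pmax(stats::rnorm(n, dem$age$adult_mean, dem$age$adult_sd), 18), 100)
  )
  age_unit <- sample(c("YR", "MON", "DEC"), n, replace = TRUE,
                     prob = c(0.90, 0.05, 0.05))
  age_val <- dplyr::case_when(
    age_unit == "YR" ~ round(age_years),
    age_unit == "MON" ~ round(age_years * 12),
    age_unit == "DEC" ~ round(age_years / 10, 1)
  )
  age_missing <- stats::runif(n) < dem$age$missing_frac
  age_val[age_missing] <- NA
  age_unit[age_missing] <- ""

  wt_kg <- pmax(stats::rnorm(n, dem$weight$mean, dem$weight$sd), 3)
  wt_unit <- sample(c("KG", "LBS"), n, replace = TRUE, prob = c(0.85, 0.15))
  wt_val <- ifelse(wt_unit == "KG", round(wt_kg, 1),
                   round(wt_kg / 0.453592, 1))
  wt_missing <- stats::runif(n) < dem$weight$missing_frac
  wt_val[wt_missing] <- NA
  wt_unit[wt_missing] <- ""

  country <- sample(names(dem$countries), n, replace = TRUE,
                    prob = dem$countries)
  country[country == "missing"] <- ""

  # --- partial-date degradation (event dates and therapy starts)
  fmt_date <- function(dates, frac) {
    out <- format(dates, "%Y%m%d")
    m <- length(out)
    u <- stats::runif(m)
    out[u < frac / 2] <- format(dates[u < frac / 2], "%Y%m")
    sel <- u >= frac / 2 & u < frac
    out[sel] <- format(dates[sel], "%Y")
    out
  }
  pf <- config$partial_date_fraction
  event_dt_str <- fmt_date(event_date, pf)
  start_dt_str <- fmt_date(drug_long$start_date, pf)
  n_partial <- sum(nchar(event_dt_str) < 8) + sum(nchar(start_dt_str) < 8)

  # --- indications: per suspect drug row, mostly drug-typical
  indi_pool <- c(
    paclitaxel = "Breast cancer",
    vincristine = "Acute lymphocytic leukaemia",
    irinotecan = "Colorectal cancer metastatic"
  )
  typical <- indi_pool[drugs$drug[drug_long$drug_idx]]
  typical[is.na(typical)] <- "Product used for unknown indication"
  indi_pt <- ifelse(stats::runif(nrow(drug_long)) < 0.35,
                    "Product used for unknown indication", typical)

  demo <- tibble::tibble(
    primaryid = primaryid,
    caseid = caseid,
    fda_dt = format(fda_date, "%Y%m%d"),
    event_dt = event_dt_str,
    sex = sex,
    age = ifelse(is.na(age_val), "", as.character(age_val)),
    age_cod = age_unit,
    wt = ifelse(is.na(wt_val), "", as.character(wt_val)),
    wt_cod = wt_unit,
    occr_country = country
  )
  drug_tbl <- tibble::tibble(
    primaryid = primaryid[drug_long$report],
    drug_seq = as.character(drug_long$drug_seq),
    role_cod = ifelse(drug_long$drug_seq == 1, "PS", "SS"),
    drugname = toupper(drugs$drug[drug_long$drug_idx])
  )
  reac_tbl <- tibble::tibble(
    primaryid = primaryid[reac_long$report],
    pt = reac_long$pt
  )
  ther_tbl <- tibble::tibble(
    primaryid = primaryid[drug_long$report],
    dsg_drug_seq = as.character(drug_long$drug_seq),
    start_dt = start_dt_str
  )
  indi_tbl <- tibble::tibble(
    primaryid = primaryid[drug_long$report],
    indi_drug_seq = as.character(drug_long$drug_seq),
    indi_pt = indi_pt
  )

  # --- duplicate injection: re-emit whole cases under a new primaryid with
  # a later receipt date; the deduplicated set must equal the original cases
  n_dup <- floor(config$duplicate_fraction * n)
  dup_caseids <- character(0)
  if (n_dup > 0) {
    dup_rows <- sort(sample.int(n, n_dup))
    dup_caseids <- caseid[dup_rows]
    new_pid <- sprintf("%d", 900000000 + seq_len(n_dup))
    map <- stats::setNames(new_pid, primaryid[dup_rows])
    dup_demo <- demo[dup_rows, ]
    dup_demo$primaryid <- new_pid
    dup_demo$fda_dt <- format(fda_date[dup_rows] + 10, "%Y%m%d")
    demo <- dplyr::bind_rows(demo, dup_demo)
    reemit <- function(tbl) {
      sub <- tbl[tbl$primaryid %in% names(map), ]
      sub$primaryid <- unname(map[sub$primaryid])
      dplyr::bind_rows(tbl, sub)
    }
    drug_tbl <- reemit(drug_tbl)
    reac_tbl <- reemit(reac_tbl)
    ther_tbl <- reemit(ther_tbl)
    indi_tbl <- reemit(indi_tbl)
  }

  truth_pairs <- tidyr::expand_grid(drug = drugs$drug, pt = events$pt) |>
    dplyr::left_join(ps, by = c("drug", "pt")) |>
    dplyr::mutate(relative_rate = dplyr::coalesce(.data$relative_rate, 1))

  structure(
    list(
      tables = list(demo = demo, drug = drug_tbl, reac = reac_tbl,
                    ther = ther_tbl, indi = indi_tbl),
      truth = list(
        pairs = truth_pairs,
        tto = config$tto,
        duplicate_caseids = dup_caseids,
        n_partial_dates = n_partial,
        n_reports = n,
        seed = config$seed
      )
    ),
    class = "faers_sim"
  )
}

#' Write a synthetic dataset as FAERS-format ASCII files
#'
#' Writes the five dollar-delimited tables (`DEMO.txt`, `DRUG.txt`,
#' `REAC.txt`, `THER.txt`, `INDI.txt`) plus `truth_manifest.json` to a
#' directory. Output is byte-identical for identical input.
#'
#' @param sim a `faers_sim` from [simulate_faers()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the file paths written.
#' @export
write_faers_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "faers_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
             ther = "THER.txt", indi = "INDI.txt")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  for (nm in names(files)) {
    readr::write_delim(sim$tables[[nm]], paths[[nm]], delim = "$",
                       na = "", quote = "none", eol = "\n")
  }
  manifest <- file.path(dir, "truth_manifest.json")
  jsonlite::write_json(
    list(
      pairs = sim$truth$pairs,
      tto = sim$truth$tto,
      duplicate_caseids = sim$truth$duplicate_caseids,
      n_partial_dates = sim$truth$n_partial_dates,
      n_reports = sim$truth$n_reports,
      seed = sim$truth$seed
    ),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(paths, truth = manifest))
}

#' @export
print.faers_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic FAERS dataset: %d cases (%d DEMO rows incl. %d duplicates)\n",
    x$truth$n_reports, nrow(x$tables$demo), length(x$truth$duplicate_caseids)))
  cat(sprintf("  drugs: %s\n",
              paste(unique(x$truth$tto$drug), collapse = ", ")))
  cat(sprintf("  planted pairs with rate != 1: %d; partial date fields: %d; seed %d\n",
              sum(x$truth$pairs$relative_rate != 1), x$truth$n_partial_dates,
              x$truth$seed))
  invisible(x)
}
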