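#' Read FAERS quarterly ASCII tables
#'
#' Parses the dollar-delimited, header-rowed FAERS dialect. Mandatory
#' columns are checked per table (`primaryid`, `caseid` in DEMO;
#' `primaryid`, `drugname`, `role_cod` in DRUG; `primaryid`, `pt` in REAC);
#' extra columns are preserved. All fields are read as character; typing is
#' done downstream.
#'
#' @param paths either a directory containing `DEMO.txt`, `DRUG.txt`,
#'   `REAC.txt`, `THER.txt`, `INDI.txt` (as written by
#'   [write_faers_tables()]), or a named vector/list of file paths with
#'   names among `demo`, `drug`, `reac`, `ther`, `indi`.
#' @return a named list of tibbles of class `faers_raw`.
#' @export
read_faers_tables <- function(paths) {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    paths <- c(demo = file.path(paths, "DEMO.txt"),
               drug = file.path(paths, "DRUG.txt"),
               reac = file.path(paths, "REAC.txt"),
               ther = file.path(paths, "THER.txt"),
               indi = file.path(paths, "INDI.txt"))
  }
  paths <- unlist(paths)
  mandatory <- list(
    demo = c("primaryid", "caseid"),
    drug = c("primaryid", "drugname", "role_cod"),
    reac = c("primaryid", "pt")
  )
  out <- list()
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!file.exists(p)) {
      abort_faersignal(sprintf("file not found for table %s: %s",
                               toupper(nm), p),
                       "faersignal_schema_error")
    }
    tbl <- readr::read_delim(
      p, delim = "$", quote = "",
      col_types = readr::cols(.default = readr::col_character()),
      na = character(), progress = FALSE,
      show_col_types = FALSE
    )
    need <- mandatory[[nm]]
    missing_cols <- setdiff(need, names(tbl))
    if (length(missing_cols) > 0) {
      abort_faersignal(
        sprintf("missing mandatory column %s",
                paste0(toupper(nm), ".", missing_cols, collapse = ", ")),
        "faersignal_schema_error"
      )
    }
    out[[nm]] <- tbl
  }
  structure(out, class = "faers_raw")
}

#' Deduplicate cases in a DEMO table
#'
#' FAERS emits a new report version (new `primaryid`) each time a case is
#' updated; duplicate reports with the same case ID are removed, keeping the
#' version with the latest receipt date (`fda_dt`), ties broken by the
#' numerically largest `primaryid`. Applying the function twice equals
#' applying it once.
#'
#' @param demo a DEMO tibble with columns `primaryid`, `caseid` and the
#'   date column named by `date_col`.
#' @param date_col name of the version/receipt date column (default
#'   `"fda_dt"`).
#' @return the kept DEMO rows (one per caseid), with the number of removed
#'   rows attached as attribute `"n_removed"`.
#' @export
deduplicate_cases <- function(demo, date_col = "fda_dt") {
  stopifnot(all(c("primaryid", "caseid", date_col) %in% names(demo)))
  if (nrow(demo) == 0) {
    out <- demo
    attr(out, "n_removed") <- 0L
    return(out)
  }
  ord <- order(demo$caseid,
               as.numeric(demo[[date_col]]),
               suppressWarnings(as.numeric(demo$primaryid)),
               decreasing = TRUE, method = "radix")
  sorted <- demo[ord, ]
  kept <- sorted[!duplicated(sorted$caseid), ]
  # restore input order of the survivors
  kept <- kept[order(match(kept$primaryid, demo$primaryid)), ]
  attr(kept, "n_removed") <- nrow(demo) - nrow(kept)
  kept
}

#' Normalize raw drug names through a synonym map
#'
#' Raw FAERS drug names are free text (trade names, salts, case and spacing
#' variants). Names are case-folded and whitespace-collapsed, then looked up
#' in a user-supplied synonym map; unmapped names pass through case-folded
#' and are counted in the `"n_unmapped"` attribute.
#'
#' @param raw character vector of raw drug names.
#' @param synonym_map a named character vector (names = case-folded raw
#'   strings, values = standard names), a two-column data frame
#'   (`raw`, `standard`), or `NULL` for pure case-folding.
#' @return character vector of standardized names with attribute
#'   `"n_unmapped"`.
#' @examples
#' normalize_drug_name(c("TAXOL", "  Irinotecan HCl "),
#'                     c(taxol = "paclitaxel", `irinotecan hcl` = "irinotecan"))
#' @export
normalize_drug_name <- function(raw, synonym_map = NULL) {
  folded <- stringr::str_squish(tolower(raw))
  if (is.data.frame(synonym_map)) {
    synonym_map <- stats::setNames(synonym_map[[2]], synonym_map[[1]])
  }
  if (is.null(synonym_map) || length(synonym_map) == 0) {
    attr(folded, "n_unmapped") <- length(folded)
    return(folded)
  }
  names(synonym_map) <- stringr::str_squish(tolower(names(synonym_map)))
  hit <- synonym_map[folded]
  unmapped <- is.na(hit)
  out <- ifelse(unmapped, folded, unname(hit))
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Harmonize reported age to years
#'
#' FAERS ages come with a unit code; all are converted to years. Values
#' outside `[0, 150)` after conversion, and unknown unit codes, become
#' missing with a warning.
#'
#' @param value numeric (or coercible) age values.
#' @param unit unit codes: `DEC` (decades), `YR`, `MON`, `WK`, `DY`, `HR`.
#' @return numeric vector of ages in years (NA where unusable).
#' @examples
#' harmonize_age(c(24, 6.2, 200), c("MON", "DEC", "YR"))
#' @export
harmonize_age <- function(value, unit) {
  value <- suppressWarnings(as.numeric(value))
  unit <- toupper(stringr::str_trim(as.character(unit)))
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor_map[unit]
  unknown <- !is.na(value) & !is.na(unit) & unit != "" & is.na(f)
  if (any(unknown)) {
    warning(sprintf("%d age value(s) with unknown unit set to missing",
                    sum(unknown)), call. = FALSE)
  }
  years <- value * unname(f)
  out_of_range <- !is.na(years) & (years < 0 | years >= 150)
  if (any(out_of_range)) {
    warning(sprintf("%d age value(s) outside [0, 150) set to missing",
                    sum(out_of_range)), call. = FALSE)
  }
  years[out_of_range] <- NA_real_
  years
}

#' Harmonize reported weight to kilograms
#'
#' Converts `LBS` and `GMS` to kilograms; values outside `(0, 500)` after
#' conversion become missing.
#'
#' @param value numeric (or coercible) weights.
#' @param unit unit codes: `KG`, `LBS`, `GMS`.
#' @return numeric vector of weights in kg (NA where unusable).
#' @export
harmonize_weight <- function(value, unit) {
  value <- suppressWarnings(as.numeric(value))
  unit <- toupper(stringr::str_trim(as.character(unit)))
  factor_map <- c(KG = 1, LBS = 0.453592, GMS = 1 / 1000)
  f <- factor_map[unit]
  kg <- value * unname(f)
  kg[!is.na(kg) & (kg <= 0 | kg >= 500)] <- NA_real_
  kg
}

#' Attach MedDRA system organ classes to preferred terms
#'
#' Tags each reaction preferred term (PT) with its primary system organ
#' class (SOC) from a user-supplied dictionary; PTs absent from the
#' dictionary get SOC `"UNMAPPED"` and are counted.
#'
#' @param reactions character vector of PTs, or a tibble with a `pt` column.
#' @param dict a `MedDRA`-style dictionary: named character vector
#'   (PT -> SOC) or two-column data frame (`pt`, `soc`).
#' @return a tibble with the input plus a `soc` column; the number of
#'   unmapped PTs is attached as attribute `"n_unmapped"`.
#' @export
attach_meddra <- function(reactions, dict) {
  if (is.data.frame(dict)) dict <- stats::setNames(dict[[2]], dict[[1]])
  tbl <- if (is.data.frame(reactions)) {
    tibble::as_tibble(reactions)
  } else {
    tibble::tibble(pt = as.character(reactions))
  }
  soc <- unname(dict[tbl$pt])
  n_unmapped <- sum(is.na(soc) & !is.na(tbl$pt))
  soc[is.na(soc)] <- "UNMAPPED"
  tbl$soc <- soc
  if (nrow(tbl) == 0) tbl$soc <- character(0)
  attr(tbl, "n_unmapped") <- n_unmapped
  tbl
}

#' Assemble clean case reports from raw FAERS tables
#'
#' Runs deduplication on DEMO, harmonizes demographics (sex, age in years,
#' weight in kg, country, event date with precision, report year from the
#' receipt date), normalizes drug names, joins therapy start dates from
#' THER by drug sequence, attaches MedDRA SOCs to reactions, and joins
#' indications. Child-table rows referencing a primaryid that did not
#' survive deduplication (or never existed) are dropped; rows referencing a
#' primaryid absent from DEMO entirely are additionally reported with a
#' warning.
#'
#' The suspect-role filter is *not* applied here; contingency building
#' decides which roles define drug exposure.
#'
#' @param raw a `faers_raw` list from [read_faers_tables()] or a
#'   `faers_sim$tables` list.
#' @param synonym_map passed to [normalize_drug_name()].
#' @param dict passed to [attach_meddra()]; `NULL` leaves reactions
#'   unmapped (`soc = "UNMAPPED"`).
#' @return an object of class `faers_cases`: a list of tibbles
#'   `demo` (one row per case), `drugs`, `reactions`, `indications`,
#'   all keyed by `primaryid`.
#' @export
build_case_reports <- function(raw, synonym_map = NULL, dict = NULL) {
  demo_kept <- deduplicate_cases(raw$demo)
  kept_ids <- demo_kept$primaryid

  event <- parse_faers_date(demo_kept$event_dt %||% rep("", nrow(demo_kept)))
  fda <- parse_faers_date(demo_kept$fda_dt %||% rep("", nrow(demo_kept)))
  demo <- tibble::tibble(
    primaryid = demo_kept$primaryid,
    caseid = demo_kept$caseid,
    sex = dplyr::if_else(demo_kept$sex %in% c("F", "M"),
                         demo_kept$sex, NA_character_,
                         missing = NA_character_),
    age_years = harmonize_age(demo_kept$age %||% NA, demo_kept$age_cod %||% ""),
    weight_kg = harmonize_weight(demo_kept$wt %||% NA, demo_kept$wt_cod %||% ""),
    country = dplyr::na_if(demo_kept$occr_country %||% NA_character_, ""),
    event_date = event$date,
    event_precision = event$precision,
    report_year = fda$year
  )

  drugs_raw <- raw$drug |> dplyr::filter(.data$primaryid %in% kept_ids)
  ther <- raw$ther
  if (!is.null(ther) && nrow(ther) > 0) {
    st <- parse_faers_date(ther$start_dt)
    ther2 <- tibble::tibble(primaryid = ther$primaryid,
                            drug_seq = ther$dsg_drug_seq,
                            start_date = st$date,
                            start_precision = st$precision)
  } else {
    ther2 <- tibble::tibble(primaryid = character(), drug_seq = character(),
                            start_date = as.Date(character()),
                            start_precision = character())
  }
  std <- normalize_drug_name(drugs_raw$drugname, synonym_map)
  drugs <- drugs_raw |>
    dplyr::mutate(raw_name = .data$drugname,
                  standard_name = as.character(std)) |>
    dplyr::left_join(ther2, by = c("primaryid", "drug_seq")) |>
    dplyr::select("primaryid", "drug_seq", "role_cod", "raw_name",
                  "standard_name", "start_date", "start_precision") |>
    dplyr::mutate(
      start_precision = dplyr::coalesce(.data$start_precision, "missing")
    )

  reac_all <- raw$reac
  orphan <- !(reac_all$primaryid %in% raw$demo$primaryid)
  if (any(orphan)) {
    warning(sprintf("%d REAC row(s) reference unknown primaryid; dropped",
                    sum(orphan)), call. = FALSE)
  }
  reac_kept <- reac_all[reac_all$primaryid %in% kept_ids, ]
  reactions <- attach_meddra(reac_kept, dict %||% character(0)) |>
    dplyr::distinct(.data$primaryid, .data$pt, .keep_all = TRUE)

  indi <- raw$indi
  indications <- if (!is.null(indi) && nrow(indi) > 0) {
    indi |>
      dplyr::filter(.data$primaryid %in% kept_ids) |>
      dplyr::select("primaryid", pt = "indi_pt")
  } else {
    tibble::tibble(primaryid = character(), pt = character())
  }

  structure(
    list(demo = demo, drugs = drugs, reactions = reactions,
         indications = indications),
    class = "faers_cases"
  )
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("FAERS case collection: %d cases, %d drug rows, %d reactions, %d indications\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$reactions),
              nrow(x$indications)))
  invisible(x)
}

#' Read a PT -> SOC dictionary or a drug synonym map from disk
#'
#' Both are two-column delimited text files with a header row: the MedDRA
#' dictionary maps each preferred term to its primary system organ class;
#' the synonym map maps case-folded raw drug strings to standard names.
#'
#' @param path file path (tab-delimited by default).
#' @param delim field delimiter.
#' @return a two-column tibble.
#' @export
read_meddra_dict <- function(path, delim = "\t") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_meddra_dict
#' @export
read_synonym_map <- function(path, delim = "\t") {
  read_meddra_dict(path, delim)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
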