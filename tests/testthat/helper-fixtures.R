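# Shared fixtures: a toy MedDRA dictionary, a toy drug synonym map, and a
# constructor for hand-built case collections so contingency/reporting tests
# can enumerate expectations by hand.

toy_dict <- function() {
  c(
    "Neutropenia" = "Blood and lymphatic system disorders",
    "Anaemia" = "Blood and lymphatic system disorders",
    "Febrile neutropenia" = "Blood and lymphatic system disorders",
    "Diarrhoea" = "Gastrointestinal disorders",
    "Nausea" = "Gastrointestinal disorders",
    "Neuropathy peripheral" = "Nervous system disorders",
    "Dyspnoea" = "Respiratory, thoracic and mediastinal disorders",
    "Flushing" = "Vascular disorders"
  )
}

toy_synonyms <- function() {
  c(
    "taxol" = "paclitaxel",
    "abraxane" = "paclitaxel",
    "irinotecan hcl" = "irinotecan",
    "oncovin" = "vincristine"
  )
}

# Build a faers_cases collection from a compact description:
# reports = named list: name -> list(drugs = chr, reactions = chr)
# All drugs get role PS; sex/ages left missing unless supplied via demo_extra.
make_cases <- function(reports, dict = NULL, demo_extra = NULL) {
  ids <- names(reports)
  demo <- tibble::tibble(
    primaryid = ids,
    caseid = ids,
    sex = NA_character_,
    age_years = NA_real_,
    weight_kg = NA_real_,
    country = NA_character_,
    event_date = as.Date(NA),
    event_precision = "missing",
    report_year = NA_integer_
  )
  if (!is.null(demo_extra)) {
    for (col in names(demo_extra)) demo[[col]] <- demo_extra[[col]]
  }
  drugs <- purrr::map_dfr(ids, function(id) {
    d <- reports[[id]]$drugs
    if (length(d) == 0) return(tibble::tibble())
    tibble::tibble(
      primaryid = id, drug_seq = as.character(seq_along(d)),
      role_cod = "PS", raw_name = d, standard_name = d,
      start_date = as.Date(NA), start_precision = "missing"
    )
  })
  reac <- purrr::map_dfr(ids, function(id) {
    r <- reports[[id]]$reactions
    if (length(r) == 0) return(tibble::tibble())
    tibble::tibble(primaryid = id, pt = r)
  })
  if (nrow(reac) > 0) {
    reac <- faersignal::attach_meddra(reac, dict %||% toy_dict())
  } else {
    reac <- tibble::tibble(primaryid = character(), pt = character(),
                           soc = character())
  }
  structure(
    list(demo = demo, drugs = drugs, reactions = reac,
         indications = tibble::tibble(primaryid = character(),
                                      pt = character())),
    class = "faers_cases"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small all-null generator config: one event per drug pair structure kept
# simple, every relative rate 1.
null_config <- function(n_reports, seed, n_drugs = 5, n_events = 12) {
  sim_config(
    n_reports = n_reports,
    drugs = tibble::tibble(drug = sprintf("drug%02d", seq_len(n_drugs)),
                           exposure = rep(1 / n_drugs, n_drugs)),
    events = tibble::tibble(pt = sprintf("PT%02d", seq_len(n_events)),
                            soc = rep(sprintf("SOC%d", 1:3),
                                      length.out = n_events),
                            background = rep(c(0.03, 0.05, 0.08),
                                             length.out = n_events)),
    planted_signals = tibble::tibble(drug = character(), pt = character(),
                                     relative_rate = numeric()),
    tto = tibble::tibble(drug = sprintf("drug%02d", seq_len(n_drugs)),
                         shape = rep(0.7, n_drugs),
                         scale = rep(50, n_drugs)),
    duplicate_fraction = 0,
    partial_date_fraction = 0,
    seed = seed
  )
}

# Config with disjoint planted pairs: each of n_drugs drugs plants `rate` on
# its own event, so every planted pair is identifiable in the 2x2 universe.
planted_config <- function(n_reports, seed, n_drugs = 10, rate = 5,
                           background = 0.03) {
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  events <- sprintf("PT%02d", seq_len(2 * n_drugs))
  sim_config(
    n_reports = n_reports,
    drugs = tibble::tibble(drug = drugs, exposure = rep(1 / n_drugs, n_drugs)),
    events = tibble::tibble(pt = events,
                            soc = rep("SOC1", length(events)),
                            background = rep(background, length(events))),
    planted_signals = tibble::tibble(drug = drugs,
                                     pt = events[seq_len(n_drugs)],
                                     relative_rate = rate),
    tto = tibble::tibble(drug = drugs, shape = rep(0.7, n_drugs),
                         scale = rep(50, n_drugs)),
    duplicate_fraction = 0,
    partial_date_fraction = 0,
    seed = seed
  )
}
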