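# Case-level preprocessing of raw reporting-system tables: deduplication,
# deleted-case removal, completeness filtering, drug-name normalization,
# primary-suspect selection, and indication-PT exclusion.

#' Deduplicate demographic rows to one report per case
#'
#' Spontaneous reporting systems receive the same case repeatedly (updates,
#' re-submissions). For each CASEID the kept row is the one maximizing
#' `(FDA_DT, PRIMARYID)` lexicographically: the most recent receipt date,
#' and among equal dates the largest PRIMARYID. Idempotent and
#' order-independent.
#'
#' @param demo_rows Tibble with columns `caseid`, `fda_dt`, `primaryid`.
#' @return One row per CASEID.
#' @export
deduplicate <- function(demo_rows) {
  n_in <- nrow(demo_rows)
  out <- demo_rows |>
    dplyr::mutate(.fda = dplyr::coalesce(.data$fda_dt, -1L)) |>
    dplyr::arrange(.data$caseid, dplyr::desc(.data$.fda), dplyr::desc(.data$primaryid)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE) |>
    dplyr::select(-".fda")
  pv_log("deduplicate: %d rows -> %d unique cases (%d removed)",
         n_in, nrow(out), n_in - nrow(out))
  out
}

#' Remove cases named on deleted-case lists
#'
#' Quarterly packages ship lists of CASEIDs withdrawn from the system;
#' surviving rows never carry a listed CASEID. Listed CASEIDs absent from
#' the data are ignored.
#'
#' @param demo_rows Tibble with a `caseid` column.
#' @param deleted_caseids Integer vector of CASEIDs to drop.
#' @return Filtered tibble.
#' @export
apply_deletions <- function(demo_rows, deleted_caseids) {
  out <- demo_rows[!(demo_rows$caseid %in% deleted_caseids), ]
  pv_log("apply_deletions: removed %d of %d rows",
         nrow(demo_rows) - nrow(out), nrow(demo_rows))
  out
}

#' Convert reported age to years
#'
#' Ages arrive as a value plus a unit code. Conversion factors: `YR` 1,
#' `MON` 1/12, `WK` 1/52.18, `DY` 1/365.25, `HR` 1/8766. Blank,
#' unparseable, unknown-unit or negative values become `NA` (unknown).
#'
#' @param value Numeric age values.
#' @param unit_code Character unit codes.
#' @return Numeric age in years (NA where unknown).
#' @export
convert_age <- function(value, unit_code) {
  value <- suppressWarnings(as.numeric(value))
  factor <- c(YR = 1, MON = 1 / 12, WK = 1 / 52.18,
              DY = 1 / 365.25, HR = 1 / 8766)[as.character(unit_code)]
  out <- value * unname(factor)
  neg <- !is.na(value) & value < 0
  if (any(neg)) pv_log("convert_age: %d negative age value(s) set unknown", sum(neg))
  out[neg] <- NA_real_
  out
}

#' Normalize drug names against a synonym table
#'
#' Replaces every matched spelling variant by its canonical name;
#' matching is case-insensitive after trimming surrounding whitespace.
#' Unmatched names pass through unchanged (lower-cased canonical form is
#' NOT imposed on them) and are tallied to the log. Conflicting duplicate
#' mappings in the table are a configuration error.
#'
#' @param drug_rows Tibble with a `drugname` column (e.g. the DRUG table).
#' @param synonym_table Tibble with columns `variant`, `canonical`.
#' @return `drug_rows` with `drugname` normalized.
#' @export
normalize_drug_names <- function(drug_rows, synonym_table) {
  key <- tolower(trimws(synonym_table$variant))
  if (anyDuplicated(key)) {
    agg <- tapply(synonym_table$canonical, key, function(x) length(unique(x)))
    if (any(agg > 1)) {
      rlang::abort(paste0("conflicting synonym mappings for: ",
                          paste(names(agg)[agg > 1], collapse = ", ")),
                   class = "pvsignal_config_error")
    }
  }
  map <- setNames(synonym_table$canonical, key)
  lookup <- tolower(trimws(drug_rows$drugname))
  hit <- lookup %in% names(map)
  out <- drug_rows
  out$drugname <- ifelse(hit, unname(map[lookup]), trimws(drug_rows$drugname))
  pv_log("normalize_drug_names: %d of %d rows matched a variant",
         sum(hit), nrow(drug_rows))
  out
}

#' Assemble case records from pooled raw tables
#'
#' Joins the DRUG/REAC/OUTC/INDI tables onto the (deduplicated,
#' deletion-filtered) DEMO rows by PRIMARYID and nests them into one row
#' per case with list columns: `drugs` (tibble of `drugname`, `role_cod`),
#' `pts` (unique PT set), `outcomes` (unique outcome codes), `indications`
#' (unique indication PTs). Ages are converted to years.
#'
#' @param tables Pooled table list, as from [bind_quarters()] /
#'   [read_srs()]; `demo` should already be deduplicated.
#' @return A case-level tibble.
#' @export
build_cases <- function(tables) {
  demo <- tables$demo
  keep <- function(tab) tab[tab$primaryid %in% demo$primaryid, ]
  nest_by_pid <- function(tab, col) {
    tab <- keep(tab)
    tab <- tab[!is.na(tab[[col]]), c("primaryid", col)]
    tab <- dplyr::distinct(tab)
    split(tab[[col]], factor(tab$primaryid, levels = demo$primaryid))
  }
  drug <- keep(tables$drug)
  drug <- drug[!is.na(drug$drugname), ]
  drugs <- split(drug[c("drugname", "role_cod")],
                 factor(drug$primaryid, levels = demo$primaryid))
  gender <- dplyr::case_when(demo$sex == "M" ~ "male",
                             demo$sex == "F" ~ "female",
                             TRUE ~ "unknown")
  tibble::tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = demo$fda_dt,
    quarter = if ("quarter" %in% names(demo)) demo$quarter else NA_character_,
    age_years = convert_age(demo$age, demo$age_cod),
    gender = gender,
    occp_cod = demo$occp_cod,
    reporter_country = demo$reporter_country,
    event_dt = if ("event_dt" %in% names(demo)) demo$event_dt else NA_integer_,
    drugs = unname(drugs),
    pts = unname(nest_by_pid(tables$reac, "pt")),
    outcomes = unname(nest_by_pid(tables$outc, "outc_cod")),
    indications = unname(nest_by_pid(tables$indi, "indi_pt"))
  )
}

#' Filter cases to those complete in required fields
#'
#' Removes cases missing any required field and logs a per-field removal
#' tally. Field names: `drugs` and `pts` (non-empty list entries), plus
#' the scalar fields `age_years`, `gender`, `occp_cod`,
#' `reporter_country`, `outcomes`. The default keeps only the
#' drug-information and reaction-information requirements; demographic
#' blanks stay in the data as "unknown" strata.
#'
#' @param cases Case-level tibble from [build_cases()].
#' @param required_fields Character vector of field names.
#' @return Filtered tibble.
#' @export
filter_complete <- function(cases, required_fields = c("drugs", "pts")) {
  present <- function(field) {
    x <- cases[[field]]
    if (is.list(x)) {
      lengths(x) > 0 & !vapply(x, function(e) all(is.na(unlist(e))), logical(1))
    } else if (field == "gender") {
      !is.na(x) & x != "unknown"
    } else {
      !is.na(x)
    }
  }
  ok <- rep(TRUE, nrow(cases))
  for (f in required_fields) {
    p <- present(f)
    pv_log("filter_complete: %d case(s) missing %s", sum(!p), f)
    ok <- ok & p
  }
  out <- cases[ok, ]
  pv_log("filter_complete: %d -> %d cases", nrow(cases), nrow(out))
  out
}

#' Split cases into target-drug and background sets
#'
#' The target set contains cases listing `target_drug` with role code `PS`
#' (primary suspect); every other case forms the background. A case with
#' the target drug only as a concomitant stays in the background.
#'
#' @param cases Case-level tibble (drug names normalized).
#' @param target_drug Canonical target drug name.
#' @return List with tibbles `target` and `background`.
#' @export
select_target_cases <- function(cases, target_drug) {
  is_target <- vapply(cases$drugs, function(d) {
    nrow(d) > 0 && any(d$drugname == target_drug & d$role_cod == "PS")
  }, logical(1))
  pv_log("select_target_cases: %d target, %d background",
         sum(is_target), sum(!is_target))
  list(target = cases[is_target, ], background = cases[!is_target, ])
}

#' Remove indication PTs from case reactions
#'
#' The treated disease is sometimes reported as the adverse event
#' (indication bias); the listed PTs are removed from every case's
#' reaction set. Cases whose PT set becomes empty are dropped and tallied.
#'
#' @param cases Case-level tibble.
#' @param indication_pt_list Character vector of PT strings to exclude.
#' @return Filtered tibble.
#' @export
exclude_indication_pts <- function(cases, indication_pt_list) {
  if (!length(indication_pt_list)) return(cases)
  cases$pts <- lapply(cases$pts, setdiff, y = indication_pt_list)
  empty <- lengths(cases$pts) == 0
  if (any(empty)) {
    pv_log("exclude_indication_pts: dropped %d case(s) left with no PT",
           sum(empty))
  }
  cases[!empty, ]
}
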