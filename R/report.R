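# Pipeline orchestration and descriptive reporting: demographic strata,
# top concomitant drugs, and the end-to-end run with a stage-count
# manifest.

#' Stratified demographic summary of a case set
#'
#' Tabulates counts and percentages for age band, gender, reporter type,
#' reporting country, seriousness, outcome code, indication, and event
#' year. Percentages are always computed against the full case count, so
#' within a factor (unknowns included) they sum to 100.
#'
#' @param cases Case-level tibble.
#' @return Tibble with columns `factor`, `level`, `n`, `pct`.
#' @export
summarize_demographics <- function(cases) {
  total <- nrow(cases)
  if (total == 0) {
    return(tibble::tibble(factor = character(), level = character(),
                          n = integer(), pct = numeric()))
  }
  stratum <- function(name, values) {
    values <- as.character(values)
    values[is.na(values)] <- "unknown"
    tb <- sort(table(values), decreasing = TRUE)
    tibble::tibble(factor = name, level = names(tb),
                   n = as.integer(tb), pct = 100 * as.integer(tb) / total)
  }
  reporter <- dplyr::case_when(
    cases$occp_cod %in% c("MD", "PH", "HP", "OT", "LW") ~ "healthcare professional",
    cases$occp_cod == "CN" ~ "consumer",
    TRUE ~ "unknown")
  # one row per outcome code (a case may carry several); pct of all cases
  outc <- unlist(cases$outcomes, use.names = FALSE)
  outc_tb <- sort(table(outc), decreasing = TRUE)
  ind <- vapply(cases$indications,
                function(x) if (length(x)) x[[1]] else NA_character_,
                character(1))
  dplyr::bind_rows(
    stratum("age_band", age_band(cases$age_years)),
    stratum("gender", cases$gender),
    stratum("reporter", reporter),
    stratum("reporting_country", cases$reporter_country),
    stratum("seriousness",
            ifelse(classify_seriousness(cases$outcomes), "serious", "non-serious")),
    tibble::tibble(factor = "outcome", level = names(outc_tb),
                   n = as.integer(outc_tb), pct = 100 * as.integer(outc_tb) / total),
    stratum("indication", ind),
    stratum("event_year", substr(as.character(cases$fda_dt), 1, 4))
  )
}

#' Top concomitant drugs by report count
#'
#' Counts, per drug, the cases listing it with role C or SS (excluding the
#' target drug). The percentage denominator is the full case count, not
#' the count of cases with concomitants. Ties are broken alphabetically.
#'
#' @param cases Case-level tibble (drug names normalized).
#' @param n Number of drugs to return.
#' @param target_drug Drug to exclude from the concomitant counts.
#' @return Tibble `drug`, `n`, `pct`, at most `n` rows.
#' @export
top_concomitants <- function(cases, n = 10, target_drug = NULL) {
  total <- nrow(cases)
  if (n <= 0 || total == 0) {
    return(tibble::tibble(drug = character(), n = integer(), pct = numeric()))
  }
  con <- unlist(lapply(cases$drugs, function(d) {
    unique(d$drugname[d$role_cod %in% c("C", "SS")])
  }), use.names = FALSE)
  if (!is.null(target_drug)) con <- con[con != target_drug]
  if (!length(con)) {
    return(tibble::tibble(drug = character(), n = integer(), pct = numeric()))
  }
  tb <- table(con)
  out <- tibble::tibble(drug = names(tb), n = as.integer(tb),
                        pct = 100 * as.integer(tb) / total)
  out <- out[order(-out$n, out$drug), ]
  head(out, n)
}

#' Configure an end-to-end pipeline run
#'
#' Exactly one of `input_dir` (a directory of $-delimited quarterly files)
#' or `generator` (an [srs_config()], simulated in memory) must be given.
#'
#' @param target_drug Canonical target drug name (required).
#' @param input_dir Directory of quarterly files, or `NULL`.
#' @param generator An [srs_config()], or `NULL`.
#' @param criteria [signal_criteria()] overrides.
#' @param label_pts Product-label PT list.
#' @param indication_pts Indication-PT exclusion list.
#' @param synonym_table Drug-name normalization table.
#' @param pt_dictionary PT-to-SOC dictionary.
#' @param drug_properties Property table for covariate derivation.
#' @param required_fields Completeness requirements, see [filter_complete()].
#' @param alpha Univariate screening threshold.
#' @param output_dir If non-NULL, tables are written there as TSV.
#' @param seed Seed controlling any simulation randomness.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(target_drug,
                            input_dir = NULL,
                            generator = NULL,
                            criteria = signal_criteria(),
                            label_pts = default_label_pts(),
                            indication_pts = default_indication_pts(),
                            synonym_table = default_synonym_table(),
                            pt_dictionary = default_pt_dictionary(),
                            drug_properties = default_drug_properties(),
                            required_fields = c("drugs", "pts"),
                            alpha = 0.05,
                            output_dir = NULL,
                            seed = 1L) {
  if (missing(target_drug) || is.null(target_drug) || !nzchar(target_drug)) {
    rlang::abort("`target_drug` is required", class = "pvsignal_config_error")
  }
  if (is.null(input_dir) == is.null(generator)) {
    rlang::abort("exactly one of `input_dir` or `generator` must be supplied",
                 class = "pvsignal_config_error")
  }
  if (!is.null(generator) && !inherits(generator, "srs_config")) {
    rlang::abort("`generator` must be an srs_config()",
                 class = "pvsignal_config_error")
  }
  structure(list(target_drug = target_drug, input_dir = input_dir,
                 generator = generator, criteria = criteria,
                 label_pts = label_pts, indication_pts = indication_pts,
                 synonym_table = synonym_table, pt_dictionary = pt_dictionary,
                 drug_properties = drug_properties,
                 required_fields = required_fields, alpha = alpha,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the signal-mining pipeline end-to-end
#'
#' Stages: read (or simulate) the quarterly tables; deduplicate the DEMO
#' rows; apply deleted-case lists; normalize drug names; assemble case
#' records; filter on required fields; split target vs background on
#' primary-suspect role; exclude indication PTs from target cases; compute
#' ROR/PRR disproportionality and screen signals; compare against the
#' product label; derive covariates and fit the severity regressions.
#' Every stage count is recorded in the manifest; reruns with the same
#' config (and seed) are identical.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pv_pipeline`: list with `manifest`,
#'   `demographics`, `top_concomitants`, `stats` (all PTs), `signals`
#'   (flagged, with `in_label`), `label_summary`, `severity`
#'   (a `severity_fit`, or NULL if not estimable), `target_cases`,
#'   `ground_truth` (generator mode only).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    rlang::abort("`config` must be a pipeline_config()",
                 class = "pvsignal_config_error")
  }
  ground_truth <- NULL
  if (!is.null(config$generator)) {
    ds <- generate_dataset(config$generator)
    tables <- bind_quarters(ds$quarters)
    ground_truth <- ds$ground_truth
  } else {
    tables <- read_srs(config$input_dir)
  }
  manifest <- list(input_rows = nrow(tables$demo))

  demo <- deduplicate(tables$demo)
  manifest$post_dedup <- nrow(demo)
  demo <- apply_deletions(demo, tables$deleted)
  manifest$post_deletion <- nrow(demo)

  tables$demo <- demo
  tables$drug <- normalize_drug_names(tables$drug, config$synonym_table)
  cases <- build_cases(tables)
  cases <- filter_complete(cases, config$required_fields)
  manifest$post_filter <- nrow(cases)

  split <- select_target_cases(cases, config$target_drug)
  target <- exclude_indication_pts(split$target, config$indication_pts)
  manifest$target_cases <- nrow(target)
  manifest$background_cases <- nrow(split$background)

  stats <- disproportionality(target, split$background,
                              pt_dictionary = config$pt_dictionary)
  stats <- screen_signals(stats, config$criteria)
  signals <- compare_with_label(stats, config$label_pts)
  lab <- label_summary(signals)
  manifest$signals <- lab$n_signals
  manifest$unlabeled_signals <- lab$n_unlabeled

  severity <- NULL
  if (nrow(target) > 0) {
    profiles <- derive_covariates(target, config$drug_properties,
                                  config$target_drug)
    severity <- tryCatch(
      severity_analysis(profiles, alpha = config$alpha),
      error = function(e) {
        pv_log("severity stage skipped: %s", conditionMessage(e))
        NULL
      })
  }

  out <- structure(list(
    manifest = tibble::tibble(stage = names(manifest),
                              count = unlist(manifest, use.names = FALSE)),
    demographics = summarize_demographics(target),
    top_concomitants = top_concomitants(target, 10, config$target_drug),
    stats = stats,
    signals = signals,
    label_summary = lab,
    severity = severity,
    target_cases = target,
    ground_truth = ground_truth
  ), class = "pv_pipeline")

  if (!is.null(config$output_dir)) write_pipeline(out, config$output_dir)
  out
}

write_pipeline <- function(result, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  readr::write_tsv(result$manifest, file.path(output_dir, "manifest.tsv"))
  readr::write_tsv(result$demographics, file.path(output_dir, "demographics.tsv"))
  readr::write_tsv(result$top_concomitants, file.path(output_dir, "concomitants.tsv"))
  readr::write_tsv(result$signals, file.path(output_dir, "signals.tsv"))
  if (!is.null(result$severity)) {
    readr::write_tsv(tidy(result$severity), file.path(output_dir, "severity.tsv"))
  }
  invisible(output_dir)
}

#' @export
print.pv_pipeline <- function(x, ...) {
  cat("Spontaneous-report signal-mining pipeline\n")
  for (i in seq_len(nrow(x$manifest))) {
    cat(sprintf("  %-20s %d\n", x$manifest$stage[i], x$manifest$count[i]))
  }
  top <- rank_signals(x$signals, "report_count", 5)
  if (nrow(top)) {
    cat("  top signals by report count:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-28s a=%4d ROR %.2f (%.2f-%.2f) PRR %.2f (chi2 %.1f)%s\n",
                  top$pt[i], top$a[i], top$ror[i], top$ror_ci_low[i],
                  top$ror_ci_high[i], top$prr[i], top$chi2[i],
                  if (!top$in_label[i]) " [unlabeled]" else ""))
    }
  }
  invisible(x)
}
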