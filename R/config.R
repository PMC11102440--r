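#' Default preferred-term vocabulary for the synthetic generator
#'
#' A small MedDRA-like vocabulary of adverse-event preferred terms (PTs)
#' with their system organ class (SOC) assignments, covering the event
#' profile typical of an endocrine breast-cancer therapy. Used both as the
#' generator's sampling vocabulary and as the default PT dictionary for
#' attaching SOCs to signal tables.
#'
#' @return A tibble with columns `pt` and `soc`.
#' @export
default_pt_dictionary <- function() {
  tibble::tribble(
    ~pt, ~soc,
    "Neutropenia",              "Blood and lymphatic system disorders",
    "Leukopenia",               "Blood and lymphatic system disorders",
    "Thrombocytopenia",         "Blood and lymphatic system disorders",
    "Anaemia",                  "Blood and lymphatic system disorders",
    "Pancytopenia",             "Blood and lymphatic system disorders",
    "Injection site pain",      "General disorders and administration site conditions",
    "Injection site pruritus",  "General disorders and administration site conditions",
    "Asthenia",                 "General disorders and administration site conditions",
    "Fatigue",                  "General disorders and administration site conditions",
    "Pyrexia",                  "General disorders and administration site conditions",
    "Oedema peripheral",        "General disorders and administration site conditions",
    "Cough",                    "Respiratory, thoracic and mediastinal disorders",
    "Dyspnoea",                 "Respiratory, thoracic and mediastinal disorders",
    "Pulmonary embolism",       "Respiratory, thoracic and mediastinal disorders",
    "Interstitial lung disease","Respiratory, thoracic and mediastinal disorders",
    "Decreased appetite",       "Metabolism and nutrition disorders",
    "Hyperglycaemia",           "Metabolism and nutrition disorders",
    "Hypokalaemia",             "Metabolism and nutrition disorders",
    "Alopecia",                 "Skin and subcutaneous tissue disorders",
    "Rash",                     "Skin and subcutaneous tissue disorders",
    "Pruritus",                 "Skin and subcutaneous tissue disorders",
    "Back pain",                "Musculoskeletal and connective tissue disorders",
    "Arthralgia",               "Musculoskeletal and connective tissue disorders",
    "Myalgia",                  "Musculoskeletal and connective tissue disorders",
    "Pain in extremity",        "Musculoskeletal and connective tissue disorders",
    "Nausea",                   "Gastrointestinal disorders",
    "Vomiting",                 "Gastrointestinal disorders",
    "Diarrhoea",                "Gastrointestinal disorders",
    "Constipation",             "Gastrointestinal disorders",
    "Headache",                 "Nervous system disorders",
    "Dizziness",                "Nervous system disorders",
    "Insomnia",                 "Psychiatric disorders",
    "Jaundice",                 "Hepatobiliary disorders",
    "Breast cancer",            "Neoplasms benign, malignant and unspecified",
    "Breast cancer metastatic", "Neoplasms benign, malignant and unspecified"
  )
}

#' Default indication exclusion list
#'
#' Preferred terms naming the target drug's indications. Reports sometimes
#' list the treated disease itself as an adverse event ("indication bias");
#' these PTs are removed from target-drug cases before signal screening.
#'
#' @return Character vector of PT strings.
#' @export
default_indication_pts <- function() {
  c("Breast cancer", "Breast cancer metastatic")
}

#' Default product-label PT list
#'
#' Adverse-event preferred terms documented in the (synthetic) product
#' label used by the bundled examples. Flagged signals absent from this
#' list are reported as unlabeled adverse events.
#'
#' @return Character vector of PT strings.
#' @export
default_label_pts <- function() {
  c("Injection site pain", "Injection site pruritus", "Asthenia", "Fatigue",
    "Nausea", "Vomiting", "Diarrhoea", "Constipation", "Headache",
    "Back pain", "Arthralgia", "Pain in extremity", "Decreased appetite",
    "Alopecia", "Rash", "Pyrexia", "Cough", "Dizziness",
    "Neutropenia", "Leukopenia", "Anaemia")
}

#' Default drug-name synonym table
#'
#' Maps reported spelling variants (trade names, case variants) to a
#' canonical drug name, emulating the vocabulary-based standardization
#' applied to raw reporting-system drug strings. Matching is
#' case-insensitive after whitespace trimming.
#'
#' @return A tibble with columns `variant` and `canonical`.
#' @export
default_synonym_table <- function() {
  tibble::tribble(
    ~variant,        ~canonical,
    "FASLODEX",      "fulvestrant",
    "Faslodex",      "fulvestrant",
    "FULVESTRANT",   "fulvestrant",
    "HERCEPTIN",     "trastuzumab",
    "XGEVA",         "denosumab",
    "PROLIA",        "denosumab",
    "ZOMETA",        "zoledronic acid",
    "GLUCOPHAGE",    "metformin",
    "LIPITOR",       "atorvastatin",
    "TYLENOL",       "paracetamol",
    "BIAXIN",        "clarithromycin",
    "PRILOSEC",      "omeprazole"
  )
}

#' Synthetic drug-property table
#'
#' Plasma protein binding percentage and CYP3A4-inhibitor flag for the
#' drugs used by the bundled generator. The values are synthetic,
#' chosen to populate each protein-binding class cleanly; they are not an
#' authoritative pharmacology reference. CYP3A4 inhibitors in this table
#' carry binding below 85% so that adding one to a report never changes
#' the report's maximum-binding class.
#'
#' @return A tibble with columns `drug`, `protein_binding_pct`,
#'   `is_cyp3a4_inhibitor`.
#' @export
default_drug_properties <- function() {
  tibble::tribble(
    ~drug,             ~protein_binding_pct, ~is_cyp3a4_inhibitor,
    "fulvestrant",     99,   FALSE,
    # binding class < 85
    "metformin",       10,   FALSE,
    "paracetamol",     25,   FALSE,
    "denosumab",       60,   FALSE,
    # binding class 85 - < 98
    "zoledronic acid", 87,   FALSE,
    "exemestane",      90,   FALSE,
    "omeprazole",      95,   FALSE,
    # binding class >= 98
    "atorvastatin",    98,   FALSE,
    "ibuprofen",       99,   FALSE,
    "warfarin",        99,   FALSE,
    # CYP3A4 inhibitors (low binding by construction, see above)
    "clarithromycin",  70,   TRUE,
    "fluconazole",     11,   TRUE
  )
}

#' Logistic severity model for the synthetic generator
#'
#' Defines the probability that a generated report is serious:
#' `logit P(serious) = intercept + sum of coefficients` for the report's
#' covariate levels. Reference levels (gender male, age band 0-44, no
#' concomitant) carry coefficient exactly 0 and need not be listed.
#'
#' The default coefficients are the multivariate odds-ratio estimates for
#' a large fulvestrant reporting cohort (age bands protective relative to
#' 0-44; concomitant protein binding >= 98% a risk factor, OR 1.522), with
#' the intercept set so that the marginal serious fraction under the
#' default covariate mix is about 85%.
#'
#' @param intercept Log-odds of a serious outcome at reference levels.
#' @param coefficients Named numeric vector of log odds ratios keyed by
#'   covariate level (e.g. `age_band:60-74`, `pb_class:>=98`).
#' @return An object of class `severity_model`.
#' @export
severity_model <- function(intercept = 2.194,
                           coefficients = c(
                             "age_band:45-59"  = log(0.797),
                             "age_band:60-74"  = log(0.521),
                             "age_band:>=75"   = log(0.586),
                             "pb_class:<85"    = log(1.228),
                             "pb_class:85-<98" = log(0.861),
                             "pb_class:>=98"   = log(1.522)
                           )) {
  if (!is.numeric(intercept) || length(intercept) != 1 || is.na(intercept)) {
    rlang::abort("`intercept` must be a single log-odds value",
                 class = "pvsignal_config_error")
  }
  if (length(coefficients) && is.null(names(coefficients))) {
    rlang::abort("`coefficients` must be named by covariate level",
                 class = "pvsignal_config_error")
  }
  structure(list(intercept = intercept, coefficients = coefficients),
            class = "severity_model")
}

#' Default covariate mix for the synthetic generator
#'
#' Marginal probabilities for gender, age band, concomitant
#' protein-binding class, and CYP3A4 co-prescription, matching the
#' composition of a large fulvestrant reporting cohort (about 98.5%
#' female among reports with known gender; age concentrated in the 60-74
#' band; about 43% of reports carrying at least one concomitant drug, of
#' which about 4.5% include a CYP3A4 inhibitor).
#'
#' @return A named list of probability vectors; each factor's
#'   probabilities sum to 1.
#' @export
default_covariate_mix <- function() {
  list(
    gender = c(male = 99, female = 6534) / 6633,
    age_band = c("0-44" = 385, "45-59" = 1550, "60-74" = 2337, ">=75" = 1199) / 5471,
    # concomitant protein-binding class; "none" means no concomitant drug
    pb_class = c(none = 3940 / 6947,
                 "<85"    = (3007 / 6947) * 0.33,
                 "85-<98" = (3007 / 6947) * 0.42,
                 ">=98"   = (3007 / 6947) * 0.25),
    # probability a report WITH concomitants also includes a CYP3A4 inhibitor
    cyp_given_concomitant = 134 / 3007
  )
}

#' Configure the synthetic spontaneous-reporting-system generator
#'
#' Assembles and validates the full parameterization of
#' [generate_dataset()]: cohort size, quarter structure, the target drug
#' and its background, duplicate/deletion/missingness rates, the PT
#' vocabulary with injected signal strengths, the logistic severity model,
#' and the covariate mix. Identical configurations (including `seed`)
#' yield byte-identical datasets.
#'
#' @param n_cases Number of unique cases to generate (before duplicate
#'   injection and deletions).
#' @param n_quarters Number of quarterly file sets.
#' @param target_drug Canonical name of the drug under study.
#' @param background_drugs Drugs used as primary suspects of background
#'   reports.
#' @param target_fraction Fraction of cases whose primary suspect is the
#'   target drug.
#' @param duplicate_rate Fraction of cases re-emitted as duplicates
#'   (same CASEID, later FDA_DT or larger PRIMARYID).
#' @param deletion_rate Fraction of cases later named on a deleted-case
#'   list.
#' @param missing_field_rates Named fractions in `[0, 1)` giving the
#'   probability that a demographic field (`age`, `sex`, `occp_cod`,
#'   `reporter_country`) is blanked.
#' @param synonym_table Variant-to-canonical drug-name table; variants are
#'   injected into the written DRUG rows.
#' @param variant_rate Probability a drug name is written as one of its
#'   variants rather than the canonical spelling.
#' @param pt_vocabulary Tibble of `pt`, `soc` defining the samplable event
#'   vocabulary (indication PTs are handled separately).
#' @param signal_specs Tibble with columns `pt`, `p_target`,
#'   `p_background`: per-report probabilities that the PT is listed, for
#'   target-drug and background reports. PTs not listed here use
#'   `base_pt_rate` in both arms (true reporting odds ratio 1).
#' @param base_pt_rate Per-report listing probability for unsignalled PTs.
#' @param indication_rate Probability that a target case's indication PT
#'   is also (spuriously) listed as an adverse event, emulating
#'   indication bias.
#' @param severity_model A [severity_model()].
#' @param covariate_mix See [default_covariate_mix()].
#' @param drug_properties Property table used to realize concomitant
#'   drugs consistent with the drawn covariate classes.
#' @param seed Integer seed; the single source of randomness.
#' @return A validated `srs_config` object.
#' @export
srs_config <- function(n_cases,
                       n_quarters = 4,
                       target_drug = "fulvestrant",
                       background_drugs = c("letrozole", "anastrozole",
                                            "tamoxifen", "palbociclib",
                                            "trastuzumab", "capecitabine",
                                            "docetaxel", "paclitaxel"),
                       target_fraction = 0.2,
                       duplicate_rate = 0.08,
                       deletion_rate = 0.01,
                       missing_field_rates = c(age = 1476 / 6947,
                                               sex = 314 / 6947,
                                               occp_cod = 141 / 6947,
                                               reporter_country = 0.02),
                       synonym_table = default_synonym_table(),
                       variant_rate = 0.3,
                       pt_vocabulary = default_pt_dictionary(),
                       signal_specs = tibble::tibble(
                         pt = c("Neutropenia", "Injection site pruritus"),
                         p_target = c(0.0417, 0.008),
                         p_background = c(0.00423, 0.0001)
                       ),
                       base_pt_rate = 0.02,
                       indication_rate = 0.05,
                       severity_model = pvsignal::severity_model(),
                       covariate_mix = default_covariate_mix(),
                       drug_properties = default_drug_properties(),
                       seed = 1L) {
  n_cases <- assert_count(n_cases, "n_cases")
  n_quarters <- assert_count(n_quarters, "n_quarters", positive = TRUE)
  assert_fraction(target_fraction, "target_fraction", allow_one = TRUE)
  assert_fraction(duplicate_rate, "duplicate_rate")
  assert_fraction(deletion_rate, "deletion_rate")
  assert_fraction(missing_field_rates, "missing_field_rates")
  assert_fraction(variant_rate, "variant_rate", allow_one = TRUE)
  assert_fraction(base_pt_rate, "base_pt_rate")
  assert_fraction(indication_rate, "indication_rate")
  if (nrow(pt_vocabulary) == 0) {
    rlang::abort("`pt_vocabulary` must be non-empty", class = "pvsignal_config_error")
  }
  if (nrow(signal_specs)) {
    assert_fraction(signal_specs$p_target, "signal_specs$p_target")
    if (any(signal_specs$p_background <= 0 | signal_specs$p_background >= 1)) {
      rlang::abort("`signal_specs$p_background` must be in (0, 1)",
                   class = "pvsignal_config_error")
    }
    extra <- setdiff(signal_specs$pt, pt_vocabulary$pt)
    if (length(extra)) {
      rlang::abort(paste0("signal_specs name PTs absent from pt_vocabulary: ",
                          paste(extra, collapse = ", ")),
                   class = "pvsignal_config_error")
    }
  }
  for (f in c("gender", "age_band", "pb_class")) {
    p <- covariate_mix[[f]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9) {
      rlang::abort(sprintf("covariate_mix$%s probabilities must sum to 1", f),
                   class = "pvsignal_config_error")
    }
  }
  assert_fraction(covariate_mix$cyp_given_concomitant,
                  "covariate_mix$cyp_given_concomitant")
  if (!inherits(severity_model, "severity_model")) {
    rlang::abort("`severity_model` must be created by severity_model()",
                 class = "pvsignal_config_error")
  }
  structure(list(
    n_cases = n_cases, n_quarters = n_quarters,
    target_drug = target_drug, background_drugs = background_drugs,
    target_fraction = target_fraction,
    duplicate_rate = duplicate_rate, deletion_rate = deletion_rate,
    missing_field_rates = missing_field_rates,
    synonym_table = synonym_table, variant_rate = variant_rate,
    pt_vocabulary = pt_vocabulary, signal_specs = signal_specs,
    base_pt_rate = base_pt_rate, indication_rate = indication_rate,
    severity_model = severity_model, covariate_mix = covariate_mix,
    drug_properties = drug_properties,
    seed = as.integer(seed)
  ), class = "srs_config")
}

#' Implied true reporting odds ratio of a signal specification
#'
#' Converts per-arm listing probabilities to the reporting odds ratio they
#' imply: `[p_t/(1-p_t)] / [p_b/(1-p_b)]`.
#'
#' @param p_target,p_background Per-report listing probabilities.
#' @return Numeric vector of odds ratios.
#' @export
implied_ror <- function(p_target, p_background) {
  (p_target / (1 - p_target)) / (p_background / (1 - p_background))
}
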