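# Synthetic spontaneous-reporting-system generator.
#
# Produces FAERS-shaped quarterly tables with known ground truth: injected
# per-PT reporting odds ratios, duplicate/deletion structure and a logistic
# severity model, so every downstream stage can be validated without a
# reporting-system archive.

QUARTER_END_YEAR <- 2023L
QUARTER_END_Q <- 3L

quarter_labels <- function(n) {
  t_end <- QUARTER_END_YEAR * 4L + (QUARTER_END_Q - 1L)
  t <- t_end - (n - seq_len(n))
  sprintf("%02dQ%d", (t %/% 4L) %% 100L, t %% 4L + 1L)
}

quarter_bounds <- function(n) {
  t_end <- QUARTER_END_YEAR * 4L + (QUARTER_END_Q - 1L)
  t <- t_end - (n - seq_len(n))
  start <- as.Date(sprintf("%d-%02d-01", t %/% 4L, (t %% 4L) * 3L + 1L))
  t2 <- t + 1L
  nxt <- as.Date(sprintf("%d-%02d-01", t2 %/% 4L, (t2 %% 4L) * 3L + 1L))
  list(start = start, end = nxt - 1)
}

date_to_int <- function(d) as.integer(format(d, "%Y%m%d"))

# severity linear predictor: intercept + sum of level coefficients
model_eta <- function(model, data,
                      factors = c("gender", "age_band", "pb_class", "cyp_class")) {
  eta <- rep(model$intercept, nrow(data))
  for (f in intersect(factors, names(data))) {
    key <- paste0(f, ":", as.character(data[[f]]))
    coefs <- model$coefficients[key]
    coefs[is.na(coefs)] <- 0
    eta <- eta + unname(coefs)
  }
  eta
}

sample_lv <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# ---- case-level generation ------------------------------------------------

gen_case_core <- function(config) {
  n <- config$n_cases
  mix <- config$covariate_mix
  if (n == 0) {
    return(tibble::tibble(
      caseid = integer(), primaryid = integer(), quarter_idx = integer(),
      fda_dt = as.Date(character()), gender = character(),
      age_band = character(), age = numeric(), age_cod = character(),
      occp_cod = character(), reporter_country = character(),
      is_target = logical(), ps_drug = character(),
      concomitants = list(), pb_class = character(), cyp_class = character(),
      indication = character()
    ))
  }
  caseid <- 10000000L + seq_len(n)
  quarter_idx <- sample.int(config$n_quarters, n, replace = TRUE)
  qb <- quarter_bounds(config$n_quarters)
  qlen <- as.integer(qb$end - qb$start)
  fda_dt <- qb$start[quarter_idx] +
    floor(runif(n) * (qlen[quarter_idx] - 35L))  # head-room for duplicate dates

  gender <- sample_lv(n, mix$gender)
  age_band <- sample_lv(n, mix$age_band)
  age_years <- dplyr::case_when(
    age_band == "0-44"  ~ sample(28:44, n, replace = TRUE),
    age_band == "45-59" ~ sample(45:59, n, replace = TRUE),
    age_band == "60-74" ~ sample(60:74, n, replace = TRUE),
    TRUE                ~ sample(75:90, n, replace = TRUE)
  )
  u <- runif(n)
  age_cod <- dplyr::case_when(u < 0.03 ~ "MON", u < 0.05 ~ "DY", TRUE ~ "YR")
  age <- dplyr::case_when(
    age_cod == "YR"  ~ as.numeric(age_years),
    age_cod == "MON" ~ age_years * 12,
    TRUE             ~ ceiling(age_years * 365.25)
  )
  occp_cod <- sample_lv(n, c(MD = 0.45, PH = 0.15, HP = 0.11, CN = 0.29))
  reporter_country <- sample_lv(n, c(US = 0.50, DE = 0.11, FR = 0.06, CA = 0.05,
                                     JP = 0.05, GB = 0.12, IT = 0.11))

  is_target <- runif(n) < config$target_fraction
  ps_drug <- ifelse(is_target, config$target_drug,
                    sample(config$background_drugs, n, replace = TRUE))

  props <- config$drug_properties
  noncyp <- props[!props$is_cyp3a4_inhibitor & props$drug != config$target_drug, ]
  pool <- list(
    "<85"    = noncyp$drug[noncyp$protein_binding_pct < 85],
    "85-<98" = noncyp$drug[noncyp$protein_binding_pct >= 85 & noncyp$protein_binding_pct < 98],
    ">=98"   = noncyp$drug[noncyp$protein_binding_pct >= 98]
  )
  cyp_pool <- props$drug[props$is_cyp3a4_inhibitor]
  pb_class <- sample_lv(n, mix$pb_class)
  has_con <- pb_class != "none"
  cyp_flag <- has_con & (runif(n) < mix$cyp_given_concomitant)
  extra <- runif(n) < 0.4
  pick <- function(pool) pool[sample.int(length(pool), 1L)]
  concomitants <- purrr::pmap(
    list(pb_class, cyp_flag, extra),
    function(cls, cyp, ex) {
      if (cls == "none") return(character())
      d <- pick(pool[[cls]])
      if (ex) d <- unique(c(d, pick(pool[["<85"]])))
      if (cyp) d <- unique(c(d, pick(cyp_pool)))
      d
    }
  )
  cyp_class <- dplyr::case_when(!has_con ~ "none",
                                cyp_flag ~ "cyp3a4_inhibitor",
                                TRUE ~ "other_concomitant")

  ind_u <- runif(n)
  indication <- dplyr::case_when(
    ind_u < 0.62 ~ "Breast cancer",
    ind_u < 0.98 ~ "Breast cancer metastatic",
    TRUE ~ NA_character_
  )

  # demographic missingness (MCAR): blank at configured per-field rates;
  # duplicates inherit the blanks so dedup is checkable by count alone
  mr <- config$missing_field_rates
  if (!is.na(mr["age"]) && mr["age"] > 0) {
    miss <- runif(n) < mr["age"]
    age[miss] <- NA; age_cod[miss] <- NA
  }
  if (!is.na(mr["sex"]) && mr["sex"] > 0) gender[runif(n) < mr["sex"]] <- NA
  if (!is.na(mr["occp_cod"]) && mr["occp_cod"] > 0) occp_cod[runif(n) < mr["occp_cod"]] <- NA
  if (!is.na(mr["reporter_country"]) && mr["reporter_country"] > 0) {
    reporter_country[runif(n) < mr["reporter_country"]] <- NA
  }

  tibble::tibble(
    caseid = caseid, primaryid = caseid * 10L + 1L, quarter_idx = quarter_idx,
    fda_dt = fda_dt, gender = gender, age_band = age_band, age = age,
    age_cod = age_cod, occp_cod = occp_cod, reporter_country = reporter_country,
    is_target = is_target, ps_drug = ps_drug, concomitants = concomitants,
    pb_class = pb_class, cyp_class = cyp_class, indication = indication
  )
}

# Each report samples each vocabulary PT independently (Bernoulli), with a
# full-row resample when no PT comes up, so every report lists >= 1 PT.
gen_reactions <- function(cases, config) {
  n <- nrow(cases)
  if (n == 0) {
    cases$pts <- list()
    return(cases)
  }
  ind_pts <- unique(stats::na.omit(cases$indication))
  vocab <- setdiff(config$pt_vocabulary$pt, ind_pts)
  p_bg <- setNames(rep(config$base_pt_rate, length(vocab)), vocab)
  p_tg <- p_bg
  if (nrow(config$signal_specs)) {
    ss <- config$signal_specs[config$signal_specs$pt %in% vocab, ]
    p_bg[ss$pt] <- ss$p_background
    p_tg[ss$pt] <- ss$p_target
  }
  P <- length(vocab)
  draw_arm <- function(idx, p) {
    m <- length(idx)
    out <- vector("list", m)
    pending <- seq_len(m)
    while (length(pending)) {
      hits <- matrix(runif(length(pending) * P), ncol = P) <
        matrix(p, nrow = length(pending), ncol = P, byrow = TRUE)
      got <- rowSums(hits) > 0
      for (k in which(got)) out[[pending[k]]] <- vocab[hits[k, ]]
      pending <- pending[!got]
    }
    out
  }
  pts <- vector("list", n)
  tg <- which(cases$is_target); bg <- which(!cases$is_target)
  if (length(tg)) pts[tg] <- draw_arm(tg, p_tg)
  if (length(bg)) pts[bg] <- draw_arm(bg, p_bg)
  # indication bias: the treated disease occasionally reported as an AE
  bias <- runif(n) < config$indication_rate & !is.na(cases$indication)
  pts[bias] <- purrr::map2(pts[bias], cases$indication[bias], ~ unique(c(.x, .y)))
  cases$pts <- pts
  cases
}

gen_outcomes <- function(cases, config) {
  n <- nrow(cases)
  if (n == 0) {
    cases$serious <- logical(); cases$outc_codes <- list()
    return(cases)
  }
  eta <- model_eta(config$severity_model, cases)
  serious <- runif(n) < stats::plogis(eta)
  serious_codes <- c(DE = 1439, LT = 66, HO = 1782, DS = 155, CA = 10, RI = 30)
  codes <- ifelse(serious,
                  sample_lv(n, serious_codes / sum(serious_codes)),
                  "OT")
  cases$serious <- serious
  cases$outc_codes <- as.list(codes)
  cases
}

#' Re-emit a fraction of cases as duplicate reports
#'
#' Emulates the duplicate submissions that case-level deduplication must
#' remove. `ceiling(duplicate_rate * n)` cases are re-emitted with the same
#' CASEID and either a later FDA_DT or a larger PRIMARYID; the clinical
#' content is copied verbatim so that dedup correctness is checkable by
#' count alone. Originals are kept.
#'
#' @param cases A case-level tibble carrying at least `caseid`,
#'   `primaryid`, `fda_dt` (Date).
#' @param duplicate_rate Fraction in `[0, 1)`.
#' @param seed Integer seed for the duplicate draw.
#' @return The input with duplicate rows appended.
#' @export
inject_duplicates <- function(cases, duplicate_rate, seed = 1L) {
  assert_fraction(duplicate_rate, "duplicate_rate")
  n <- nrow(cases)
  n_dup <- ceiling(duplicate_rate * n)
  if (n_dup == 0) return(cases)
  with_substream(seed, "pick", {
    idx <- sample.int(n, n_dup)
    dup <- cases[idx, ]
    dup$primaryid <- dup$caseid * 10L + 2L
    later <- seq_len(n_dup) %% 2L == 0L
    dup$fda_dt[later] <- dup$fda_dt[later] + sample(1:30, sum(later), replace = TRUE)
    dplyr::bind_rows(cases, dup)
  })
}

pick_deletions <- function(cases, config) {
  n_del <- floor(config$deletion_rate * nrow(cases))
  eligible <- cases$caseid[cases$quarter_idx < config$n_quarters]
  n_del <- min(n_del, length(eligible))
  if (n_del == 0) return(integer())
  sort(sample(eligible, n_del))
}

variant_names <- function(drug, config) {
  syn <- config$synonym_table
  if (is.null(syn) || nrow(syn) == 0 || config$variant_rate == 0) return(drug)
  out <- drug
  flip <- runif(length(drug)) < config$variant_rate
  for (i in which(flip)) {
    v <- syn$variant[syn$canonical == drug[i]]
    if (length(v)) out[i] <- v[sample.int(length(v), 1L)]
  }
  out
}

materialize_quarters <- function(cases, deleted_caseids, config) {
  labels <- quarter_labels(config$n_quarters)
  empty <- list(
    demo = tibble::tibble(primaryid = integer(), caseid = integer(),
                          fda_dt = integer(), age = numeric(), age_cod = character(),
                          sex = character(), occp_cod = character(),
                          reporter_country = character(), event_dt = integer()),
    drug = tibble::tibble(primaryid = integer(), caseid = integer(),
                          drugname = character(), role_cod = character()),
    reac = tibble::tibble(primaryid = integer(), caseid = integer(), pt = character()),
    outc = tibble::tibble(primaryid = integer(), caseid = integer(), outc_cod = character()),
    ther = tibble::tibble(primaryid = integer(), caseid = integer(), start_dt = integer()),
    indi = tibble::tibble(primaryid = integer(), caseid = integer(), indi_pt = character()),
    deleted = integer()
  )
  out <- lapply(seq_len(config$n_quarters), function(q) {
    rows <- cases[cases$quarter_idx == q, ]
    if (nrow(rows) == 0) {
      tabs <- empty
    } else {
      sex <- dplyr::case_when(rows$gender == "male" ~ "M",
                              rows$gender == "female" ~ "F",
                              TRUE ~ NA_character_)
      demo <- tibble::tibble(
        primaryid = rows$primaryid, caseid = rows$caseid,
        fda_dt = date_to_int(rows$fda_dt), age = rows$age, age_cod = rows$age_cod,
        sex = sex, occp_cod = rows$occp_cod,
        reporter_country = rows$reporter_country,
        event_dt = date_to_int(rows$fda_dt - 30)
      )
      con <- tidyr::unnest(
        tibble::tibble(primaryid = rows$primaryid, caseid = rows$caseid,
                       drugname = rows$concomitants),
        "drugname")
      if (nrow(con)) {
        con$role_cod <- sample_lv(nrow(con), c(C = 0.9, SS = 0.1))
      } else {
        con$role_cod <- character()
      }
      drug <- dplyr::bind_rows(
        tibble::tibble(primaryid = rows$primaryid, caseid = rows$caseid,
                       drugname = rows$ps_drug, role_cod = "PS"),
        con
      )
      drug$drugname <- variant_names(drug$drugname, config)
      drug <- dplyr::arrange(drug, .data$primaryid, .data$role_cod, .data$drugname)
      reac <- tidyr::unnest(
        tibble::tibble(primaryid = rows$primaryid, caseid = rows$caseid,
                       pt = rows$pts), "pt")
      outc <- tidyr::unnest(
        tibble::tibble(primaryid = rows$primaryid, caseid = rows$caseid,
                       outc_cod = rows$outc_codes), "outc_cod")
      ther <- tibble::tibble(primaryid = rows$primaryid, caseid = rows$caseid,
                             start_dt = date_to_int(rows$fda_dt - 60))
      indi <- tibble::tibble(primaryid = rows$primaryid, caseid = rows$caseid,
                             indi_pt = rows$indication)
      indi <- indi[!is.na(indi$indi_pt), ]
      tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc,
                   ther = ther, indi = indi, deleted = integer())
    }
    # deleted-case lists ship with the final quarter
    if (q == config$n_quarters) tabs$deleted <- deleted_caseids
    tabs
  })
  names(out) <- labels
  out
}

#' Generate a synthetic multi-quarter reporting-system dataset
#'
#' Draws `n_cases` unique cases (demographics, suspect and concomitant
#' drugs, adverse-event PTs, outcome codes), re-emits a fraction as
#' duplicate reports, selects cases for a deleted-case list, and
#' materializes FAERS-shaped quarterly tables (DEMO, DRUG, REAC, OUTC,
#' THER, INDI plus the deletion list). PT listing probabilities follow the
#' configured signal specifications, so every PT has a known implied
#' reporting odds ratio; outcome seriousness follows the configured
#' logistic severity model. Fully reproducible: the same config (including
#' seed) yields byte-identical output.
#'
#' @param config An [srs_config()].
#' @return A list with elements `quarters` (named list of per-quarter table
#'   lists) and `ground_truth` (list with `intended_cases`, the per-PT
#'   `true_ror` tibble, the generating `severity_model`, and the deleted
#'   CASEIDs).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "srs_config")) {
    rlang::abort("`config` must be created by srs_config()",
                 class = "pvsignal_config_error")
  }
  seed <- config$seed
  cases <- with_substream(seed, "cases", gen_case_core(config))
  cases <- with_substream(seed, "reactions", gen_reactions(cases, config))
  cases <- with_substream(seed, "severity", gen_outcomes(cases, config))
  deleted <- with_substream(seed, "deletions", pick_deletions(cases, config))
  aug <- inject_duplicates(cases, config$duplicate_rate,
                           substream_seed(seed, "duplicates"))
  quarters <- with_substream(seed, "materialize",
                             materialize_quarters(aug, deleted, config))

  ind_pts <- unique(stats::na.omit(cases$indication))
  vocab <- setdiff(config$pt_vocabulary$pt, ind_pts)
  tr <- tibble::tibble(pt = vocab,
                       p_target = config$base_pt_rate,
                       p_background = config$base_pt_rate)
  if (nrow(config$signal_specs)) {
    m <- match(config$signal_specs$pt, tr$pt)
    tr$p_target[m] <- config$signal_specs$p_target
    tr$p_background[m] <- config$signal_specs$p_background
  }
  tr$true_ror <- implied_ror(tr$p_target, tr$p_background)
  list(
    quarters = quarters,
    ground_truth = list(
      intended_cases = config$n_cases - length(deleted),
      true_ror = tr,
      severity_model = config$severity_model,
      deleted_caseids = deleted
    )
  )
}

#' Simulate covariate profiles from a logistic severity model
#'
#' Draws per-report covariates (gender, age band, concomitant
#' protein-binding class, CYP3A4 class) from the supplied marginal mix and
#' a serious/non-serious outcome from the logistic model, bypassing the
#' full report-table machinery. Used for regression parameter-recovery
#' studies.
#'
#' @param n Number of profiles.
#' @param model A [severity_model()].
#' @param mix Covariate marginals, see [default_covariate_mix()].
#' @param seed Integer seed.
#' @return A tibble with columns `serious` (logical), `gender`,
#'   `age_band`, `pb_class`, `cyp_class` (factors, reference level first).
#' @export
simulate_profiles <- function(n, model = severity_model(),
                              mix = default_covariate_mix(), seed = 1L) {
  n <- assert_count(n, "n")
  with_substream(seed, "profiles", {
    gender <- sample_lv(n, mix$gender)
    age_band <- sample_lv(n, mix$age_band)
    pb_class <- sample_lv(n, mix$pb_class)
    cyp_class <- ifelse(pb_class == "none", "none",
                        ifelse(runif(n) < mix$cyp_given_concomitant,
                               "cyp3a4_inhibitor", "other_concomitant"))
    prof <- tibble::tibble(
      gender = factor(gender, levels = c("male", "female")),
      age_band = factor(age_band, levels = c("0-44", "45-59", "60-74", ">=75")),
      pb_class = factor(pb_class, levels = c("none", "<85", "85-<98", ">=98")),
      cyp_class = factor(cyp_class,
                         levels = c("none", "other_concomitant", "cyp3a4_inhibitor"))
    )
    prof$serious <- runif(n) < stats::plogis(model_eta(model, prof))
    prof[, c("serious", "gender", "age_band", "pb_class", "cyp_class")]
  })
}
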