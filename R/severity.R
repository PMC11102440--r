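# Severe-event risk modelling: seriousness classification, covariate
# derivation (age band, gender, concomitant protein-binding class, CYP3A4
# class) and univariate/multivariate logistic regression reported as odds
# ratios with Wald 95% confidence intervals.

SERIOUS_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI")
KNOWN_OUTCOME_CODES <- c(SERIOUS_CODES, "OT")

#' Classify reports as serious
#'
#' A report is serious when any of its outcome codes is DE (death), LT
#' (life-threatening), HO (hospitalization or prolongation), DS
#' (disability), CA (congenital anomaly) or RI (required intervention to
#' prevent harm). Reports with multiple events are serious if any event
#' qualifies. Unrecognized codes are non-qualifying and logged.
#'
#' @param outcome_codes A list of character vectors (one per report) or a
#'   single character vector for one report.
#' @param serious_codes Qualifying code set (configurable).
#' @return Logical vector, one element per report.
#' @export
classify_seriousness <- function(outcome_codes, serious_codes = SERIOUS_CODES) {
  if (!is.list(outcome_codes)) outcome_codes <- list(outcome_codes)
  all_codes <- unlist(outcome_codes, use.names = FALSE)
  unknown <- setdiff(unique(all_codes), c(KNOWN_OUTCOME_CODES, serious_codes, NA))
  if (length(unknown)) {
    pv_log("classify_seriousness: unknown outcome code(s) ignored: %s",
           paste(unknown, collapse = ", "))
  }
  vapply(outcome_codes, function(x) any(x %in% serious_codes), logical(1))
}

#' Band an age in years
#'
#' Cut-points 45, 60, 75; `NA` maps to `"unknown"`. Minors fold into the
#' 0-44 reference band.
#'
#' @param age_years Numeric vector.
#' @return Character vector of bands.
#' @export
age_band <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 45 ~ "0-44",
    age_years < 60 ~ "45-59",
    age_years < 75 ~ "60-74",
    TRUE ~ ">=75"
  )
}

pb_class_of <- function(pct) {
  dplyr::case_when(pct >= 98 ~ ">=98", pct >= 85 ~ "85-<98", TRUE ~ "<85")
}

#' Derive regression covariates for each target-drug case
#'
#' Concomitant drugs are those with role code C or SS, excluding the
#' target drug itself. The protein-binding class is the class of the
#' maximum binding percentage among a report's concomitants (`none` when
#' there are none); the CYP3A4 class is `cyp3a4_inhibitor` if any
#' concomitant is a flagged inhibitor, `other_concomitant` if concomitants
#' exist but none is flagged, otherwise `none`. Concomitants absent from
#' the property table contribute nothing and are tallied to the log.
#'
#' @param cases Case-level tibble (drug names normalized).
#' @param property_table Tibble `drug`, `protein_binding_pct`,
#'   `is_cyp3a4_inhibitor`.
#' @param target_drug Canonical target drug name.
#' @return A tibble of covariate profiles: `caseid`, `serious`, `gender`,
#'   `age_band`, `pb_class`, `cyp_class` (factors with reference level
#'   first; unknowns kept as an explicit level for gender/age).
#' @export
derive_covariates <- function(cases, property_table, target_drug) {
  pb <- setNames(property_table$protein_binding_pct, property_table$drug)
  cyp <- setNames(property_table$is_cyp3a4_inhibitor, property_table$drug)
  n_unmatched <- 0L
  per_case <- lapply(cases$drugs, function(d) {
    con <- unique(d$drugname[d$role_cod %in% c("C", "SS") & d$drugname != target_drug])
    if (!length(con)) return(c(pb = NA_real_, cyp = 0, any = 0, unmatched = 0))
    known <- con[con %in% names(pb)]
    c(pb = if (length(known)) max(pb[known]) else NA_real_,
      cyp = as.numeric(any(cyp[known])),
      any = 1,
      unmatched = length(con) - length(known))
  })
  m <- do.call(rbind, per_case)
  if (nrow(cases) == 0) {
    m <- matrix(numeric(), ncol = 4,
                dimnames = list(NULL, c("pb", "cyp", "any", "unmatched")))
  }
  n_unmatched <- sum(m[, "unmatched"])
  if (n_unmatched > 0) {
    pv_log("derive_covariates: %d concomitant record(s) absent from property table",
           n_unmatched)
  }
  pb_cls <- ifelse(m[, "any"] == 0, "none",
                   ifelse(is.na(m[, "pb"]), "none", pb_class_of(m[, "pb"])))
  cyp_cls <- ifelse(m[, "any"] == 0, "none",
                    ifelse(m[, "cyp"] > 0, "cyp3a4_inhibitor", "other_concomitant"))
  tibble::tibble(
    caseid = cases$caseid,
    serious = classify_seriousness(cases$outcomes),
    gender = factor(cases$gender, levels = c("male", "female", "unknown")),
    age_band = factor(age_band(cases$age_years),
                      levels = c("0-44", "45-59", "60-74", ">=75", "unknown")),
    pb_class = factor(pb_cls, levels = c("none", "<85", "85-<98", ">=98")),
    cyp_class = factor(cyp_cls,
                       levels = c("none", "other_concomitant", "cyp3a4_inhibitor"))
  )
}

drop_unknown <- function(profiles, factors) {
  keep <- rep(TRUE, nrow(profiles))
  for (f in factors) {
    x <- as.character(profiles[[f]])
    keep <- keep & !is.na(x) & x != "unknown"
  }
  out <- profiles[keep, ]
  for (f in factors) out[[f]] <- droplevels(out[[f]])
  out
}

# one fitted glm -> tidy effect table with reference rows
effect_table <- function(fit, data, factors) {
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  rows <- list()
  for (f in factors) {
    levs <- levels(data[[f]])
    counts <- table(data[[f]])
    for (i in seq_along(levs)) {
      lev <- levs[i]
      nm <- paste0(f, lev)
      if (i == 1) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          factor = f, level = lev, n_level = as.integer(counts[lev]),
          or = 1, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_, is_reference = TRUE)
      } else if (nm %in% names(cf)) {
        z <- unname(cf[nm] / se[nm])
        rows[[length(rows) + 1]] <- tibble::tibble(
          factor = f, level = lev, n_level = as.integer(counts[lev]),
          or = exp(unname(cf[nm])),
          ci_low = exp(unname(cf[nm] - 1.96 * se[nm])),
          ci_high = exp(unname(cf[nm] + 1.96 * se[nm])),
          p_value = 2 * stats::pnorm(-abs(z)), is_reference = FALSE)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Fit a logistic regression of serious outcome on coded factors
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]) of `serious ~ factors`, dummy-coded against each
#' factor's first (reference) level. Rows with an unknown level in any
#' requested factor are excluded. Returns one row per factor level with
#' the odds ratio `exp(coef)`, Wald 95% CI `exp(coef +/- 1.96 SE)` and
#' two-sided Wald p-value; reference rows carry OR fixed at 1.
#'
#' @param profiles Covariate tibble from [derive_covariates()] or
#'   [simulate_profiles()] with a logical/0-1 `serious` column.
#' @param factors Character vector of factor columns to include jointly.
#' @return A list with `estimates` (effect tibble) and `fit` (the glm).
#' @export
fit_logistic <- function(profiles, factors) {
  data <- drop_unknown(profiles, factors)
  if (nrow(data) == 0 || length(unique(data$serious)) < 2) {
    rlang::abort("outcome must include both classes after exclusions",
                 class = "pvsignal_input_error")
  }
  for (f in factors) {
    if (nlevels(data[[f]]) < 2) {
      rlang::abort(sprintf("factor `%s` has a single level after exclusions", f),
                   class = "pvsignal_input_error")
    }
  }
  form <- stats::as.formula(paste("serious ~", paste(factors, collapse = " + ")))
  fit <- stats::glm(form, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    rlang::abort(paste0("logistic fit did not converge for: ",
                        paste(factors, collapse = ", ")),
                 class = "pvsignal_fit_error")
  }
  if (any(is.na(stats::coef(fit)))) {
    rlang::abort(paste0("aliased (collinear) terms among factors: ",
                        paste(factors, collapse = ", ")),
                 class = "pvsignal_fit_error")
  }
  if (any(!is.finite(stats::coef(fit))) ||
      any(sqrt(diag(stats::vcov(fit))) > 1e3)) {
    rlang::abort(paste0("separation suspected in factors: ",
                        paste(factors, collapse = ", ")),
                 class = "pvsignal_fit_error")
  }
  list(estimates = effect_table(fit, data, factors), fit = fit)
}

#' Univariate screen for multivariate inclusion
#'
#' Fits each factor alone and admits it to the multivariate model iff any
#' non-reference level has a Wald p-value below `alpha`. The selection is
#' reported via the log, never silent.
#'
#' @param profiles Covariate tibble.
#' @param all_factors Candidate factor names.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `selected` (character), `univariate` (combined effect
#'   tibble over all candidates).
#' @export
univariate_screen <- function(profiles, all_factors, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) {
    rlang::abort("`alpha` must be in (0, 1)", class = "pvsignal_config_error")
  }
  uni <- lapply(all_factors, function(f) fit_logistic(profiles, f)$estimates)
  uni <- dplyr::bind_rows(uni)
  sel <- vapply(all_factors, function(f) {
    p <- uni$p_value[uni$factor == f & !uni$is_reference]
    any(p < alpha, na.rm = TRUE)
  }, logical(1))
  pv_log("univariate_screen: selected {%s}; dropped {%s}",
         paste(all_factors[sel], collapse = ", "),
         paste(all_factors[!sel], collapse = ", "))
  list(selected = all_factors[sel], univariate = uni)
}

#' Univariate and multivariate severe-event risk analysis
#'
#' Runs the univariate screen over the candidate factors, then fits the
#' multivariate logistic model on the selected subset (skipped, with a
#' notice, when nothing is selected).
#'
#' @param profiles Covariate tibble from [derive_covariates()].
#' @param factors Candidate factors.
#' @param alpha Univariate inclusion threshold.
#' @return An object of class `severity_fit`: list with `univariate`,
#'   `multivariate` (effect tibbles; multivariate `NULL` if skipped),
#'   `selected`, `n_used`, and the multivariate `fit`.
#' @export
severity_analysis <- function(profiles,
                              factors = c("gender", "age_band",
                                          "pb_class", "cyp_class"),
                              alpha = 0.05) {
  scr <- univariate_screen(profiles, factors, alpha)
  multi <- NULL
  fit <- NULL
  if (length(scr$selected)) {
    # order by univariate strength so that, if the selected factors are
    # collinear (e.g. the protein-binding and CYP classes both encode
    # "has a concomitant drug"), the weakest factor is dropped first
    strength <- vapply(scr$selected, function(f) {
      p <- scr$univariate$p_value[scr$univariate$factor == f &
                                    !scr$univariate$is_reference]
      min(p, na.rm = TRUE)
    }, numeric(1))
    keep <- scr$selected[order(strength)]
    res <- NULL
    while (is.null(res) && length(keep)) {
      res <- tryCatch(fit_logistic(profiles, keep),
                      pvsignal_fit_error = function(e) NULL)
      if (is.null(res)) {
        pv_log("severity_analysis: dropping `%s` from the multivariate model (collinearity/instability)",
               keep[length(keep)])
        keep <- keep[-length(keep)]
      }
    }
    if (is.null(res)) {
      rlang::abort("no multivariate model could be fitted",
                   class = "pvsignal_fit_error")
    }
    scr$selected <- keep
    multi <- res$estimates
    fit <- res$fit
  } else {
    pv_log("severity_analysis: no factor passed the univariate screen; multivariate step skipped")
  }
  structure(list(univariate = scr$univariate, multivariate = multi,
                 selected = scr$selected, fit = fit,
                 n_total = nrow(profiles),
                 n_serious = sum(profiles$serious)),
            class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, ...) {
  cat("Severe-event logistic risk analysis\n")
  cat(sprintf("  reports: %d (%d serious, %.2f%%)\n", x$n_total, x$n_serious,
              100 * x$n_serious / max(x$n_total, 1)))
  cat(sprintf("  factors selected by univariate screen: %s\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)"))
  if (!is.null(x$multivariate)) {
    cat("  multivariate odds ratios:\n")
    df <- x$multivariate[!x$multivariate$is_reference, ]
    for (i in seq_len(nrow(df))) {
      cat(sprintf("    %s=%s: OR %.3f (%.3f, %.3f), p=%.3g\n",
                  df$factor[i], df$level[i], df$or[i], df$ci_low[i],
                  df$ci_high[i], df$p_value[i]))
    }
  }
  invisible(x)
}

#' Tidy a severity fit into one effect table
#'
#' @param x A `severity_fit`.
#' @param ... Unused.
#' @return Long tibble with an `analysis` column (`univariate` /
#'   `multivariate`) over the effect estimates.
#' @importFrom generics tidy
#' @export
tidy.severity_fit <- function(x, ...) {
  uni <- dplyr::mutate(x$univariate, analysis = "univariate")
  out <- uni
  if (!is.null(x$multivariate)) {
    out <- dplyr::bind_rows(uni, dplyr::mutate(x$multivariate,
                                               analysis = "multivariate"))
  }
  dplyr::select(out, "analysis", dplyr::everything())
}

#' Model-level summary of a severity fit
#'
#' @param x A `severity_fit`.
#' @param ... Unused.
#' @return One-row tibble: totals, serious fraction, selected factors, and
#'   (when fitted) the multivariate deviance/AIC.
#' @importFrom generics glance
#' @export
glance.severity_fit <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    n_serious = x$n_serious,
    pct_serious = 100 * x$n_serious / max(x$n_total, 1),
    n_factors_selected = length(x$selected),
    deviance = if (!is.null(x$fit)) stats::deviance(x$fit) else NA_real_,
    aic = if (!is.null(x$fit)) stats::AIC(x$fit) else NA_real_
  )
}

#' Forest plot of severity odds ratios
#'
#' @param object A `severity_fit`.
#' @param ... Unused.
#' @return A ggplot forest plot of univariate and multivariate ORs.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.severity_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[!df$is_reference, ]
  df$term <- paste(df$factor, df$level, sep = ": ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$term,
                                   colour = .data$analysis)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
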