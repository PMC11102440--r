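# Seriousness classification, covariate derivation and logistic risk models.

test_that("a report is serious when any outcome code qualifies", {
  expect_true(classify_seriousness("HO"))
  expect_false(classify_seriousness("OT"))
  expect_true(classify_seriousness(c("OT", "DE")))
  expect_equal(classify_seriousness(list("HO", "OT", c("OT", "DE"), "ZZ")),
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("serious plus non-serious counts conserve the case total", {
  ds <- generate_dataset(srs_config(n_cases = 500, seed = 5))
  tabs <- bind_quarters(ds$quarters)
  tabs$demo <- apply_deletions(deduplicate(tabs$demo), tabs$deleted)
  cases <- build_cases(tabs)
  serious <- classify_seriousness(cases$outcomes)
  expect_equal(sum(serious) + sum(!serious), nrow(cases))
})

test_that("covariates derive from age, gender and concomitant properties", {
  props <- default_drug_properties()
  cases <- mk_cases(1:4,
    age_years = c(63, 30, NA, 80),
    drugs = list(
      tibble::tibble(drugname = c("fulvestrant", "exemestane", "warfarin"),
                     role_cod = c("PS", "C", "C")),           # 90, 99 -> >=98
      tibble::tibble(drugname = "fulvestrant", role_cod = "PS"),  # none
      tibble::tibble(drugname = c("fulvestrant", "clarithromycin"),
                     role_cod = c("PS", "C")),                # cyp inhibitor
      tibble::tibble(drugname = c("fulvestrant", "mysterydrug"),
                     role_cod = c("PS", "SS"))                # unmatched
    ),
    outcomes = list("HO", "OT", "OT", "DE"))
  prof <- derive_covariates(cases, props, "fulvestrant")
  expect_equal(as.character(prof$age_band), c("60-74", "0-44", "unknown", ">=75"))
  expect_equal(as.character(prof$pb_class), c(">=98", "none", "<85", "none"))
  expect_equal(as.character(prof$cyp_class),
               c("other_concomitant", "none", "cyp3a4_inhibitor", "other_concomitant"))
  expect_equal(prof$serious, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("a single binary factor fit equals the closed-form odds ratio", {
  # exposed: 30 serious / 10 not; unexposed: 10 serious / 30 not
  prof <- tibble::tibble(
    serious = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30)),
    exposed = factor(rep(c("yes", "no"), c(40, 40)), levels = c("no", "yes"))
  )
  est <- fit_logistic(prof, "exposed")$estimates
  or <- est$or[est$level == "yes"]
  expect_equal(or, (30 * 30) / (10 * 10), tolerance = 1e-6)
})

test_that("null data give near-unit odds ratios", {
  model <- severity_model(intercept = 0.5, coefficients = numeric())
  prof <- simulate_profiles(50000, model = model, seed = 6)
  est <- fit_logistic(prof, c("gender", "age_band", "pb_class"))$estimates
  expect_true(all(abs(log(est$or[!est$is_reference])) < 0.15))
})

test_that("odds ratios are invariant to reordering non-reference levels", {
  prof <- simulate_profiles(20000, seed = 7)
  est1 <- fit_logistic(prof, "pb_class")$estimates
  prof2 <- prof
  prof2$pb_class <- factor(prof2$pb_class,
                           levels = c("none", ">=98", "<85", "85-<98"))
  est2 <- fit_logistic(prof2, "pb_class")$estimates
  for (lev in c("<85", "85-<98", ">=98")) {
    expect_equal(est1$or[est1$level == lev], est2$or[est2$level == lev],
                 tolerance = 1e-10)
  }
})

test_that("multivariate coefficients are recovered with small bias", {
  model <- severity_model()
  bias <- matrix(NA_real_, nrow = 20, ncol = 6)
  truth <- model$coefficients
  for (r in 1:20) {
    prof <- simulate_profiles(200000, model = model, seed = 500 + r)
    est <- fit_logistic(prof, c("age_band", "pb_class"))$estimates
    est <- est[!est$is_reference, ]
    key <- paste0(est$factor, ":", est$level)
    bias[r, ] <- log(est$or)[match(names(truth), key)] - truth
  }
  expect_lt(max(abs(colMeans(bias))), 0.02)
})

test_that("degenerate outcomes raise informative fit errors", {
  prof <- simulate_profiles(1000, seed = 8)
  prof$serious <- TRUE
  expect_error(fit_logistic(prof, "age_band"), "both classes",
               class = "pvsignal_input_error")
})

test_that("the univariate screen admits only factors with significant levels", {
  model <- severity_model(intercept = 1.5, coefficients = c(
    "age_band:60-74" = log(0.5), "pb_class:>=98" = log(1.6)))
  prof <- simulate_profiles(30000, model = model, seed = 9)
  scr <- univariate_screen(prof, c("gender", "age_band", "pb_class", "cyp_class"))
  expect_true(all(c("age_band", "pb_class") %in% scr$selected))
  expect_false("gender" %in% scr$selected)

  fit <- severity_analysis(prof)
  expect_s3_class(fit, "severity_fit")
  td <- tidy(fit)
  expect_true(all(c("univariate", "multivariate") %in% td$analysis))
  expect_true(all(td$or[td$is_reference] == 1))
  expect_true(all(td$ci_low <= td$or & td$or <= td$ci_high, na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(gl$n_total, 30000)

  # all-null model: nothing selected, multivariate skipped with notice
  null_model <- severity_model(intercept = 1, coefficients = numeric())
  null_prof <- simulate_profiles(300, model = null_model, seed = 10)
  fit0 <- severity_analysis(null_prof)
  expect_null(fit0$multivariate)
})
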