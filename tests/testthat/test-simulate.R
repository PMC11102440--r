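# Synthetic spontaneous-reporting-system generator.

test_that("empty configuration yields empty tables and zero ground truth", {
  ds <- generate_dataset(srs_config(n_cases = 0, seed = 1))
  expect_equal(ds$ground_truth$intended_cases, 0)
  for (q in ds$quarters) {
    expect_equal(nrow(q$demo), 0)
    expect_equal(nrow(q$reac), 0)
    expect_length(q$deleted, 0)
  }
})

test_that("identical configuration yields identical datasets", {
  cfg <- srs_config(n_cases = 400, seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(srs_config(n_cases = 400, seed = 100))
  expect_false(identical(d1$quarters, d3$quarters))
})

test_that("invalid probabilities raise configuration errors naming the field", {
  expect_error(srs_config(n_cases = 10, duplicate_rate = 1.2),
               "duplicate_rate", class = "pvsignal_config_error")
  expect_error(srs_config(n_cases = 10, deletion_rate = -0.1),
               "deletion_rate", class = "pvsignal_config_error")
  expect_error(
    srs_config(n_cases = 10,
               signal_specs = tibble::tibble(pt = "Neutropenia",
                                             p_target = 0.1, p_background = 0)),
    "p_background", class = "pvsignal_config_error")
})

test_that("duplicate injection re-emits the exact count with larger sort keys", {
  cases <- mk_cases(1:1000, fda_dt = as.Date("2023-01-15"))
  expect_identical(inject_duplicates(cases, 0, seed = 5), cases)

  aug <- inject_duplicates(cases, 0.1, seed = 5)
  expect_equal(nrow(aug), 1100)
  expect_equal(dplyr::n_distinct(aug$caseid), 1000)
  demo <- dplyr::mutate(aug, fda_dt = as.integer(format(fda_dt, "%Y%m%d")))
  expect_equal(nrow(deduplicate(demo)), 1000)

  one <- mk_cases(1L, fda_dt = as.Date("2023-01-15"))
  aug1 <- inject_duplicates(one, 0.5, seed = 5)
  expect_equal(nrow(aug1), 2)
  key_bigger <- aug1$fda_dt[2] > aug1$fda_dt[1] ||
    (aug1$fda_dt[2] == aug1$fda_dt[1] && aug1$primaryid[2] > aug1$primaryid[1])
  expect_true(key_bigger)
})

test_that("unique CASEIDs after duplication and deletion match the intended count", {
  cfg <- srs_config(n_cases = 1000, duplicate_rate = 0.1, deletion_rate = 0.05,
                    seed = 21)
  ds <- generate_dataset(cfg)
  tabs <- bind_quarters(ds$quarters)
  demo <- apply_deletions(deduplicate(tabs$demo), tabs$deleted)
  expect_equal(nrow(demo), ds$ground_truth$intended_cases)
  expect_equal(dplyr::n_distinct(tabs$demo$primaryid), nrow(tabs$demo))
})

test_that("without injected signals every empirical ROR is consistent with 1", {
  cfg <- srs_config(n_cases = 10000, signal_specs = tibble::tibble(
    pt = character(), p_target = numeric(), p_background = numeric()),
    seed = 31)
  ds <- generate_dataset(cfg)
  tabs <- bind_quarters(ds$quarters)
  tabs$drug <- normalize_drug_names(tabs$drug, cfg$synonym_table)
  cases <- build_cases(list(demo = apply_deletions(deduplicate(tabs$demo), tabs$deleted),
                            drug = tabs$drug, reac = tabs$reac,
                            outc = tabs$outc, ther = tabs$ther, indi = tabs$indi))
  sets <- select_target_cases(cases, "fulvestrant")
  st <- compute_ror(contingency_counts(sets$target, sets$background))
  st <- st[!is.na(st$ror) & !(st$pt %in% default_indication_pts()), ]
  z <- abs(log(st$ror)) / sqrt(1 / st$a + 1 / st$b + 1 / st$c + 1 / st$d)
  expect_gt(nrow(st), 20)
  expect_true(all(z < 4))
})

test_that("an injected signal's empirical ROR covers its implied value", {
  expect_equal(implied_ror(0.0417, 0.00423), 10.25, tolerance = 0.01)
  cfg <- srs_config(
    n_cases = 20000,
    signal_specs = tibble::tibble(pt = "Neutropenia",
                                  p_target = 0.0417, p_background = 0.00423),
    seed = 17)
  ds <- generate_dataset(cfg)
  tabs <- bind_quarters(ds$quarters)
  # brute-force oracle: count directly over generated rows, no pipeline
  demo <- apply_deletions(deduplicate(tabs$demo), tabs$deleted)
  drug <- normalize_drug_names(tabs$drug, cfg$synonym_table)
  target_pids <- unique(drug$primaryid[drug$drugname == "fulvestrant" &
                                         drug$role_cod == "PS"])
  is_t <- demo$primaryid %in% target_pids
  has_pt <- demo$primaryid %in% tabs$reac$primaryid[tabs$reac$pt == "Neutropenia"]
  a <- sum(is_t & has_pt); b <- sum(is_t & !has_pt)
  c_ <- sum(!is_t & has_pt); d <- sum(!is_t & !has_pt)
  st <- compute_ror(tab1(a, b, c_, d))
  true_ror <- ds$ground_truth$true_ror$true_ror[
    ds$ground_truth$true_ror$pt == "Neutropenia"]
  expect_equal(true_ror, 10.25, tolerance = 0.01)
  expect_true(st$ror_ci_low <= 10.3 && st$ror_ci_high >= 10.3)
})

test_that("with zero coefficients the serious fraction matches the intercept", {
  n <- 40000
  model <- severity_model(intercept = qlogis(0.7), coefficients = numeric())
  prof <- simulate_profiles(n, model = model, seed = 3)
  mc_se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(mean(prof$serious) - 0.7), 3 * mc_se)
})

test_that("profile simulation respects the covariate marginals", {
  prof <- simulate_profiles(50000, seed = 12)
  mix <- default_covariate_mix()
  expect_equal(as.numeric(prop.table(table(prof$age_band))),
               as.numeric(mix$age_band), tolerance = 0.02)
  expect_equal(as.numeric(prop.table(table(prof$pb_class))),
               as.numeric(mix$pb_class), tolerance = 0.02)
  expect_true(all(prof$cyp_class[prof$pb_class == "none"] == "none"))
})
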