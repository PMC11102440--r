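# Preprocessing: deduplication, deletions, completeness, normalization,
# target selection, indication exclusion, age conversion.

test_that("deduplication keeps the most recent date, then the largest primaryid", {
  rows <- tibble::tibble(caseid = c(111L, 111L), fda_dt = c(20230101L, 20230401L),
                         primaryid = c(5L, 4L))
  expect_equal(deduplicate(rows)$primaryid, 4L)

  rows2 <- tibble::tibble(caseid = c(222L, 222L), fda_dt = c(20230101L, 20230101L),
                          primaryid = c(5L, 9L))
  expect_equal(deduplicate(rows2)$primaryid, 9L)

  single <- tibble::tibble(caseid = 1L, fda_dt = 20230101L, primaryid = 2L)
  expect_equal(deduplicate(single), single)
})

test_that("deduplication is idempotent and permutation-invariant", {
  set.seed(8)
  rows <- tibble::tibble(
    caseid = sample(1:40, 200, replace = TRUE),
    fda_dt = sample(c(20230101L, 20230215L, 20230601L, NA), 200, replace = TRUE),
    primaryid = sample.int(10000, 200)
  )
  once <- deduplicate(rows)
  expect_equal(deduplicate(once), once)
  expect_equal(dplyr::n_distinct(once$caseid), nrow(once))
  expect_lte(nrow(once), nrow(rows))
  for (i in 1:5) {
    perm <- rows[sample.int(nrow(rows)), ]
    expect_equal(dplyr::arrange(deduplicate(perm), caseid),
                 dplyr::arrange(once, caseid))
  }
})

test_that("deletion lists remove exactly the listed present cases", {
  rows <- tibble::tibble(caseid = 1:1000, fda_dt = 20230101L, primaryid = 1:1000)
  expect_equal(apply_deletions(rows, integer()), rows)
  expect_equal(nrow(apply_deletions(rows, 1:50)), 950)
  expect_equal(nrow(apply_deletions(rows, c(5000L, 6000L))), 1000)
})

test_that("completeness filtering removes cases missing required fields", {
  cases <- mk_cases(1:100)
  cases$pts[[7]] <- character()            # empty reaction set
  cases$gender[1:7] <- NA
  expect_equal(nrow(filter_complete(cases, c("drugs", "pts"))), 99)
  expect_equal(filter_complete(cases, character()), cases)
  expect_equal(nrow(filter_complete(cases, "gender")), 93)
})

test_that("drug-name normalization maps variants case-insensitively", {
  syn <- tibble::tibble(variant = c("FASLODEX", "HERCEPTIN"),
                        canonical = c("fulvestrant", "trastuzumab"))
  rows <- tibble::tibble(drugname = c("FASLODEX", "Faslodex ", "letrozole",
                                      "herceptin"))
  out <- normalize_drug_names(rows, syn)
  expect_equal(out$drugname,
               c("fulvestrant", "fulvestrant", "letrozole", "trastuzumab"))

  bad <- tibble::tibble(variant = c("X", "x"), canonical = c("a", "b"))
  expect_error(normalize_drug_names(rows, bad), "conflict",
               class = "pvsignal_config_error")
})

test_that("target selection requires the primary-suspect role", {
  cases <- mk_cases(1:3, drugs = list(
    tibble::tibble(drugname = c("letrozole", "fulvestrant"),
                   role_cod = c("PS", "C")),      # target only concomitant
    tibble::tibble(drugname = c("fulvestrant", "aspirin", "metformin", "warfarin"),
                   role_cod = c("PS", "C", "C", "C")),
    tibble::tibble(drugname = "letrozole", role_cod = "PS")
  ))
  sets <- select_target_cases(cases, "fulvestrant")
  expect_equal(sets$target$caseid, 2L)
  expect_equal(sort(sets$background$caseid), c(1L, 3L))
  expect_equal(nrow(sets$target$drugs[[1]]), 4)

  none <- select_target_cases(cases[3, ], "fulvestrant")
  expect_equal(nrow(none$target), 0)
})

test_that("indication PTs are removed and emptied cases dropped", {
  cases <- mk_cases(1:3, pts = list(c("Breast cancer", "Neutropenia"),
                                    "Neutropenia",
                                    "Breast cancer"))
  out <- exclude_indication_pts(cases, "Breast cancer")
  expect_equal(out$caseid, c(1L, 2L))
  expect_equal(out$pts[[1]], "Neutropenia")
  expect_equal(exclude_indication_pts(cases, character()), cases)
})

test_that("ages convert to years by unit code", {
  expect_equal(convert_age(730.5, "DY"), 2.0)
  expect_equal(convert_age(65, "YR"), 65.0)
  expect_equal(convert_age(18, "MON"), 1.5)
  expect_true(is.na(convert_age(NA, NA)))
  expect_true(is.na(convert_age("n/a", "YR")))
  expect_true(is.na(convert_age(-3, "YR")))
})

test_that("pipeline conserves cases: target + background = filtered total", {
  cfg <- srs_config(n_cases = 3000, seed = 44)
  ds <- generate_dataset(cfg)
  tabs <- bind_quarters(ds$quarters)
  tabs$demo <- apply_deletions(deduplicate(tabs$demo), tabs$deleted)
  tabs$drug <- normalize_drug_names(tabs$drug, cfg$synonym_table)
  cases <- filter_complete(build_cases(tabs))
  expect_equal(nrow(cases), ds$ground_truth$intended_cases)
  sets <- select_target_cases(cases, "fulvestrant")
  expect_equal(nrow(sets$target) + nrow(sets$background), nrow(cases))
})
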