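# Disproportionality statistics and signal screening.

test_that("contingency tables count unique cases per PT", {
  sets <- mk_2x2_cases(2, 3, 4, 96)
  tab <- build_contingency(sets$target, sets$background, "X")
  expect_equal(tab[c("a", "b", "c", "d")], tab1(2L, 3L, 4L, 96L),
               ignore_attr = TRUE)
  expect_equal(tab$a + tab$b, nrow(sets$target))

  # recurring PT within one case counts once
  sets$target$pts[[1]] <- c("X", "X", "Other")
  expect_equal(build_contingency(sets$target, sets$background, "X")$a, 2)

  absent <- build_contingency(sets$target, sets$background, "Nowhere")
  expect_equal(absent$a, 0)
  expect_equal(absent$c, 0)

  overlap <- sets
  overlap$background$caseid[1] <- sets$target$caseid[1]
  expect_error(build_contingency(overlap$target, overlap$background, "X"),
               "overlap", class = "pvsignal_input_error")

  # every case has >= 1 PT, so per-PT a's sum to at least the case count
  counts <- contingency_counts(sets$target, sets$background)
  expect_gte(sum(counts$a), nrow(sets$target))
})

test_that("ROR and PRR match hand-computed values", {
  st <- compute_prr(compute_ror(tab1(2, 3, 4, 96)))
  expect_equal(st$ror, 16)                      # (2*96)/(3*4)
  expect_equal(st$prr, 10)                      # (2/5)/(4/100)
  expect_equal(st$chi2, 105 * 180^2 / (5 * 100 * 6 * 99))

  unity <- compute_ror(tab1(10, 10, 10, 10))
  expect_equal(unity$ror, 1)
  expect_equal(log(unity$ror_ci_high), -log(unity$ror_ci_low))

  null <- compute_prr(tab1(10, 90, 100, 900))   # ad = bc
  expect_equal(null$prr, 1)
  expect_equal(null$chi2, 0)
})

test_that("zero cells give undefined statistics unless corrected", {
  st <- compute_prr(compute_ror(tab1(0, 5, 3, 97)))
  expect_true(is.na(st$ror))
  expect_true(is.na(st$ror_ci_low))
  corrected <- compute_ror(tab1(0, 5, 3, 97), correction = TRUE)
  expect_equal(corrected$ror, (0.5 * 97.5) / (5.5 * 3.5))
  expect_false(screen_signals(compute_prr(compute_ror(tab1(0, 5, 3, 97))))$is_signal)
})

test_that("chi-square equals the brute-force observed-vs-expected sum", {
  set.seed(9)
  rt <- tab1(a = as.numeric(sample(1:500, 10000, TRUE)),
             b = as.numeric(sample(1:5000, 10000, TRUE)),
             c = as.numeric(sample(1:5000, 10000, TRUE)),
             d = as.numeric(sample(1:100000, 10000, TRUE)))
  st <- compute_prr(rt)
  oracle <- with(rt, {
    n <- a + b + c + d
    e <- function(r, cc) r * cc / n
    (a - e(a + b, a + c))^2 / e(a + b, a + c) +
      (b - e(a + b, b + d))^2 / e(a + b, b + d) +
      (c - e(c + d, a + c))^2 / e(c + d, a + c) +
      (d - e(c + d, b + d))^2 / e(c + d, b + d)
  })
  expect_lt(max(abs(st$chi2 - oracle) / pmax(oracle, 1e-12)), 1e-9)
})

test_that("ROR exceeds PRR exactly when ROR exceeds 1", {
  set.seed(10)
  rt <- tab1(a = as.numeric(sample(1:500, 10000, TRUE)),
             b = as.numeric(sample(1:5000, 10000, TRUE)),
             c = as.numeric(sample(1:5000, 10000, TRUE)),
             d = as.numeric(sample(1:100000, 10000, TRUE)))
  st <- compute_prr(compute_ror(rt))
  nd <- abs(st$ror - 1) > 1e-12
  expect_true(all((st$ror > st$prr)[nd] == (st$ror > 1)[nd]))
})

test_that("screening applies the dual criteria with the count floor", {
  st <- tibble::tibble(
    pt = c("low_count", "boundary", "weak_ror", "clear"),
    a = c(2, 3, 50, 40),
    ror = c(16, 1.5, 1.2, 5), ror_ci_low = c(2.1, 1.01, 0.99, 3),
    ror_ci_high = c(120, 2.2, 1.4, 8),
    prr = c(10, 2.1, 2.5, 4.9), chi2 = c(11, 4.0, 30, 300))
  out <- screen_signals(st)
  expect_equal(out$is_signal, c(FALSE, TRUE, FALSE, TRUE))
  expect_true(screen_signals(st, signal_criteria(combine = "prr_only"))$is_signal[3])
})

test_that("raising any threshold never adds a signal", {
  set.seed(11)
  rt <- compute_prr(compute_ror(tab1(
    a = sample(1:60, 400, TRUE), b = sample(1:2000, 400, TRUE),
    c = sample(1:2000, 400, TRUE), d = sample(1:50000, 400, TRUE))))
  rt$pt <- paste0("pt", seq_len(nrow(rt)))
  base <- screen_signals(rt)$is_signal
  harder <- list(
    signal_criteria(min_reports = 5),
    signal_criteria(ror_ci_low_gt = 1.5),
    signal_criteria(prr_gt = 3),
    signal_criteria(chi2_ge = 10))
  for (cr in harder) {
    expect_true(all(screen_signals(rt, cr)$is_signal <= base))
  }
})

test_that("label comparison partitions signals and reports the fraction", {
  sig <- tibble::tibble(pt = paste0("pt", 1:210), is_signal = TRUE)
  out <- compare_with_label(sig, paste0("pt", 1:165))
  summ <- label_summary(out)
  expect_equal(summ$n_unlabeled, 45)
  expect_equal(summ$pct_unlabeled, 100 * 45 / 210)

  all_un <- label_summary(compare_with_label(sig, character()))
  expect_equal(all_un$n_unlabeled, 210)

  ten <- tibble::tibble(pt = paste0("q", 1:10), is_signal = TRUE)
  expect_equal(label_summary(compare_with_label(ten, paste0("q", 1:4)))$n_unlabeled, 6)
})

test_that("signal ranking is deterministic under ties", {
  sig <- tibble::tibble(pt = c("b_pt", "a_pt", "c_pt"), a = c(10, 10, 50),
                        ror = c(2, 2, 1.5))
  byn <- rank_signals(sig, "report_count", 10)
  expect_equal(byn$pt, c("c_pt", "a_pt", "b_pt"))
  expect_equal(nrow(rank_signals(sig, "ror", 99)), 3)
  expect_equal(rank_signals(sig, "ror", 2)$pt, c("a_pt", "b_pt"))
})

test_that("stat inversion round-trips self-generated tables", {
  tab <- tab1(325, 6373, 17500, 3e7)
  st <- compute_prr(compute_ror(tab))
  rec <- invert_stats(325, st$ror, st$prr, st$chi2)
  expect_equal(rec$b, 6373, tolerance = 1e-6)
  expect_equal(rec$c, 17500, tolerance = 1e-6)
  expect_equal(rec$d, 3e7, tolerance = 1e-6)
  back <- compute_prr(compute_ror(rec))
  expect_equal(back$ror, st$ror, tolerance = 1e-6)
  expect_equal(back$prr, st$prr, tolerance = 1e-6)
  expect_equal(back$chi2, st$chi2, tolerance = 1e-6)
})

test_that("inconsistent printed statistics are reported as infeasible", {
  # ROR < 1 with PRR > 1 violates the sign-coherence identity: no table exists
  expect_error(invert_stats(10, 0.5, 2, 10),
               class = "pvsignal_infeasible_error")
  expect_error(invert_stats(0, 2, 1.9, 10), class = "pvsignal_input_error")
  expect_error(invert_stats(10, 2, 2, 10), class = "pvsignal_input_error")
})

test_that("null tables exclude 1 from the 95% CI at the nominal rate", {
  set.seed(42)
  n_t <- 200; n_b <- 2000; p <- 0.2; reps <- 1000
  a <- rbinom(reps, n_t, p)
  c_ <- rbinom(reps, n_b, p)
  tab <- tab1(a, n_t - a, c_, n_b - c_)
  tab <- tab[tab$a > 0 & tab$b > 0 & tab$c > 0 & tab$d > 0, ]
  st <- compute_ror(tab)
  excl <- mean(st$ror_ci_low > 1 | st$ror_ci_high < 1)
  mc_se <- sqrt(0.05 * 0.95 / nrow(tab))
  expect_lt(abs(excl - 0.05), 2 * mc_se)
})
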