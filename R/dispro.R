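# Disproportionality statistics: per-PT 2x2 contingency tables, ROR and
# PRR with their screening criteria, label comparison, ranking, and the
# inversion of published statistics back to a contingency table.
#
# Layout of the 2x2 table for one (drug, PT) pair:
#       a = target-drug reports listing the PT
#       b = target-drug reports not listing it
#       c = background reports listing the PT
#       d = background reports not listing it
# Counting unit is the unique case: a PT recurring within one report
# counts once.

#' Build the 2x2 contingency table for one PT
#'
#' @param target_cases,background_cases Disjoint case-level tibbles (from
#'   [select_target_cases()]).
#' @param pt PT string.
#' @return A one-row tibble with columns `pt`, `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(target_cases, background_cases, pt) {
  if (length(intersect(target_cases$caseid, background_cases$caseid))) {
    rlang::abort("target and background case sets overlap",
                 class = "pvsignal_input_error")
  }
  a <- sum(vapply(target_cases$pts, function(p) pt %in% p, logical(1)))
  c_ <- sum(vapply(background_cases$pts, function(p) pt %in% p, logical(1)))
  tibble::tibble(pt = pt, a = a, b = nrow(target_cases) - a,
                 c = c_, d = nrow(background_cases) - c_)
}

# vectorized per-PT counts over the union of PTs seen in the target set
contingency_counts <- function(target_cases, background_cases,
                               pts = NULL) {
  if (length(intersect(target_cases$caseid, background_cases$caseid))) {
    rlang::abort("target and background case sets overlap",
                 class = "pvsignal_input_error")
  }
  tg <- unlist(lapply(target_cases$pts, unique), use.names = FALSE)
  bg <- unlist(lapply(background_cases$pts, unique), use.names = FALSE)
  if (is.null(pts)) pts <- sort(unique(tg))
  a <- as.integer(table(factor(tg, levels = pts)))
  c_ <- as.integer(table(factor(bg, levels = pts)))
  tibble::tibble(pt = pts, a = a, b = nrow(target_cases) - a,
                 c = c_, d = nrow(background_cases) - c_)
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' `ROR = (a d)/(b c)`; `CI = exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' With any zero cell the statistic is undefined and returned as `NA`
#' unless `correction = TRUE`, in which case the Haldane continuity
#' correction (0.5 added to every cell of affected tables) is applied.
#'
#' @param tab Tibble with columns `a`, `b`, `c`, `d` (one row per PT).
#' @param correction Apply the 0.5 continuity correction to tables with a
#'   zero cell.
#' @return `tab` with columns `ror`, `ror_ci_low`, `ror_ci_high` added.
#' @export
compute_ror <- function(tab, correction = FALSE) {
  a <- as.numeric(tab$a); b <- as.numeric(tab$b)
  c_ <- as.numeric(tab$c); d <- as.numeric(tab$d)
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  if (correction) {
    a <- ifelse(zero, a + 0.5, a); b <- ifelse(zero, b + 0.5, b)
    c_ <- ifelse(zero, c_ + 0.5, c_); d <- ifelse(zero, d + 0.5, d)
    zero <- rep(FALSE, length(a))
  }
  ror <- ifelse(zero, NA_real_, (a * d) / (b * c_))
  se <- ifelse(zero, NA_real_, sqrt(1 / a + 1 / b + 1 / c_ + 1 / d))
  tab$ror <- ror
  tab$ror_ci_low <- exp(log(ror) - 1.96 * se)
  tab$ror_ci_high <- exp(log(ror) + 1.96 * se)
  tab
}

#' Proportional reporting ratio with chi-square statistic
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the companion Pearson chi-square (no
#' continuity correction by default) is
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, which is zero exactly when
#' `ad = bc`. Undefined statistics (zero denominator, `c = 0`) are `NA`
#' unless a Yates-corrected chi-square is requested via `yates = TRUE`
#' (which subtracts `N/2` from `|ad - bc|`, floored at zero).
#'
#' @param tab Tibble with columns `a`, `b`, `c`, `d`.
#' @param yates Use the Yates continuity correction for the chi-square.
#' @return `tab` with columns `prr`, `chi2` added.
#' @export
compute_prr <- function(tab, yates = FALSE) {
  a <- as.numeric(tab$a); b <- as.numeric(tab$b)
  c_ <- as.numeric(tab$c); d <- as.numeric(tab$d)
  n <- a + b + c_ + d
  bad <- (a + b) == 0 | (c_ + d) == 0 | c_ == 0
  prr <- ifelse(bad, NA_real_, (a / (a + b)) / (c_ / (c_ + d)))
  margin <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  dev <- abs(a * d - b * c_)
  if (yates) dev <- pmax(dev - n / 2, 0)
  chi2 <- ifelse(margin == 0, NA_real_, n * dev^2 / margin)
  tab$prr <- prr
  tab$chi2 <- chi2
  tab
}

#' Per-PT disproportionality statistics for a target drug
#'
#' Builds the 2x2 table of every PT occurring in the target set against
#' the pooled background, computes ROR (with Wald 95% CI), PRR and
#' chi-square, and attaches the SOC from the supplied PT dictionary.
#'
#' @param target_cases,background_cases Disjoint case-level tibbles.
#' @param pt_dictionary Tibble `pt`, `soc` (optional; `NA` SOC otherwise).
#' @param correction,yates Passed to [compute_ror()] / [compute_prr()].
#' @return A tibble, one row per PT: `pt`, `soc`, `a`, `b`, `c`, `d`,
#'   `ror`, `ror_ci_low`, `ror_ci_high`, `prr`, `chi2`.
#' @export
disproportionality <- function(target_cases, background_cases,
                               pt_dictionary = NULL,
                               correction = FALSE, yates = FALSE) {
  stats <- contingency_counts(target_cases, background_cases) |>
    compute_ror(correction = correction) |>
    compute_prr(yates = yates)
  if (!is.null(pt_dictionary)) {
    stats <- dplyr::left_join(stats, pt_dictionary[c("pt", "soc")], by = "pt")
  } else {
    stats$soc <- NA_character_
  }
  dplyr::select(stats, "pt", "soc", dplyr::everything())
}

#' Signal-screening criteria
#'
#' Defaults: at least 3 reports; ROR 95% CI lower bound > 1; PRR > 2 with
#' chi-square >= 4. `combine` selects whether both methods must flag
#' (default), or only one of them.
#'
#' @param min_reports,ror_ci_low_gt,prr_gt,chi2_ge Thresholds.
#' @param combine `"both"`, `"ror_only"` or `"prr_only"`.
#' @return A `signal_criteria` list.
#' @export
signal_criteria <- function(min_reports = 3, ror_ci_low_gt = 1,
                            prr_gt = 2, chi2_ge = 4,
                            combine = c("both", "ror_only", "prr_only")) {
  combine <- match.arg(combine)
  if (any(c(min_reports, ror_ci_low_gt, prr_gt, chi2_ge) <= 0)) {
    rlang::abort("criteria thresholds must be positive",
                 class = "pvsignal_config_error")
  }
  structure(list(min_reports = min_reports, ror_ci_low_gt = ror_ci_low_gt,
                 prr_gt = prr_gt, chi2_ge = chi2_ge, combine = combine),
            class = "signal_criteria")
}

#' Flag signals under the screening criteria
#'
#' A PT is a signal when the report count and the enabled method criteria
#' all hold; undefined statistics (`NA`, from zero cells) never flag.
#'
#' @param stats Tibble from [disproportionality()].
#' @param criteria A [signal_criteria()].
#' @return `stats` with a logical `is_signal` column.
#' @export
screen_signals <- function(stats, criteria = signal_criteria()) {
  ror_ok <- !is.na(stats$ror_ci_low) & stats$ror_ci_low > criteria$ror_ci_low_gt
  prr_ok <- !is.na(stats$prr) & !is.na(stats$chi2) &
    stats$prr > criteria$prr_gt & stats$chi2 >= criteria$chi2_ge
  method_ok <- switch(criteria$combine,
                      both = ror_ok & prr_ok,
                      ror_only = ror_ok,
                      prr_only = prr_ok)
  stats$is_signal <- stats$a >= criteria$min_reports & method_ok
  stats
}

#' Partition flagged signals by product-label status
#'
#' Marks each flagged signal as labeled (PT present in the product-label
#' list) or unlabeled, and logs the partition counts.
#'
#' @param signals Screened stats tibble (uses rows with `is_signal`).
#' @param label_pt_list Character vector of labeled PTs.
#' @return The flagged subset with a logical `in_label` column.
#' @export
compare_with_label <- function(signals, label_pt_list) {
  flagged <- signals[signals$is_signal, ]
  flagged$in_label <- flagged$pt %in% label_pt_list
  pv_log("compare_with_label: %d signals, %d labeled, %d unlabeled",
         nrow(flagged), sum(flagged$in_label), sum(!flagged$in_label))
  flagged
}

#' Summary counts of the label comparison
#'
#' @param labeled_signals Result of [compare_with_label()].
#' @return One-row tibble: `n_signals`, `n_labeled`, `n_unlabeled`,
#'   `pct_unlabeled` (percentage of all signals).
#' @export
label_summary <- function(labeled_signals) {
  n <- nrow(labeled_signals)
  n_un <- sum(!labeled_signals$in_label)
  tibble::tibble(n_signals = n, n_labeled = n - n_un, n_unlabeled = n_un,
                 pct_unlabeled = if (n > 0) 100 * n_un / n else NA_real_)
}

#' Rank signals by report count or signal strength
#'
#' Stable descending order on the chosen key; ties broken by the other
#' key (descending) and then by PT string, so the order is deterministic.
#'
#' @param signals Stats tibble (typically the flagged subset).
#' @param key `"report_count"` (column `a`) or `"ror"`.
#' @param n Number of rows to keep (full list if larger).
#' @return The top-`n` rows.
#' @export
rank_signals <- function(signals, key = c("report_count", "ror"), n = 10) {
  key <- match.arg(key)
  ord <- if (key == "report_count") {
    order(-signals$a, -signals$ror, signals$pt)
  } else {
    order(-signals$ror, -signals$a, signals$pt)
  }
  head(signals[ord, ], n)
}

#' Reconstruct a 2x2 table from published disproportionality statistics
#'
#' Published signal tables print, per PT, the report count `a` and the
#' point estimates (ROR, PRR, chi-square) but not the underlying 2x2
#' table. Given those four numbers this audit tool solves the three
#' defining equations for the remaining cells `b`, `c`, `d`
#' (real-valued), enabling recomputation of any derived quantity such as
#' the ROR confidence interval. The solution uses the exact relation
#' `d = ROR * b * c / a` to eliminate `d`, then solves the PRR and
#' chi-square residuals for `(log b, log c)` by Newton iteration seeded
#' from a coarse grid search.
#'
#' @param a Report count (>= 1).
#' @param ror,prr Published point estimates (positive, `ror != prr`).
#' @param chi2 Published chi-square (> 0).
#' @param tol Relative tolerance on the recovered statistics.
#' @return One-row tibble with real-valued `a`, `b`, `c`, `d`.
#' @export
invert_stats <- function(a, ror, prr, chi2, tol = 1e-6) {
  if (a < 1 || ror <= 0 || prr <= 0 || chi2 <= 0) {
    rlang::abort("require a >= 1, ror > 0, prr > 0, chi2 > 0",
                 class = "pvsignal_input_error")
  }
  if (abs(log(ror / prr)) < 1e-12) {
    rlang::abort("ror and prr must differ to pin down the table",
                 class = "pvsignal_input_error")
  }
  d_of <- function(b, c_) ror * b * c_ / a
  resid <- function(lbc) {
    b <- exp(lbc[1]); c_ <- exp(lbc[2]); d <- d_of(b, c_)
    n <- a + b + c_ + d
    prr_hat <- (a / (a + b)) / (c_ / (c_ + d))
    chi2_hat <- n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
    c(log(prr_hat / prr), log(chi2_hat / chi2))
  }
  grid <- expand.grid(lb = log(a) + seq(-1, 14, length.out = 80),
                      lc = seq(0, 20, length.out = 80))
  ss <- vapply(seq_len(nrow(grid)),
               function(i) sum(resid(c(grid$lb[i], grid$lc[i]))^2), numeric(1))
  start <- c(grid$lb[which.min(ss)], grid$lc[which.min(ss)])
  sol <- tryCatch(pracma::fsolve(resid, start), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol$x)) || sum(resid(sol$x)^2) > tol^2) {
    rlang::abort(
      "no positive table reproduces the supplied statistics (inconsistent inputs)",
      class = "pvsignal_infeasible_error")
  }
  b <- exp(sol$x[1]); c_ <- exp(sol$x[2])
  tibble::tibble(a = a, b = b, c = c_, d = d_of(b, c_))
}

#' Volcano-style signal overview plot
#'
#' Scatter of log10 report count against log2 ROR, colored by signal
#' status, with the strongest signals labelled.
#'
#' @param stats Screened stats tibble (with `is_signal`).
#' @param label_top Number of PTs to label by ROR.
#' @return A ggplot object.
#' @export
plot_signals <- function(stats, label_top = 5) {
  df <- stats[!is.na(stats$ror), ]
  lab <- rank_signals(df[df$is_signal, ], key = "ror", n = label_top)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$a), y = log2(.data$ror),
                                   colour = .data$is_signal)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$pt),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "log10 reports with PT (a)", y = "log2 ROR",
                  colour = "signal") +
    ggplot2::theme_minimal()
}
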