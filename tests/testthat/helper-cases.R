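# Suppress per-stage filter logging during tests.
options(pvsignal.quiet = TRUE)

pts_or <- function(x, n, default) {
  if (is.null(x)) return(rep(list(default), n))
  if (!is.list(x)) x <- list(x)
  rep_len(x, n)
}

# Minimal case-tibble builder: every list-field defaults to one sensible
# value per case so individual tests only set what they exercise.
mk_cases <- function(caseid,
                     pts = NULL,
                     drugs = NULL,
                     outcomes = NULL,
                     gender = "female",
                     age_years = 60,
                     indications = NULL,
                     fda_dt = 20230101L) {
  n <- length(caseid)
  tibble::tibble(
    primaryid = as.integer(caseid) * 10L + 1L,
    caseid = as.integer(caseid),
    fda_dt = rep_len(fda_dt, n),
    age_years = rep_len(age_years, n),
    gender = rep_len(gender, n),
    occp_cod = rep_len("MD", n),
    reporter_country = rep_len("US", n),
    drugs = pts_or(drugs, n, tibble::tibble(drugname = "fulvestrant", role_cod = "PS")),
    pts = pts_or(pts, n, "Nausea"),
    outcomes = pts_or(outcomes, n, "OT"),
    indications = pts_or(indications, n, character())
  )
}

# disjoint target/background case sets realizing given 2x2 counts for one PT
mk_2x2_cases <- function(a, b, c, d, pt = "X") {
  list(
    target = mk_cases(seq_len(a + b),
                      pts = c(rep(list(c(pt, "Other")), a), rep(list("Other"), b))),
    background = mk_cases(a + b + seq_len(c + d),
                          pts = c(rep(list(pt), c), rep(list("Other"), d)))
  )
}

tab1 <- function(a, b, c, d) tibble::tibble(a = a, b = b, c = c, d = d)
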