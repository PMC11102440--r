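# Internal helpers shared across modules.

#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr across all_of anti_join arrange bind_rows case_when
#'   count desc distinct filter group_by if_else inner_join left_join
#'   mutate n pull rename row_number select semi_join slice slice_max
#'   summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis qlogis rbinom runif setNames glm binomial
#'   coef vcov pchisq quantile uniroot
#' @importFrom utils head
NULL

# Derive a reproducible substream seed from the global seed and a label.
# Each generator component seeds its own substream so that, e.g., adding
# quarters or changing the duplicate rate does not perturb the demographic
# draws. Kept strictly below 2^31 - 1.
substream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 99991
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}

# Filter-stage logging: every filter reports what it removed.
pv_log <- function(...) {
  if (isTRUE(getOption("pvsignal.quiet", FALSE))) return(invisible(NULL))
  rlang::inform(sprintf(...), class = "pvsignal_log")
}

assert_fraction <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) < 1 || any(is.na(x)) || any(x < 0) || !all(hi_ok)) {
    rlang::abort(sprintf("`%s` must be in [0, 1%s)", name, if (allow_one) "]" else ""),
                 class = "pvsignal_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) {
    rlang::abort(sprintf("`%s` must be a %s integer", name,
                         if (positive) "positive" else "non-negative"),
                 class = "pvsignal_config_error")
  }
  invisible(as.integer(x))
}
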