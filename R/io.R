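# Reading and writing FAERS-style $-delimited quarterly ASCII files.
#
# Dialect: one header row of upper-case column names, fields separated by
# "$", no quoting or escaping (a field containing "$" cannot be
# represented and is rejected at write time), blank fields are empty
# strings. Deleted-case lists are headerless, one CASEID per line.

TABLE_COLUMNS <- list(
  demo = c("primaryid", "caseid", "fda_dt", "age", "age_cod", "sex",
           "occp_cod", "reporter_country", "event_dt"),
  drug = c("primaryid", "caseid", "drugname", "role_cod"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  ther = c("primaryid", "caseid", "start_dt"),
  indi = c("primaryid", "caseid", "indi_pt")
)

TABLE_TYPES <- list(
  demo = c("i", "i", "i", "d", "c", "c", "c", "c", "i"),
  drug = c("i", "i", "c", "c"),
  reac = c("i", "i", "c"),
  outc = c("i", "i", "c"),
  ther = c("i", "i", "i"),
  indi = c("i", "i", "c")
)

quarter_file <- function(directory, table, quarter_label) {
  file.path(directory, paste0(toupper(table), quarter_label, ".txt"))
}

#' Write one quarter's tables as $-delimited ASCII files
#'
#' Writes `DEMO<q>.txt`, `DRUG<q>.txt`, `REAC<q>.txt`, `OUTC<q>.txt`,
#' `THER<q>.txt`, `INDI<q>.txt` and `DELETED<q>.txt` into `directory`.
#' Missing values are written as empty fields. A field containing the `$`
#' delimiter cannot be represented in this dialect and raises an error.
#' Reading the written files with [read_quarter()] reproduces the tables
#' field-for-field.
#'
#' @param tables Named list with elements `demo`, `drug`, `reac`, `outc`,
#'   `ther`, `indi` (tibbles) and `deleted` (integer CASEID vector), as
#'   produced by [generate_dataset()].
#' @param directory Output directory (created if absent).
#' @param quarter_label Quarter tag such as `"23Q1"`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_quarter_files <- function(tables, directory, quarter_label) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(paste0("cannot create directory: ", directory),
                          class = "pvsignal_io_error")
  }
  paths <- character()
  for (tab in names(TABLE_COLUMNS)) {
    df <- tables[[tab]]
    cols <- TABLE_COLUMNS[[tab]]
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols)) {
      rlang::abort(sprintf("table `%s` lacks columns: %s", tab,
                           paste(missing_cols, collapse = ", ")),
                   class = "pvsignal_io_error")
    }
    chr <- lapply(df[cols], function(x) {
      x <- as.character(x)
      x[is.na(x)] <- ""
      x
    })
    if (any(vapply(chr, function(x) any(grepl("$", x, fixed = TRUE)), logical(1)))) {
      rlang::abort(
        "field contains the `$` delimiter; not representable in this dialect",
        class = "pvsignal_io_error")
    }
    lines <- c(paste(toupper(cols), collapse = "$"),
               if (nrow(df)) do.call(paste, c(chr, sep = "$")))
    path <- quarter_file(directory, tab, quarter_label)
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  del_path <- quarter_file(directory, "deleted", quarter_label)
  writeLines(as.character(tables$deleted %||% integer()), del_path)
  invisible(c(paths, del_path))
}

parse_dollar_file <- function(path, table) {
  if (!file.exists(path)) {
    rlang::abort(paste0("missing mandatory file: ", path),
                 class = "pvsignal_ingest_error")
  }
  cols <- TABLE_COLUMNS[[table]]
  header <- tolower(strsplit(readLines(path, n = 1), "$", fixed = TRUE)[[1]])
  if (!setequal(header, cols)) {
    rlang::abort(sprintf("%s: expected columns %s, found %s", basename(path),
                         paste(cols, collapse = ","), paste(header, collapse = ",")),
                 class = "pvsignal_ingest_error")
  }
  # malformed rows are collected via problems() and skipped below
  res <- suppressWarnings(readr::read_delim(
    path, delim = "$", quote = "", na = "",
    col_types = paste(TABLE_TYPES[[table]][match(header, cols)], collapse = ""),
    col_names = header, skip = 1, progress = FALSE, lazy = FALSE
  ))
  probs <- readr::problems(res)
  if (nrow(probs)) {
    bad <- unique(probs$row)
    res <- res[-bad, ]
    pv_log("%s: skipped %d malformed row(s)", basename(path), length(bad))
  }
  res <- res[cols]
  pv_log("%s: %d rows parsed", basename(path), nrow(res))
  tibble::as_tibble(res)
}

#' Read one quarter's $-delimited tables
#'
#' Parses the DEMO/DRUG/REAC/OUTC/THER/INDI files for one quarter plus the
#' deleted-case list (absent list treated as empty). Blank fields are
#' preserved as `NA`; malformed rows are skipped with a logged count; row
#' counts are logged per file.
#'
#' @param directory Directory containing the quarter's files.
#' @param quarter_label Quarter tag such as `"23Q1"`.
#' @return A named list of tibbles (`demo`, `drug`, `reac`, `outc`,
#'   `ther`, `indi`) plus `deleted` (integer vector).
#' @export
read_quarter <- function(directory, quarter_label) {
  if (!dir.exists(directory)) {
    rlang::abort(paste0("no such directory: ", directory),
                 class = "pvsignal_ingest_error")
  }
  out <- lapply(names(TABLE_COLUMNS), function(tab) {
    parse_dollar_file(quarter_file(directory, tab, quarter_label), tab)
  })
  names(out) <- names(TABLE_COLUMNS)
  del_path <- quarter_file(directory, "deleted", quarter_label)
  out$deleted <- if (file.exists(del_path)) {
    lines <- readLines(del_path)
    as.integer(lines[nzchar(lines)])
  } else {
    integer()
  }
  out
}

#' Write a full generated dataset to disk
#'
#' Convenience wrapper applying [write_quarter_files()] to every quarter of
#' a [generate_dataset()] result, plus the ground-truth table as
#' tab-separated text.
#'
#' @param dataset Result of [generate_dataset()].
#' @param directory Output directory.
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, directory) {
  for (q in names(dataset$quarters)) {
    write_quarter_files(dataset$quarters[[q]], directory, q)
  }
  readr::write_tsv(dataset$ground_truth$true_ror,
                   file.path(directory, "ground_truth_ror.tsv"))
  invisible(directory)
}

#' Combine per-quarter tables into one multi-quarter table set
#'
#' Binds the quarters of a [generate_dataset()] result (or of repeated
#' [read_quarter()] calls) into single DEMO/DRUG/... tables, tagging demo
#' rows with their quarter label and pooling the deleted-case lists.
#'
#' @param quarters Named list of per-quarter table lists.
#' @return A list of pooled tibbles plus the pooled `deleted` vector.
#' @export
bind_quarters <- function(quarters) {
  out <- lapply(names(TABLE_COLUMNS), function(tab) {
    dplyr::bind_rows(lapply(names(quarters), function(q) {
      df <- quarters[[q]][[tab]]
      if (tab == "demo") df$quarter <- rep(q, nrow(df))
      df
    }))
  })
  names(out) <- names(TABLE_COLUMNS)
  out$deleted <- unlist(lapply(quarters, `[[`, "deleted"), use.names = FALSE)
  out
}

#' Read all quarters found in a directory
#'
#' Scans `directory` for `DEMO*.txt` files to discover quarter labels,
#' reads each quarter with [read_quarter()], and pools the result with
#' [bind_quarters()].
#'
#' @param directory Directory of quarterly files.
#' @return Pooled table list, as from [bind_quarters()].
#' @export
read_srs <- function(directory) {
  demo_files <- list.files(directory, pattern = "^DEMO.*\\.txt$")
  if (!length(demo_files)) {
    rlang::abort(paste0("no DEMO*.txt files found in ", directory),
                 class = "pvsignal_ingest_error")
  }
  labels <- sub("^DEMO(.*)\\.txt$", "\\1", demo_files)
  quarters <- lapply(labels, function(q) read_quarter(directory, q))
  names(quarters) <- labels
  bind_quarters(quarters)
}
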