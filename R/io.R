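# Long-format RT table I/O. One row = one trial: condition label, RT in ms.

#' Canonicalize condition labels
#'
#' Condition labels are order-insensitive sets of modality letters; the
#' canonical spellings are A, V, S, AV, VS, AS, AVS ("VA" becomes "AV",
#' "SA" becomes "AS", any permutation of the three letters becomes "AVS").
#'
#' @param x Character vector of labels.
#' @return Character vector of canonical labels.
#' @examples
#' canonicalize_condition(c("VA", "sa", "svA"))
#' @export
canonicalize_condition <- function(x) {
  key <- vapply(toupper(trimws(x)), function(lab) {
    paste(sort(strsplit(lab, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  lookup <- setNames(
    CONDITIONS,
    vapply(CONDITIONS,
           function(lab) paste(sort(strsplit(lab, "")[[1]]), collapse = ""),
           character(1)))
  out <- lookup[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(sprintf(
      "Unknown condition label(s): %s. Valid labels (any letter order): %s.",
      paste(bad, collapse = ", "), paste(CONDITIONS, collapse = ", ")))
  }
  unname(out)
}

# Internal: check/canonicalize a long-format condition table.
validate_study_table <- function(data) {
  if (!is.data.frame(data)) abort("Expected a data frame of trials.")
  if (!"rt_ms" %in% names(data) && "rt" %in% names(data)) {
    data <- dplyr::rename(data, rt_ms = "rt")
  }
  if (!all(c("condition", "rt_ms") %in% names(data))) {
    abort("The table needs `condition` and `rt_ms` columns.")
  }
  data$condition <- canonicalize_condition(data$condition)
  if (!is.numeric(data$rt_ms)) abort("`rt_ms` must be numeric (ms).")
  tibble::as_tibble(data)
}

#' Read and write long-format reaction-time tables
#'
#' The interchange format is comma-separated UTF-8 text with a header; one
#' row per trial with columns `condition` (label in A, V, S, AV, VS, AS,
#' AVS, any letter order) and `rt_ms` (positive, milliseconds); optional
#' `trial` and `architecture`/`source` columns pass through. On read, rows
#' with missing or non-positive RT are dropped with a message; unknown
#' condition labels are an error.
#'
#' @param path File path.
#' @param data Table to write (columns as above).
#' @return `read_rt_csv()` returns a validated tibble; `write_rt_csv()`
#'   returns `data` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_rt_csv(simulate_superposition(trimodal_config(n = 20)), f)
#' read_rt_csv(f)
#' @export
read_rt_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(data) == 0L) abort(sprintf("No trials found in '%s'.", path))
  if (!"rt_ms" %in% names(data) && "rt" %in% names(data)) {
    data <- dplyr::rename(data, rt_ms = "rt")
  }
  if (!all(c("condition", "rt_ms") %in% names(data))) {
    abort("The file needs `condition` and `rt_ms` (or `rt`) columns.")
  }
  rt <- suppressWarnings(as.numeric(data$rt_ms))
  keep <- !is.na(rt) & rt > 0
  if (any(!keep)) {
    inform(sprintf("Dropped %d row(s) with missing or non-positive RT.",
                   sum(!keep)))
    data <- data[keep, , drop = FALSE]
    rt <- rt[keep]
  }
  if (nrow(data) == 0L) abort(sprintf("No usable trials in '%s'.", path))
  data$rt_ms <- rt
  validate_study_table(data)
}

#' @rdname read_rt_csv
#' @export
write_rt_csv <- function(data, path) {
  data <- validate_study_table(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Read and write flat simulation config files
#'
#' Plain-text `key = value` lines with keys `c` (threshold), `lambda_A`,
#' `lambda_V`, `lambda_S` (rates per ms), `n`, `seed`, `r_AV`, `r_AS`,
#' `r_VS` (target latency correlations) and optionally `architecture`
#' (`race` or `superposition`). Lines starting with `#` are comments.
#'
#' @param path File path.
#' @param config A [trimodal_config()].
#' @param architecture Optional architecture tag to record.
#' @return `read_sim_config()` returns a list with elements `config` (a
#'   [trimodal_config()]) and `architecture` (string or `NULL`).
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(sprintf("Malformed config line: '%s'.", lines[bad][1]))
  vals <- setNames(vapply(kv, `[[`, character(1), 2L),
                   vapply(kv, `[[`, character(1), 1L))
  num <- function(key, default) {
    if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  }
  cfg <- trimodal_config(
    shape = num("c", 2),
    rates = c(A = num("lambda_A", 0.01), V = num("lambda_V", 0.01),
              S = num("lambda_S", 0.01)),
    n = num("n", 2000),
    seed = num("seed", 1),
    correlation = correlation_matrix(num("r_AV", 0), num("r_AS", 0),
                                     num("r_VS", 0)))
  list(config = cfg,
       architecture = if ("architecture" %in% names(vals)) vals[["architecture"]])
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path, architecture = NULL) {
  stopifnot(inherits(config, "trimodal_config"))
  lines <- c(
    sprintf("c = %d", config$shape),
    sprintf("lambda_A = %.10g", config$rates[["A"]]),
    sprintf("lambda_V = %.10g", config$rates[["V"]]),
    sprintf("lambda_S = %.10g", config$rates[["S"]]),
    sprintf("n = %d", config$n),
    sprintf("seed = %d", config$seed),
    sprintf("r_AV = %.10g", config$correlation["A", "V"]),
    sprintf("r_AS = %.10g", config$correlation["A", "S"]),
    sprintf("r_VS = %.10g", config$correlation["V", "S"]))
  if (!is.null(architecture)) {
    lines <- c(lines, sprintf("architecture = %s", architecture))
  }
  writeLines(lines, path)
  invisible(path)
}
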