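#' Read and write scoresheet CSVs
#'
#' The scoresheet format is one CSV row per participant: `id`, `age`,
#' `education_years`, `sex` (F/M), then for each line id in
#' [gvt_line_ids()] a pair `<line>_ok` (0/1) and `<line>_time` (seconds,
#' blank unless the line was followed correctly). UTF-8, dot decimal
#' separator.
#'
#' @param path Path to a CSV file.
#' @return `read_scoresheet()`: a validated scoresheet tibble (the
#'   `education_years` column is renamed `education` internally).
#' @export
read_scoresheet <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("education_years" %in% names(data)) {
    data <- dplyr::rename(data, education = "education_years")
  }
  if (nrow(data) > 0) {
    data$id <- as.character(data$id)
    for (col in time_cols()) data[[col]] <- as.numeric(data[[col]])
    for (col in ok_cols()) data[[col]] <- as.integer(data[[col]])
    check_cohort(data)
  }
  data
}

#' @rdname read_scoresheet
#' @param data A scoresheet tibble.
#' @export
write_scoresheet <- function(data, path) {
  check_cohort(data)
  out <- dplyr::rename(data, education_years = "education")
  keep <- c("id", "age", "education_years", "sex",
            as.vector(rbind(ok_cols(), time_cols())))
  out <- out[intersect(keep, names(out))]
  write_atomic(readr::format_csv(out), path)
  invisible(path)
}

#' Write scored results
#'
#' Serialises the output of [gvt_score()] to CSV or JSON (chosen from the
#' file extension), atomically.
#'
#' @param scored A `gvt_scored` tibble.
#' @param path Output path ending in `.csv` or `.json`.
#' @export
write_scored <- function(scored, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write_atomic(readr::format_csv(scored), path)
  } else if (ext == "json") {
    json <- jsonlite::toJSON(as.data.frame(scored), pretty = TRUE,
                             auto_unbox = TRUE, digits = NA, na = "null",
                             dataframe = "rows")
    write_atomic(paste0(json, "\n"), path)
  } else {
    stop("unsupported output format: .", ext)
  }
  invisible(path)
}
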