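#' Line identifiers of the GVT
#'
#' The test consists of two cards (A, B) of five intertwined lines each
#' (A--E). Identifiers are `"<card>_<line>"`, ordered card A lines A--E then
#' card B lines A--E.
#'
#' @return Character vector of the 10 line identifiers.
#' @export
#' @examples
#' gvt_line_ids()
gvt_line_ids <- function() {
  c(paste0("A_", LETTERS[1:5]), paste0("B_", LETTERS[1:5]))
}

ok_cols <- function() paste0(gvt_line_ids(), "_ok")
time_cols <- function() paste0(gvt_line_ids(), "_time")

#' Round half away from zero
#'
#' Commercial rounding used throughout the published scoring tables
#' (e.g. a mean adjusted time of 21.35 s is reported as 21.4).
#' `base::round()` rounds half to even and would give 21.4 only by accident
#' of floating point.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the precision of all
#'   published tables).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Age decades covered by the norms, with their representative midpoints
age_band_table <- function() {
  tibble::tibble(
    age_band = paste(seq(20, 70, 10), seq(29, 79, 10), sep = "-"),
    lower = seq(20, 70, 10),
    upper = seq(29, 79, 10),
    midpoint = seq(24.5, 74.5, 10)
  )
}

# Education bands of the published grid with their representative values.
# The >13 representative 17 corresponds to a completed university degree.
education_band_table <- function() {
  tibble::tibble(
    education_band = c("0-5", "6-8", "9-13", ">13"),
    lower = c(0, 6, 9, 14),
    upper = c(5, 8, 13, Inf),
    representative = c(2.5, 7, 11, 17)
  )
}

#' Map ages and education to normative bands
#'
#' @param age Numeric vector of ages in years.
#' @return `age_band()`: character vector of decade labels ("20-29" ...
#'   "70-79"); ages outside 20--79 are clamped to the nearest band.
#' @export
age_band <- function(age) {
  tab <- age_band_table()
  idx <- findInterval(pmin(pmax(age, 20), 79), tab$lower)
  tab$age_band[idx]
}

#' @rdname age_band
#' @param education Numeric vector of education in years of schooling.
#' @return `education_band()`: character vector of band labels
#'   ("0-5", "6-8", "9-13", ">13").
#' @export
education_band <- function(education) {
  tab <- education_band_table()
  idx <- findInterval(pmax(education, 0), tab$lower)
  tab$education_band[idx]
}

age_midpoint <- function(age) {
  tab <- age_band_table()
  tab$midpoint[match(age_band(age), tab$age_band)]
}

education_representative <- function(education) {
  tab <- education_band_table()
  tab$representative[match(education_band(education), tab$education_band)]
}

# Normalise sex coding to the numeric 0/1 used by the adjustment models
# (F = 0, M = 1).
sex_code <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) stop("numeric sex must be coded 0 (F) / 1 (M)")
    return(as.numeric(sex))
  }
  s <- toupper(as.character(sex))
  if (!all(s %in% c("F", "M"))) stop("sex must be 'F' or 'M' (or 0/1)")
  as.numeric(s == "M")
}

# Validate a scoresheet/cohort tibble: one row per participant, with
# demographics plus <line>_ok / <line>_time pairs for all 10 lines.
check_cohort <- function(data) {
  need <- c("id", "age", "education", "sex", ok_cols(), time_cols())
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("scoresheet is missing columns: ", paste(missing, collapse = ", "))
  }
  ok <- as.matrix(data[ok_cols()])
  tm <- as.matrix(data[time_cols()])
  if (any(!ok %in% c(0, 1, NA))) stop("*_ok columns must be 0/1")
  bad <- (ok %in% 1) & (is.na(tm) | tm <= 0)
  if (any(bad)) stop("correct lines must carry a positive execution time")
  extra <- (!ok %in% 1) & !is.na(tm)
  if (any(extra)) stop("incorrect lines must not carry an execution time")
  invisible(data)
}

# Long view of the per-line outcomes: id, line_id, ok, time_s
cohort_long <- function(data) {
  ids <- gvt_line_ids()
  purrr::map_dfr(ids, function(l) {
    tibble::tibble(
      id = data$id,
      line_id = l,
      ok = as.integer(data[[paste0(l, "_ok")]]),
      time_s = as.numeric(data[[paste0(l, "_time")]])
    )
  }) |>
    dplyr::arrange(match(id, data$id), match(line_id, ids))
}
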