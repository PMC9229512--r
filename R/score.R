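#' Per-line scoring primitives
#'
#' `score_accuracy()` counts the lines followed correctly (0--10).
#' `apply_line_corrections()` adds the line-uniformization correction to
#' each valid execution time. `mean_corrected_time()` averages the adjusted
#' times over valid lines, rounded half away from zero to 1 decimal (the
#' precision of the published scoring examples); participants with no valid
#' line have no time score.
#'
#' @param data A scoresheet tibble: one row per participant with columns
#'   `id`, `age`, `education`, `sex` and, for each line id in
#'   [gvt_line_ids()], `<line>_ok` (0/1) and `<line>_time` (seconds, `NA`
#'   unless correct).
#' @return `score_accuracy()`: integer vector, one value per row.
#' @export
score_accuracy <- function(data) {
  check_cohort(data)
  as.integer(rowSums(as.matrix(data[ok_cols()]) == 1, na.rm = TRUE))
}

#' @rdname score_accuracy
#' @param corrections A line-correction table: tibble with columns
#'   `line_id` and `correction_s` covering all 10 lines.
#' @return `apply_line_corrections()`: a long tibble `id`, `line_id`,
#'   `time_adj_s` with one row per valid line.
#' @export
apply_line_corrections <- function(data, corrections) {
  check_cohort(data)
  corrections <- tibble::as_tibble(corrections)
  missing <- setdiff(gvt_line_ids(), corrections$line_id)
  if (length(missing) > 0) {
    stop("correction table is missing lines: ",
         paste(missing, collapse = ", "))
  }
  cohort_long(data) |>
    dplyr::filter(.data$ok == 1) |>
    dplyr::left_join(corrections, by = "line_id") |>
    dplyr::mutate(time_adj_s = .data$time_s + .data$correction_s) |>
    dplyr::select("id", "line_id", "time_adj_s")
}

#' @rdname score_accuracy
#' @param adjusted Output of `apply_line_corrections()`.
#' @param ids Participant ids to report (defaults to those present in
#'   `adjusted`); participants with zero valid lines get `NA`.
#' @return `mean_corrected_time()`: a tibble `id`, `mean_corrected_time_s`.
#' @export
mean_corrected_time <- function(adjusted, ids = unique(adjusted$id)) {
  means <- adjusted |>
    dplyr::summarise(m = mean(.data$time_adj_s), .by = "id")
  tibble::tibble(id = ids) |>
    dplyr::left_join(means, by = "id") |>
    dplyr::mutate(mean_corrected_time_s = round_half_away(.data$m, 1)) |>
    dplyr::select("id", "mean_corrected_time_s")
}

#' Score GVT scoresheets against a norm set
#'
#' The full clinical scoring pipeline: raw accuracy, line-uniformized
#' execution times, mean corrected time, demographic adjustments (banded by
#' default, matching the published correction grids), corrected values,
#' percentile, equivalent score and tolerance-limit classification for both
#' measures. Participants with zero correct lines receive an accuracy
#' result only; their time measure is not assessable and is reported `NA`.
#'
#' Ages outside the 20--79 normative range are scored against the nearest
#' band and flagged in the `extrapolated` column (with a warning).
#'
#' @param data A scoresheet tibble (see [score_accuracy()]); [read_scoresheet()]
#'   produces this layout from the standard CSV.
#' @param norms A `gvt_norms` object (default: the published adult norms).
#' @param mode `"banded"` (default; uses age-decade midpoints and education
#'   band representatives, reproducing the published grids) or `"exact"`
#'   (continuous age and education in the adjustment equations).
#' @return A tibble, one row per participant, with the raw and corrected
#'   measures, adjustments, percentile labels, equivalent scores (0--4) and
#'   classifications; class `gvt_scored`.
#' @export
#' @examples
#' sheet <- tibble::tibble(
#'   id = "ex2", age = 23, education = 13, sex = "M",
#'   A_A_ok = 1, A_A_time = 12.8, A_B_ok = 0, A_B_time = NA,
#'   A_C_ok = 0, A_C_time = NA, A_D_ok = 0, A_D_time = NA,
#'   A_E_ok = 0, A_E_time = NA, B_A_ok = 1, B_A_time = 12.7,
#'   B_B_ok = 0, B_B_time = NA, B_C_ok = 0, B_C_time = NA,
#'   B_D_ok = 1, B_D_time = 14.4, B_E_ok = 0, B_E_time = NA
#' )
#' gvt_score(sheet)
gvt_score <- function(data, norms = gvt_published_norms(),
                      mode = c("banded", "exact")) {
  mode <- match.arg(mode)
  check_cohort(data)
  stopifnot(inherits(norms, "gvt_norms"))

  extrapolated <- data$age < 20 | data$age > 79
  if (any(extrapolated)) {
    warning(sum(extrapolated), " participant(s) outside the 20-79 normative",
            " age range; scored against the nearest band (extrapolation)")
  }

  raw_accuracy <- score_accuracy(data)
  adjusted <- apply_line_corrections(data, norms$line_corrections)
  times <- mean_corrected_time(adjusted, ids = data$id)

  adj_acc <- demographic_adjustment(norms$models$accuracy, data$age,
                                    data$education, data$sex, mode = mode)
  adj_time <- demographic_adjustment(norms$models$time, data$age,
                                     data$education, data$sex, mode = mode)

  # both addends carry 1 decimal; re-round only to drop floating-point dust
  corrected_accuracy <- round_half_away(raw_accuracy + adj_acc, 1)
  mean_time <- times$mean_corrected_time_s
  corrected_time <- ifelse(raw_accuracy >= 1,
                           round_half_away(mean_time + adj_time, 1), NA_real_)

  sc_acc <- norms$scales$accuracy
  sc_time <- norms$scales$time
  p_acc <- to_percentile(corrected_accuracy, sc_acc)
  p_time <- to_percentile(corrected_time, sc_time)

  out <- tibble::tibble(
    id = data$id,
    age = data$age,
    education = data$education,
    sex = as.character(data$sex),
    raw_accuracy = raw_accuracy,
    mean_corrected_time = mean_time,
    correction_accuracy = adj_acc,
    correction_time = ifelse(raw_accuracy >= 1, adj_time, NA_real_),
    corrected_accuracy = corrected_accuracy,
    corrected_time = corrected_time,
    percentile_accuracy = p_acc$label,
    percentile_time = p_time$label,
    es_accuracy = to_es(corrected_accuracy, sc_acc),
    es_time = to_es(corrected_time, sc_time),
    class_accuracy = classify_score(corrected_accuracy, sc_acc),
    class_time = classify_score(corrected_time, sc_time),
    extrapolated = extrapolated
  )
  class(out) <- c("gvt_scored", class(out))
  out
}
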