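#' Demographic adjustment models
#'
#' An adjustment model removes the estimated effect of age, education and
#' sex from a raw GVT measure. Each term is a transformed predictor with a
#' (sign-reversed) regression coefficient and a centering constant equal to
#' the normative-sample mean of the transformed predictor, so that the
#' adjustment is exactly zero for a participant at the sample-average
#' demographic profile.
#'
#' The published accuracy adjustment is
#' `0.000597 (Age^2 - 2365.458) + 16.77 (1/Education - 0.0818) - 0.455 (Sex - 0.445)`
#' (sex coded F = 0, M = 1) and the published execution-time adjustment is
#' `4.364 (ln(86.9 - Age) - 3.7)`.
#'
#' @param terms A tibble with columns `predictor` ("age", "education",
#'   "sex"), `family` (a [transform_families()] name), `k`, `s` (transform
#'   constants, `NA` where unused), `coefficient` and `center`.
#' @param measure `"accuracy"` or `"time"`.
#' @param stats Optional named list of fit statistics (e.g. `r_squared`,
#'   `n`) carried along for [generics::glance()].
#' @return A `gvt_adjustment` object.
#' @export
adjustment_model <- function(terms, measure = c("accuracy", "time"),
                             stats = list()) {
  measure <- match.arg(measure)
  terms <- tibble::as_tibble(terms)
  need <- c("predictor", "family", "k", "s", "coefficient", "center")
  if (!all(need %in% names(terms))) {
    stop("terms must have columns ", paste(need, collapse = ", "))
  }
  if (!all(terms$predictor %in% c("age", "education", "sex"))) {
    stop("predictors must be age, education or sex")
  }
  structure(list(terms = terms, measure = measure, stats = stats),
            class = "gvt_adjustment")
}

#' Evaluate a demographic adjustment
#'
#' Computes the signed correction to add to a raw measure, either at the
#' participant's exact demographics (`mode = "exact"`) or at the band
#' representatives used by the published correction grids
#' (`mode = "banded"`: age mapped to its decade midpoint 24.5 ... 74.5,
#' education to its band representative 2.5 / 7 / 11 / 17). Banded mode is
#' the default because all published worked examples and grids use it.
#'
#' @param model A [adjustment_model()].
#' @param age,education Numeric vectors (years). Education may be omitted
#'   when the model has no education term.
#' @param sex `"F"`/`"M"` or 0/1 (F = 0, M = 1); optional when unused.
#' @param mode `"banded"` (default) or `"exact"`.
#' @param round If `TRUE` (default) round the final adjustment half away
#'   from zero to 1 decimal, the precision of the published grids.
#'   Intermediates are never rounded.
#' @return Numeric vector of signed adjustments.
#' @export
#' @examples
#' m <- published_accuracy_model()
#' demographic_adjustment(m, age = 48, education = 17, sex = "F")  # -0.4
demographic_adjustment <- function(model, age, education = NULL, sex = NULL,
                                   mode = c("banded", "exact"), round = TRUE) {
  stopifnot(inherits(model, "gvt_adjustment"))
  mode <- match.arg(mode)
  n <- length(age)
  vals <- list(
    age = if (mode == "banded") age_midpoint(age) else as.numeric(age),
    education = if (is.null(education)) NULL else if (mode == "banded") {
      education_representative(education)
    } else as.numeric(education),
    sex = if (is.null(sex)) NULL else sex_code(sex)
  )
  adj <- numeric(n)
  for (i in seq_len(nrow(model$terms))) {
    tm <- model$terms[i, ]
    x <- vals[[tm$predictor]]
    if (is.null(x)) stop("model needs predictor '", tm$predictor, "'")
    spec <- transform_spec(tm$family, k = tm$k, s = tm$s)
    adj <- adj + tm$coefficient * (transform_eval(spec, x) - tm$center)
  }
  if (round) round_half_away(adj, 1) else adj
}

#' Published adjustment models
#'
#' Convenience constructors for the published accuracy and execution-time
#' adjustment equations (see [adjustment_model()] for the formulas).
#'
#' @return A `gvt_adjustment`.
#' @export
published_accuracy_model <- function() {
  adjustment_model(
    tibble::tibble(
      predictor = c("age", "education", "sex"),
      family = c("quadratic", "inverse", "linear"),
      k = NA_real_, s = NA_real_,
      coefficient = c(0.000597, 16.77, -0.455),
      center = c(2365.458, 0.0818, 0.445)
    ),
    measure = "accuracy",
    stats = list(adj_r_squared = 0.194, n = 526)
  )
}

#' @rdname published_accuracy_model
#' @export
published_time_model <- function() {
  adjustment_model(
    tibble::tibble(
      predictor = "age",
      family = "logarithmic_reverse",
      k = 86.9, s = NA_real_,
      coefficient = 4.364,
      center = 3.7
    ),
    measure = "time",
    stats = list(r_squared = 0.07, n = 526)
  )
}

#' @export
print.gvt_adjustment <- function(x, ...) {
  cat("<gvt_adjustment> measure:", x$measure, "\n")
  trs <- purrr::pmap_chr(x$terms, function(predictor, family, k, s,
                                           coefficient, center) {
    spec <- transform_spec(family, k = k, s = s)
    sprintf("%+.6g * (%s - %.6g)", coefficient,
            sub("x", predictor, format(spec), fixed = TRUE), center)
  })
  cat("  adjustment =", paste(trs, collapse = " "), "\n")
  invisible(x)
}

#' Tidy a demographic adjustment model
#'
#' @param x A `gvt_adjustment`.
#' @param ... Unused.
#' @return `tidy()`: one row per model term (predictor, transform family,
#'   constants, coefficient, centering constant). `glance()`: a one-row
#'   tibble of fit statistics.
#' @exportS3Method generics::tidy
tidy.gvt_adjustment <- function(x, ...) {
  x$terms
}

#' @rdname tidy.gvt_adjustment
#' @exportS3Method generics::glance
glance.gvt_adjustment <- function(x, ...) {
  st <- x$stats
  tibble::as_tibble(c(list(measure = x$measure),
                      st[vapply(st, is.numeric, logical(1))]))
}
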