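#' Demographic design table of the normative study
#'
#' Joint counts of the normative cohort over age decade, education band and
#' sex (n = 526). Used as the default sampling frame for synthetic cohorts.
#'
#' @return A tibble with columns `age_band`, `education_band`, `sex`, `n`.
#' @export
gvt_demographics_table <- function() {
  decades <- age_band_table()$age_band
  bands <- education_band_table()$education_band
  # counts per (decade, sex), ordered 0-5, 6-8, 9-13, >13
  counts <- list(
    "20-29" = list(F = c(0, 0, 16, 47), M = c(0, 0, 12, 27)),
    "30-39" = list(F = c(0, 3, 18, 33), M = c(0, 6, 20, 21)),
    "40-49" = list(F = c(0, 5, 21, 29), M = c(1, 5, 16, 24)),
    "50-59" = list(F = c(0, 11, 26, 21), M = c(0, 10, 19, 14)),
    "60-69" = list(F = c(0, 11, 21, 8), M = c(1, 6, 15, 8)),
    "70-79" = list(F = c(4, 9, 6, 3), M = c(2, 12, 9, 6))
  )
  tidyr::expand_grid(age_band = decades, sex = c("F", "M"),
                     education_band = bands) |>
    dplyr::mutate(n = purrr::pmap_dbl(
      list(.data$age_band, .data$sex, .data$education_band),
      function(a, s, e) counts[[a]][[s]][match(e, bands)]
    ))
}

#' Synthetic cohort configuration
#'
#' Defines the generating distributions for a synthetic normative cohort
#' with the demographic and performance structure the analysis assumes:
#'
#' * demographics drawn from the joint age-decade x education-band x sex
#'   design table of the normative study (ages uniform within decade,
#'   education uniform in integer years within band);
#' * per-line correctness Bernoulli, with line-specific base rates equal to
#'   the published per-line valid proportions, shifted by a participant
#'   term that is linear in the transformed demographics (the published
#'   accuracy-equation pattern with reversed sign, i.e. the raw-score
#'   effect) plus a latent ability factor;
#' * execution times log-normal around a participant-level mean that
#'   follows the published time-equation pattern, with additive per-line
#'   offsets (the published line means minus their grand mean), a shared
#'   participant speed factor, and truncation bounds;
#' * optionally, a proportion of participants receive one inflated
#'   "restart" time (uniform in `outlier_range`), emulating the extreme
#'   outliers the filtering step removes.
#'
#' Effect coefficients are expressed on the measure scale (expected
#' raw-score change per unit of transformed predictor); their sign-reversed
#' values are the generating adjustment equations returned by
#' [true_adjustments()].
#'
#' @param n Number of participants.
#' @param accuracy_effects Named list `age`, `education`, `sex`, each a list
#'   with a [transform_spec()] (`transform`), `coefficient` (measure
#'   scale) and `center`.
#' @param time_effects Same structure for the time measure (default: age
#'   only).
#' @param accuracy_base Expected accuracy at the centered demographics
#'   (default: sum of the published per-line valid proportions).
#' @param line_valid_props Named per-line success probabilities at the
#'   centered demographics.
#' @param ability_sd SD of the participant latent ability factor, in
#'   accuracy points (default 1.5, matching the published accuracy SDs of
#'   2.2--2.8 within decades).
#' @param time_base Grand-mean execution time in seconds.
#' @param line_time_offsets Named per-line additive offsets (seconds) of
#'   the expected times around `time_base`.
#' @param sigma_participant,sigma_line Log-scale SDs of the shared
#'   participant speed factor and the per-line residual (defaults 0.30 and
#'   0.28, matching the published per-line coefficients of variation of
#'   about 0.44).
#' @param time_bounds Truncation bounds in seconds for regular times.
#' @param outlier_rate Proportion of participants given one inflated time.
#' @param outlier_range Range of the inflated times in seconds.
#' @return A `gvt_cohort_config` list.
#' @export
cohort_config <- function(n = 526,
                          accuracy_effects = default_accuracy_effects(),
                          time_effects = default_time_effects(),
                          accuracy_base = NULL,
                          line_valid_props = default_line_valid_props(),
                          ability_sd = 1.5,
                          time_base = 21.99,
                          line_time_offsets = default_line_time_offsets(),
                          sigma_participant = 0.30,
                          sigma_line = 0.28,
                          time_bounds = c(5, 77.5),
                          outlier_rate = 0,
                          outlier_range = c(80, 150)) {
  if (is.null(accuracy_base)) accuracy_base <- sum(line_valid_props)
  stopifnot(n >= 0, length(line_valid_props) == 10,
            length(line_time_offsets) == 10,
            time_bounds[1] > 0, time_bounds[2] <= 200,
            outlier_rate >= 0, outlier_rate <= 1)
  structure(list(
    n = n,
    demographics = gvt_demographics_table(),
    accuracy_effects = accuracy_effects,
    time_effects = time_effects,
    accuracy_base = accuracy_base,
    line_valid_props = line_valid_props,
    ability_sd = ability_sd,
    time_base = time_base,
    line_time_offsets = line_time_offsets,
    sigma_participant = sigma_participant,
    sigma_line = sigma_line,
    time_bounds = time_bounds,
    outlier_rate = outlier_rate,
    outlier_range = outlier_range
  ), class = "gvt_cohort_config")
}

# Raw-score effect patterns mirroring the published adjustment equations
# (reversed sign: the adjustment ADDS what the demographic effect removes).
#' @rdname cohort_config
#' @export
default_accuracy_effects <- function() {
  list(
    age = list(transform = transform_spec("quadratic"),
               coefficient = -0.000597, center = 2365.458),
    education = list(transform = transform_spec("inverse"),
                     coefficient = -16.77, center = 0.0818),
    sex = list(transform = transform_spec("linear"),
               coefficient = 0.455, center = 0.445)
  )
}

#' @rdname cohort_config
#' @export
default_time_effects <- function() {
  list(
    age = list(transform = transform_spec("logarithmic_reverse", k = 86.9),
               coefficient = -4.364, center = 3.7)
  )
}

# Published per-line valid counts out of 526
default_line_valid_props <- function() {
  stats::setNames(
    c(354, 317, 268, 255, 392, 369, 336, 386, 302, 231) / 526,
    gvt_line_ids()
  )
}

# Published per-line mean times minus their grand mean (21.99 s)
default_line_time_offsets <- function() {
  means <- c(18.3, 22.9, 28.7, 22.9, 19.4, 16.4, 20.7, 21.3, 23.6, 25.7)
  stats::setNames(means - mean(means), gvt_line_ids())
}

effect_sum <- function(effects, age, education, sex01) {
  vals <- list(age = age, education = education, sex = sex01)
  total <- 0
  for (p in names(effects)) {
    e <- effects[[p]]
    total <- total + e$coefficient *
      (transform_eval(e$transform, vals[[p]]) - e$center)
  }
  total
}

#' Generate a synthetic GVT cohort
#'
#' Draws a reproducible scoresheet cohort from a [cohort_config()]. Same
#' seed, same cohort.
#'
#' @param config A `gvt_cohort_config`.
#' @param seed Integer seed for all randomness.
#' @return A scoresheet tibble (one row per participant; the layout
#'   accepted by [gvt_score()] and [derive_norms()]), with attributes
#'   `seed` and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50), seed = 1)
#' mean(cohort$age)
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "gvt_cohort_config"))
  demo_tab <- config$demographics
  if (nrow(demo_tab) == 0 || sum(demo_tab$n) == 0) {
    stop("empty demographic table")
  }
  set.seed(as.integer(seed))
  n <- config$n
  ids <- gvt_line_ids()

  cell <- sample(nrow(demo_tab), n, replace = TRUE, prob = demo_tab$n)
  ab <- age_band_table()[match(demo_tab$age_band[cell],
                               age_band_table()$age_band), ]
  age <- ab$lower + sample.int(10, n, replace = TRUE) - 1L
  eb <- demo_tab$education_band[cell]
  edu_range <- list("0-5" = 3:5, "6-8" = 6:8, "9-13" = 9:13, ">13" = 14:18)
  education <- vapply(eb, function(b) {
    r <- edu_range[[b]]
    r[sample.int(length(r), 1)]
  }, integer(1))
  sex <- demo_tab$sex[cell]
  sex01 <- sex_code(sex)

  # accuracy: participant mean shifted by demographics + latent ability,
  # spread over lines around the published per-line base rates
  mu <- config$accuracy_base +
    effect_sum(config$accuracy_effects, age, education, sex01) +
    stats::rnorm(n, 0, config$ability_sd)
  base_p <- config$line_valid_props[ids]
  ok <- matrix(0L, n, 10, dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    p <- pmin(pmax(base_p[j] + (mu - config$accuracy_base) / 10, 0.02), 0.98)
    ok[, j] <- stats::rbinom(n, 1, p)
  }

  # times: log-normal around participant mean + line offset
  m_i <- config$time_base + effect_sum(config$time_effects, age, education,
                                       sex01)
  eta <- stats::rnorm(n, 0, config$sigma_participant)
  tm <- matrix(NA_real_, n, 10, dimnames = list(NULL, ids))
  s2 <- config$sigma_participant^2 + config$sigma_line^2
  for (j in seq_along(ids)) {
    mean_j <- pmax(m_i + config$line_time_offsets[ids[j]], 6)
    t_j <- mean_j * exp(eta + stats::rnorm(n, 0, config$sigma_line) - s2 / 2)
    t_j <- pmin(pmax(t_j, config$time_bounds[1]), config$time_bounds[2])
    tm[, j] <- ifelse(ok[, j] == 1, round(t_j, 1), NA_real_)
  }

  out <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    age = as.integer(age),
    education = as.integer(education),
    sex = sex
  )
  for (j in seq_along(ids)) {
    out[[paste0(ids[j], "_ok")]] <- ok[, j]
    out[[paste0(ids[j], "_time")]] <- tm[, j]
  }

  if (config$outlier_rate > 0 && n > 0) {
    hit <- which(stats::runif(n) < config$outlier_rate)
    out <- plant_outliers(out, hit, config$outlier_range)
  }
  attr(out, "seed") <- as.integer(seed)
  attr(out, "config") <- config
  out
}

# Give each listed participant one inflated time on a random valid line
# (participants with no valid line get line A of card A marked valid).
plant_outliers <- function(data, rows, range = c(80, 150)) {
  ids <- gvt_line_ids()
  for (i in rows) {
    valid <- ids[vapply(ids, function(l) data[[paste0(l, "_ok")]][i] == 1,
                        logical(1))]
    if (length(valid) == 0) {
      l <- ids[1]
      data[[paste0(l, "_ok")]][i] <- 1L
    } else {
      l <- valid[sample.int(length(valid), 1)]
    }
    data[[paste0(l, "_time")]][i] <- round(stats::runif(1, range[1], range[2]), 1)
  }
  data
}

#' Plant a fixed number of extreme outliers in a cohort
#'
#' Deterministically (given `seed`) inflates one execution time for each of
#' `n_offenders` distinct participants, giving filter tests a known ground
#' truth.
#'
#' @param data A scoresheet tibble.
#' @param n_offenders Number of participants to contaminate.
#' @param seed Integer seed.
#' @param range Range of the inflated times in seconds.
#' @return The modified scoresheet tibble.
#' @export
inject_outliers <- function(data, n_offenders, seed = 1L,
                            range = c(80, 150)) {
  check_cohort(data)
  stopifnot(n_offenders <= nrow(data))
  set.seed(as.integer(seed))
  rows <- sample.int(nrow(data), n_offenders)
  plant_outliers(data, rows, range)
}

#' Generating adjustment models of a synthetic configuration
#'
#' Re-expresses the generating effects as adjustment models (reversed
#' coefficients), directly comparable with what [derive_norms()] or
#' [fit_adjustment_model()] recover from a generated cohort.
#'
#' @param config A `gvt_cohort_config`.
#' @return Named list of `gvt_adjustment` objects (`accuracy`, `time`).
#' @export
true_adjustments <- function(config) {
  stopifnot(inherits(config, "gvt_cohort_config"))
  as_model <- function(effects, measure) {
    adjustment_model(
      tibble::tibble(
        predictor = names(effects),
        family = unname(vapply(effects, function(e) e$transform$family,
                               character(1))),
        k = unname(vapply(effects, function(e) e$transform$k, numeric(1))),
        s = unname(vapply(effects, function(e) e$transform$s, numeric(1))),
        coefficient = -unname(vapply(effects, function(e) e$coefficient,
                                     numeric(1))),
        center = unname(vapply(effects, function(e) e$center, numeric(1)))
      ),
      measure = measure,
      stats = list(source = "generating")
    )
  }
  list(accuracy = as_model(config$accuracy_effects, "accuracy"),
       time = as_model(config$time_effects, "time"))
}
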