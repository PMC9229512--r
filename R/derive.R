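#' Extreme-outlier threshold and case-wise filtering
#'
#' The outlier threshold pools every valid execution time over all
#' participants and lines and takes `Q3 + multiplier * IQR` (default 3, the
#' extreme-outlier convention), with quartiles computed by linear
#' interpolation between order statistics (`stats::quantile()` type 7).
#' Filtering is case-wise: a participant with any valid time at or above
#' the threshold is removed entirely.
#'
#' @param data A scoresheet tibble (see [score_accuracy()]).
#' @param multiplier IQR multiplier (default 3).
#' @return `outlier_threshold()`: the threshold in seconds.
#' @export
outlier_threshold <- function(data, multiplier = 3) {
  check_cohort(data)
  times <- cohort_long(data) |>
    dplyr::filter(.data$ok == 1) |>
    dplyr::pull("time_s")
  if (length(times) < 4) stop("need at least 4 recorded times")
  q <- stats::quantile(times, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + multiplier * (q[2] - q[1])
}

#' @rdname outlier_threshold
#' @param threshold Threshold in seconds; the comparison is `>=` (a time
#'   exactly at the threshold removes the participant).
#' @return `filter_outlier_cases()`: the filtered scoresheet tibble.
#' @export
filter_outlier_cases <- function(data, threshold) {
  check_cohort(data)
  stopifnot(threshold > 0)
  offenders <- cohort_long(data) |>
    dplyr::filter(.data$ok == 1, .data$time_s >= threshold) |>
    dplyr::pull("id") |>
    unique()
  dplyr::filter(data, !.data$id %in% offenders)
}

#' Line-uniformization correction factors
#'
#' For each of the 10 lines, the correction is the grand mean of the
#' per-line mean execution times minus that line's mean (i.e. the
#' line-vs-grand-mean difference with reversed sign). Adding the unrounded
#' corrections makes every line's mean adjusted time equal to the grand
#' mean exactly, and the corrections sum to zero. The published clinical
#' table is the same quantity rounded to 1 decimal.
#'
#' @param data A scoresheet tibble.
#' @param digits Optional rounding of the corrections (`NULL`, the default,
#'   keeps them unrounded; the published table uses `digits = 1`).
#' @return A tibble `line_id`, `correction_s`.
#' @export
line_correction_factors <- function(data, digits = NULL) {
  check_cohort(data)
  means <- cohort_long(data) |>
    dplyr::filter(.data$ok == 1) |>
    dplyr::summarise(m = mean(.data$time_s), n = dplyr::n(), .by = "line_id")
  missing <- setdiff(gvt_line_ids(), means$line_id)
  if (length(missing) > 0) {
    stop("no valid times for line(s): ", paste(missing, collapse = ", "))
  }
  line_means_correction(means$m[match(gvt_line_ids(), means$line_id)], digits)
}

# Corrections from a vector of 10 per-line means (exposed for recomputing
# the published table from printed summary statistics).
line_means_correction <- function(line_means, digits = NULL) {
  stopifnot(length(line_means) == length(gvt_line_ids()))
  corr <- mean(line_means) - line_means
  if (!is.null(digits)) corr <- round_half_away(corr, digits)
  tibble::tibble(line_id = gvt_line_ids(), correction_s = corr)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 LL + 2K + 2K(K + 1)/(n - K - 1)`, where `K` counts all
#' estimated parameters (regression coefficients plus the residual
#' variance).
#'
#' @param log_likelihood Model log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Number of observations (must exceed `K + 1`).
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-1209.8, K = 5, n = 526)
aicc <- function(log_likelihood, K, n) {
  if (any(n <= K + 1)) stop("AICc requires n > K + 1")
  -2 * log_likelihood + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

# delta to the best AICc; exact ties (including the degenerate perfect-fit
# case where every AICc is -Inf) count as delta 0
delta_from_best <- function(a) {
  ifelse(a == a[1], 0, a - a[1])
}

aicc_lm <- function(fit) {
  # a numerically perfect fit has an unbounded likelihood; report -Inf so
  # that perfect fits tie exactly and the deterministic tie-break applies
  scale <- max(1, mean(abs(stats::fitted(fit))))
  if (summary(fit)$sigma < 1e-10 * scale) return(-Inf)
  K <- length(stats::coef(fit)) + 1  # + residual variance
  aicc(as.numeric(stats::logLik(fit)), K, stats::nobs(fit))
}

#' Transformation search for one predictor
#'
#' Fits a bivariate ordinary-least-squares regression of the response on
#' each candidate transformation of the predictor and ranks the
#' transformations by AICc (ascending). Families not applicable to the
#' predictor's range (e.g. the logarithm of a non-positive value) are
#' skipped with a warning. For the reverse families the shift constant `k`
#' is chosen by grid search over `max(x) + 1 ... max(x) + k_grid_max`,
#' keeping the AICc-best value. Ties (within floating-point resolution) are
#' broken by the fixed family order of [transform_families()].
#'
#' @param x Predictor values.
#' @param y Response values (same length, at least 10).
#' @param families Character vector of families to try.
#' @param k_grid_max Width of the reverse-shift grid (default 20).
#' @return A tibble ranked by AICc with columns `family`, `k`, `s`,
#'   `aicc`, `delta_aicc`, `r_squared` and a list column `transform` of
#'   [transform_spec()] objects.
#' @export
fit_transformations <- function(x, y, families = transform_families(),
                                k_grid_max = 20) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  families <- match.arg(families, transform_families(), several.ok = TRUE)
  rows <- list()
  for (fam in families) {
    if (!transform_applicable(fam, x)) {
      warning("skipping transformation '", fam,
              "': not applicable to the predictor's range")
      next
    }
    if (fam %in% c("reverse", "logarithmic_reverse")) {
      ks <- max(x) + seq_len(k_grid_max)
      best <- NULL
      for (k in ks) {
        spec <- transform_spec(fam, k = k)
        fit <- stats::lm(y ~ t, data = data.frame(y = y,
                                                  t = transform_eval(spec, x)))
        a <- aicc_lm(fit)
        if (is.null(best) || a < best$aicc - 1e-12) {
          best <- list(spec = spec, fit = fit, aicc = a)
        }
      }
      spec <- best$spec; fit <- best$fit; a <- best$aicc
    } else {
      spec <- if (fam == "exponential") {
        transform_spec(fam, s = diff(range(x)) / 10)
      } else transform_spec(fam)
      fit <- stats::lm(y ~ t, data = data.frame(y = y,
                                                t = transform_eval(spec, x)))
      a <- aicc_lm(fit)
    }
    rows[[fam]] <- tibble::tibble(
      family = fam, k = spec$k, s = spec$s, aicc = a,
      r_squared = summary(fit)$r.squared,
      transform = list(spec)
    )
  }
  if (length(rows) == 0) stop("no applicable transformation family")
  out <- dplyr::bind_rows(rows)
  # stable sort: AICc ascending, ties by fixed family order
  out <- out[order(round(out$aicc, 8),
                   match(out$family, transform_families())), ]
  out$delta_aicc <- delta_from_best(out$aicc)
  dplyr::relocate(out, "delta_aicc", .after = "aicc")
}

#' AICc model comparison table
#'
#' Ranks a set of candidate models fitted on the same observations by
#' AICc and reports the standard comparison columns: delta AICc, relative
#' model likelihood `exp(-delta/2)`, normalized Akaike weights, cumulative
#' weights and log-likelihood.
#'
#' @param fits Named list of `lm` fits (names are the model labels).
#' @return A tibble sorted by AICc ascending with columns `model`, `K`,
#'   `aicc`, `delta_aicc`, `model_lik`, `weight`, `log_lik`, `cum_weight`;
#'   class `gvt_model_comparison`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  ns <- vapply(fits, stats::nobs, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("all candidate models must be fitted on the same observations")
  }
  out <- tibble::tibble(
    model = names(fits),
    K = unname(vapply(fits, function(f) length(stats::coef(f)) + 1,
                      numeric(1))),
    log_lik = unname(vapply(fits, function(f) as.numeric(stats::logLik(f)),
                            numeric(1))),
    aicc = unname(vapply(fits, aicc_lm, numeric(1)))
  )
  out <- out[order(round(out$aicc, 8), out$K, seq_len(nrow(out))), ]
  out$delta_aicc <- delta_from_best(out$aicc)
  out$model_lik <- exp(-out$delta_aicc / 2)
  out$weight <- out$model_lik / sum(out$model_lik)
  out$cum_weight <- cumsum(out$weight)
  out <- dplyr::select(out, "model", "K", "aicc", "delta_aicc",
                       "model_lik", "weight", "log_lik", "cum_weight")
  class(out) <- c("gvt_model_comparison", class(out))
  out
}

# The 7 non-empty predictor subsets, in the conventional order
predictor_subsets <- function(predictors = c("age", "education", "sex")) {
  subsets <- list()
  for (size in rev(seq_along(predictors))) {
    combos <- utils::combn(predictors, size, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  subsets
}

#' Fit a demographic adjustment model from a cohort
#'
#' Regresses the measure on the centered transformed predictors (each
#' transform evaluated at the participant's demographics, minus its sample
#' mean -- the centering constant) and reverses the coefficient signs, so
#' that adding the resulting adjustment to a raw score removes the
#' estimated demographic effect. By construction the mean adjustment over
#' the fitting cohort is zero.
#'
#' @param demo A tibble with columns `age`, `education`, `sex` and the
#'   measure values in `value` (rows with `NA` values are dropped).
#' @param measure `"accuracy"` or `"time"`.
#' @param transforms Named list mapping each included predictor to a
#'   [transform_spec()].
#' @return A `gvt_adjustment` with sign-reversed coefficients, centering
#'   constants, and fit statistics (`r_squared`, `n`, `sigma`, coefficient
#'   standard errors in `stats$se`).
#' @export
fit_adjustment_model <- function(demo, measure = c("accuracy", "time"),
                                 transforms) {
  measure <- match.arg(measure)
  stopifnot(all(c("age", "education", "sex", "value") %in% names(demo)))
  demo <- demo[!is.na(demo$value), ]
  preds <- names(transforms)
  stopifnot(length(preds) >= 1, all(preds %in% c("age", "education", "sex")))
  raw <- list(age = as.numeric(demo$age),
              education = as.numeric(demo$education),
              sex = sex_code(demo$sex))
  design <- lapply(preds, function(p) transform_eval(transforms[[p]], raw[[p]]))
  names(design) <- preds
  centers <- vapply(design, mean, numeric(1))
  centered <- as.data.frame(lapply(preds, function(p) design[[p]] - centers[p]))
  names(centered) <- preds
  centered$value <- demo$value
  fit <- stats::lm(value ~ ., data = centered)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design: predictors ",
         paste(preds, collapse = ", "), " are collinear after transformation")
  }
  beta <- stats::coef(fit)[preds]
  se <- summary(fit)$coefficients[preds, "Std. Error"]
  adjustment_model(
    tibble::tibble(
      predictor = preds,
      family = unname(vapply(transforms, function(t) t$family, character(1))),
      k = unname(vapply(transforms, function(t) t$k, numeric(1))),
      s = unname(vapply(transforms, function(t) t$s, numeric(1))),
      coefficient = -unname(beta),
      center = unname(centers)
    ),
    measure = measure,
    stats = list(r_squared = summary(fit)$r.squared,
                 sigma = summary(fit)$sigma,
                 n = stats::nobs(fit),
                 se = unname(se),
                 intercept = unname(stats::coef(fit)[1]))
  )
}

#' Build a banded correction grid from an adjustment model
#'
#' Evaluates [demographic_adjustment()] in banded mode over every
#' combination of the bands the model's predictors span: age decades
#' 20--29 ... 70--79, the four education bands, and both sexes. Models
#' without education or sex terms yield correspondingly smaller grids
#' (e.g. the published time model gives one row per age decade).
#'
#' @param model A `gvt_adjustment`.
#' @return A tibble with one rounded correction per cell (columns among
#'   `age_band`, `education_band`, `sex`, plus `correction`).
#' @export
build_correction_grid <- function(model) {
  preds <- model$terms$predictor
  cells <- list(age_band = age_band_table()$age_band)
  if ("education" %in% preds) {
    cells$education_band <- education_band_table()$education_band
  }
  if ("sex" %in% preds) cells$sex <- c("F", "M")
  grid <- tidyr::expand_grid(!!!cells)
  ages <- age_band_table()$midpoint[match(grid$age_band,
                                          age_band_table()$age_band)]
  edus <- if ("education" %in% preds) {
    education_band_table()$representative[match(grid$education_band,
                                                education_band_table()$education_band)]
  } else NULL
  sexes <- if ("sex" %in% preds) grid$sex else NULL
  grid$correction <- demographic_adjustment(model, ages, edus, sexes,
                                            mode = "exact")
  grid
}

#' Minimum sample size for a multiple-regression power target
#'
#' Smallest total N at which the F test of a multiple regression with `u`
#' predictors, significance level `alpha`, and Cohen effect size `f2`
#' reaches the target power, using the noncentral-F power function with
#' noncentrality `f2 * N` and denominator degrees of freedom `N - u - 1`.
#'
#' @param u Number of predictors (numerator df).
#' @param f2 Cohen's effect size f-squared.
#' @param alpha Significance level.
#' @param power Target power.
#' @param n_max Search bound (error if the target is not reached below it).
#' @return Integer minimum N.
#' @export
#' @examples
#' power_min_n(u = 3, f2 = 0.04)  # 277
power_min_n <- function(u = 3, f2 = 0.04, alpha = 0.05, power = 0.80,
                        n_max = 100000L) {
  stopifnot(u >= 1, f2 > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  pow <- function(n) {
    v <- n - u - 1
    1 - stats::pf(stats::qf(1 - alpha, u, v), u, v, ncp = f2 * n)
  }
  for (n in seq(u + 3, n_max)) {
    if (pow(n) >= power) return(as.integer(n))
  }
  stop("target power not reachable below n = ", n_max)
}

#' Derive a complete norm set from a cohort
#'
#' Re-runs the full norm-derivation pipeline on a scoresheet cohort:
#' case-wise extreme-outlier filtering; line-uniformization corrections;
#' per-participant mean corrected times; per-predictor transformation
#' search (AICc); AICc comparison of the 7 predictor subsets;
#' deviation-from-mean adjustment regression with reversed coefficients;
#' banded correction grids; and, on the corrected scores, one-sided
#' non-parametric tolerance limits, percentile tables and rank-based
#' equivalent-score bands for both measures.
#'
#' Corrected scores used for the scales are computed in exact mode
#' (continuous demographics, unrounded adjustments); the clinical tables in
#' the returned norms are rounded to 1 decimal.
#'
#' @param data A scoresheet tibble.
#' @param outlier_multiplier IQR multiplier for the extreme-outlier
#'   threshold (default 3).
#' @param threshold Optional fixed outlier threshold in seconds. By default
#'   the threshold is recomputed from the pooled execution times of `data`;
#'   passing the threshold recorded in an earlier derivation makes
#'   re-derivation on already-filtered data exactly idempotent (a
#'   recomputed quantile-based threshold can otherwise trim a few further
#'   cases).
#' @param coverage,conf Tolerance-interval coverage and confidence
#'   (default 0.95 / 0.95).
#' @param es_props ES cumulative cut proportions (default 0.20/0.35/0.50).
#' @param families Transformation families searched per predictor.
#' @param seed Optional integer recorded in the metadata (for synthetic
#'   cohorts).
#' @return A `gvt_norms` object; the extra element `derivation` holds the
#'   outlier threshold, counts, the transformation-search and
#'   model-comparison tables per measure.
#' @export
derive_norms <- function(data, outlier_multiplier = 3, threshold = NULL,
                         coverage = 0.95, conf = 0.95,
                         es_props = c(0.20, 0.35, 0.50),
                         families = transform_families(),
                         seed = NULL) {
  check_cohort(data)

  if (is.null(threshold)) {
    threshold <- outlier_threshold(data, outlier_multiplier)
  }
  kept <- filter_outlier_cases(data, threshold)
  n <- nrow(kept)
  if (n < min_n_tolerance(coverage, conf)) {
    stop("cohort too small after filtering (n = ", n, "): at least ",
         min_n_tolerance(coverage, conf), " participants are needed for a ",
         coverage * 100, "/", conf * 100, " one-sided tolerance limit")
  }

  corrections <- line_correction_factors(kept)        # unrounded
  adjusted <- apply_line_corrections(kept, corrections)
  mean_times <- adjusted |>
    dplyr::summarise(value = mean(.data$time_adj_s), .by = "id")

  base <- tibble::tibble(id = kept$id, age = kept$age,
                         education = kept$education, sex = kept$sex)
  measures <- list(
    accuracy = dplyr::mutate(base, value = as.numeric(score_accuracy(kept))),
    time = dplyr::left_join(base, mean_times, by = "id")
  )

  derivation <- list(outlier_threshold = threshold,
                     n_enrolled = nrow(data), n_kept = n)
  models <- list(); scales <- list()
  for (ms in c("accuracy", "time")) {
    demo <- measures[[ms]]
    fitdat <- demo[!is.na(demo$value), ]
    raw <- list(age = as.numeric(fitdat$age),
                education = as.numeric(fitdat$education),
                sex = sex_code(fitdat$sex))

    # best transformation per predictor (sex is binary: linear by definition)
    search <- list()
    best_tr <- list()
    for (p in c("age", "education")) {
      tab <- fit_transformations(raw[[p]], fitdat$value, families = families)
      search[[p]] <- dplyr::select(tab, -"transform")
      best_tr[[p]] <- tab$transform[[1]]
    }
    best_tr$sex <- transform_spec("linear")

    # AICc comparison of the 7 predictor subsets
    fits <- list()
    for (subset in predictor_subsets()) {
      dd <- as.data.frame(lapply(subset, function(p) {
        transform_eval(best_tr[[p]], raw[[p]])
      }))
      names(dd) <- subset
      dd$value <- fitdat$value
      fits[[paste(subset, collapse = " + ")]] <-
        stats::lm(value ~ ., data = dd)
    }
    comparison <- compare_models(fits)
    best_label <- comparison$model[1]
    best_preds <- strsplit(best_label, " \\+ ")[[1]]

    model <- fit_adjustment_model(fitdat, measure = ms,
                                  transforms = best_tr[best_preds])

    direction <- if (ms == "accuracy") "higher_better" else "lower_better"
    corrected <- demo$value +
      demographic_adjustment(model, demo$age, demo$education, demo$sex,
                             mode = "exact", round = FALSE)
    corrected <- corrected[!is.na(corrected)]
    tol <- tolerance_limits(corrected, direction, coverage, conf)
    scales[[ms]] <- list(
      measure = ms,
      direction = direction,
      tolerance = round_half_away(tol, 1),
      percentiles = percentile_table(corrected, direction = direction),
      es_bands = es_bands(corrected, tol[["outer"]], direction,
                          props = es_props),
      grid = build_correction_grid(model)
    )
    models[[ms]] <- model
    derivation[[ms]] <- list(transformation_search = search,
                             model_comparison = comparison,
                             selected_model = best_label)
  }

  norms <- gvt_norms(
    line_corrections = line_correction_factors(kept, digits = 1),
    models = models,
    scales = scales,
    metadata = list(source = "derived", cohort_n = n,
                    outlier_threshold = threshold,
                    seed = seed,
                    created = format(Sys.Date()))
  )
  norms$derivation <- derivation
  norms
}
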