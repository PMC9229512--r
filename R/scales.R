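#' Non-parametric one-sided tolerance ranks
#'
#' Order-statistic ranks, counted from the impaired tail, bracketing the
#' population quantile that leaves proportion `coverage` of the population
#' on the healthy side, with confidence `conf`. The outer rank `r` is the
#' largest rank whose order statistic is a one-sided tolerance bound, i.e.
#' the largest `r` with `P[Bin(n, 1 - coverage) <= r - 1] <= 1 - conf`; the
#' inner rank `s` is the smallest rank with
#' `P[Bin(n, 1 - coverage) < s] >= conf` (an upper confidence bound on the
#' same population quantile). Scores beyond the outer limit are classed
#' impaired, scores between the two limits uncertain.
#'
#' For the default 95/95 specification a valid outer rank first exists at
#' `n = 59` (since 0.95^59 < 0.05 but 0.95^58 > 0.05).
#'
#' @param n Sample size.
#' @param coverage Population proportion to cover (default 0.95).
#' @param conf Confidence level (default 0.95).
#' @return A list with integer elements `outer` and `inner`.
#' @export
#' @examples
#' tolerance_ranks(59)   # outer = 1
#' tolerance_ranks(526)  # the normative-sample ranks
tolerance_ranks <- function(n, coverage = 0.95, conf = 0.95) {
  stopifnot(coverage > 0, coverage < 1, conf > 0, conf < 1, n >= 1)
  p <- 1 - coverage
  r <- seq_len(n)
  ok_outer <- stats::pbinom(r - 1, n, p) <= 1 - conf
  if (!any(ok_outer)) {
    stop("no valid tolerance limit exists at n = ", n,
         " for coverage ", coverage, " and confidence ", conf,
         " (minimum n is ", min_n_tolerance(coverage, conf), ")")
  }
  outer <- max(r[ok_outer])
  ok_inner <- stats::pbinom(r - 1, n, p) >= conf
  inner <- min(r[ok_inner])
  list(outer = outer, inner = inner)
}

# Smallest n at which an outer tolerance rank exists: coverage^n <= 1 - conf
min_n_tolerance <- function(coverage = 0.95, conf = 0.95) {
  ceiling(log(1 - conf) / log(coverage))
}

#' One-sided non-parametric tolerance limits
#'
#' Takes the order statistics at the [tolerance_ranks()] from the impaired
#' tail of a vector of corrected scores: the lower tail for measures where
#' higher is better (accuracy), the upper tail for measures where lower is
#' better (execution time). The outer limit is always the more extreme of
#' the two.
#'
#' @param scores Numeric vector of corrected scores.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @inheritParams tolerance_ranks
#' @return Named numeric vector `c(outer = , inner = )`.
#' @export
tolerance_limits <- function(scores, direction = c("higher_better",
                                                   "lower_better"),
                             coverage = 0.95, conf = 0.95) {
  direction <- match.arg(direction)
  scores <- scores[!is.na(scores)]
  rk <- tolerance_ranks(length(scores), coverage, conf)
  sorted <- sort(scores, decreasing = (direction == "lower_better"))
  c(outer = sorted[rk$outer], inner = sorted[rk$inner])
}

#' Empirical percentile table for corrected scores
#'
#' Quantiles of the corrected-score distribution at the clinically reported
#' levels, oriented so that a higher percentile always means better
#' performance: for time-like measures level `l` maps to the `(100 - l)`-th
#' quantile of the scores.
#'
#' @param scores Numeric vector of corrected scores.
#' @param levels Percentile levels (default the published layout
#'   1--5, 10, 15, ..., 95, 99).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param digits Rounding of the tabulated values (default 1 decimal).
#' @return A tibble with columns `level` and `value`, ordered by level.
#' @export
percentile_table <- function(scores,
                             levels = c(1:5, seq(10, 95, 5), 99),
                             direction = c("higher_better", "lower_better"),
                             digits = 1) {
  direction <- match.arg(direction)
  scores <- scores[!is.na(scores)]
  stopifnot(length(scores) > 0)
  p <- if (direction == "higher_better") levels / 100 else 1 - levels / 100
  v <- stats::quantile(scores, p, type = 7, names = FALSE)
  tibble::tibble(level = as.numeric(levels),
                 value = round_half_away(v, digits)) |>
    dplyr::arrange(level)
}

#' Rank-based equivalent-score bands
#'
#' Partitions the corrected-score line into the five equivalent-score (ES)
#' bands used in neuropsychological norms: ES0 is beyond the outer
#' tolerance limit, ES4 is better than the sample median, and ES1--ES3
#' split the region in between at the 20% and 35% cumulative ranks counted
#' from the impaired tail.
#'
#' @param scores Numeric vector of corrected scores.
#' @param outer_limit The outer tolerance limit (ES0 boundary).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param props Cumulative cut proportions for the ES1/2, ES2/3 and ES3/4
#'   boundaries (default `c(0.20, 0.35, 0.50)`).
#' @param digits Rounding of the band edges (default 1 decimal).
#' @return A tibble with columns `es`, `lower`, `upper`, `lower_inc`,
#'   `upper_inc` describing five contiguous half-open intervals covering
#'   the real line.
#' @export
es_bands <- function(scores, outer_limit,
                     direction = c("higher_better", "lower_better"),
                     props = c(0.20, 0.35, 0.50), digits = 1) {
  direction <- match.arg(direction)
  stopifnot(length(props) == 3, all(diff(props) > 0))
  scores <- scores[!is.na(scores)]
  p <- if (direction == "higher_better") props else 1 - props
  cuts <- round_half_away(stats::quantile(scores, p, type = 7, names = FALSE),
                          digits)
  b <- c(round_half_away(outer_limit, digits), cuts)
  if (direction == "higher_better") {
    # impaired tail is low: ES0 (-Inf, b1], ES1 (b1, b2], ..., ES4 (b4, Inf)
    tibble::tibble(
      es = 0:4,
      lower = c(-Inf, b),
      upper = c(b, Inf),
      lower_inc = c(FALSE, rep(FALSE, 4)),
      upper_inc = c(rep(TRUE, 4), FALSE)
    )
  } else {
    # impaired tail is high: ES0 [b1, Inf), ES1 [b2, b1), ..., ES4 (-Inf, b4)
    tibble::tibble(
      es = 0:4,
      lower = c(b, -Inf),
      upper = c(Inf, b),
      lower_inc = c(rep(TRUE, 4), FALSE),
      upper_inc = c(FALSE, rep(FALSE, 4))
    )
  }
}

# --- lookups on published / derived scales ---------------------------------

#' Equivalent score of a corrected value
#'
#' @param corrected Numeric vector of corrected scores.
#' @param scale A per-measure scale list (element of `norms$scales`), as
#'   shipped in the published norms or built by [derive_norms()].
#' @return Integer vector of equivalent scores 0--4.
#' @export
#' @examples
#' norms <- gvt_published_norms()
#' to_es(c(9.6, 1.8), norms$scales$accuracy)  # 4, 1
to_es <- function(corrected, scale) {
  bands <- scale$es_bands
  vapply(corrected, function(x) {
    if (is.na(x)) return(NA_integer_)
    for (i in seq_len(nrow(bands))) {
      lo_ok <- if (bands$lower_inc[i]) x >= bands$lower[i] else x > bands$lower[i]
      hi_ok <- if (bands$upper_inc[i]) x <= bands$upper[i] else x < bands$upper[i]
      if (lo_ok && hi_ok) return(as.integer(bands$es[i]))
    }
    stop("ES bands do not cover the value ", x)
  }, integer(1))
}

#' Percentile of a corrected value
#'
#' Looks a corrected score up in the tabulated percentile scale. A score
#' equal to a tabulated value returns that level; a score strictly between
#' two rows returns the bracketing pair (reported as e.g. `"70-75"`, the
#' style of the published worked examples); scores beyond the table
#' extremes are reported as `"<1"` or `">99"`.
#'
#' @param corrected Numeric vector of corrected scores.
#' @param scale A per-measure scale list (element of `norms$scales`).
#' @return A tibble with columns `level_low`, `level_high` and `label`.
#' @export
#' @examples
#' norms <- gvt_published_norms()
#' to_percentile(6.3, norms$scales$accuracy)   # exactly the 50th
#' to_percentile(17.7, norms$scales$time)      # between the 70th and 75th
to_percentile <- function(corrected, scale) {
  ptab <- scale$percentiles
  higher_better <- scale$direction == "higher_better"
  one <- function(x) {
    if (is.na(x)) {
      return(tibble::tibble(level_low = NA_real_, level_high = NA_real_,
                            label = NA_character_))
    }
    # performance score: larger = better, regardless of measure direction
    perf <- if (higher_better) x else -x
    vals <- if (higher_better) ptab$value else -ptab$value
    lv <- ptab$level[order(vals)]
    vals <- sort(vals)
    eq <- which(abs(vals - perf) < 1e-9)
    if (length(eq) > 0) {
      l <- max(lv[eq])
      return(tibble::tibble(level_low = l, level_high = l,
                            label = format_level(l)))
    }
    below <- which(vals < perf)
    if (length(below) == 0) {
      return(tibble::tibble(level_low = NA_real_, level_high = min(lv),
                            label = paste0("<", format_level(min(lv)))))
    }
    if (length(below) == length(vals)) {
      return(tibble::tibble(level_low = max(lv), level_high = NA_real_,
                            label = paste0(">", format_level(max(lv)))))
    }
    lo <- lv[max(below)]
    hi <- lv[max(below) + 1]
    tibble::tibble(level_low = lo, level_high = hi,
                   label = paste0(format_level(lo), "-", format_level(hi)))
  }
  purrr::map_dfr(corrected, one)
}

format_level <- function(l) format(l, trim = TRUE)

#' Classify a corrected score against the tolerance limits
#'
#' @param corrected Numeric vector of corrected scores.
#' @param scale A per-measure scale list (element of `norms$scales`).
#' @return Character vector: `"impaired"` (at or beyond the outer limit,
#'   toward the impaired tail), `"uncertain"` (between the outer and inner
#'   limits) or `"normal-range"`.
#' @export
classify_score <- function(corrected, scale) {
  outer <- scale$tolerance[["outer"]]
  inner <- scale$tolerance[["inner"]]
  if (scale$direction == "higher_better") {
    dplyr::case_when(
      is.na(corrected) ~ NA_character_,
      corrected <= outer ~ "impaired",
      corrected <= inner ~ "uncertain",
      TRUE ~ "normal-range"
    )
  } else {
    dplyr::case_when(
      is.na(corrected) ~ NA_character_,
      corrected >= outer ~ "impaired",
      corrected >= inner ~ "uncertain",
      TRUE ~ "normal-range"
    )
  }
}
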