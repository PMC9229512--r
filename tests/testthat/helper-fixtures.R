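# Fixtures built in code: the two published worked examples and small
# hand-made scoresheets.

make_record <- function(id, age, education, sex, ok, times) {
  ids <- gvt_line_ids()
  d <- tibble::tibble(id = id, age = age, education = education, sex = sex)
  for (j in seq_along(ids)) {
    d[[paste0(ids[j], "_ok")]] <- as.integer(ok[j])
    d[[paste0(ids[j], "_time")]] <- ifelse(ok[j] == 1, times[j], NA_real_)
  }
  d
}

# Worked example 1: 48-year-old woman, university education, all 10 correct
example1_record <- function() {
  make_record("ex1", 48, 17, "F", rep(1L, 10),
              c(19.4, 21.0, 33.9, 23.9, 18.4, 16.5, 13.3, 19.7, 20.3, 19.7))
}

# Worked example 2: 23-year-old man, 13 years of education, 3 correct lines
example2_record <- function() {
  make_record("ex2", 23, 13, "M",
              c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L, 0L),
              c(12.8, NA, NA, NA, NA, 12.7, NA, NA, 14.4, NA))
}

# The first-correction values as printed in the worked examples (card B
# line E appears there as +3.7, where the published correction table has
# -3.7; the examples' own arithmetic follows +3.7).
example_corrections <- function() {
  tibble::tibble(
    line_id = gvt_line_ids(),
    correction_s = c(3.6, -0.9, -6.7, -0.9, 2.6, 5.7, 1.3, 0.7, -1.7, 3.7)
  )
}

published_norms <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gvt_published_norms()
    cache
  }
})

# Published norms with the worked examples' printed correction values
example_norms <- function() {
  norms <- published_norms()
  norms$line_corrections <- example_corrections()
  norms
}

# Per-line mean execution times as published for the normative cohort
published_line_means <- function() {
  c(18.3, 22.9, 28.7, 22.9, 19.4, 16.4, 20.7, 21.3, 23.6, 25.7)
}

# (log-likelihood, K, printed AICc) pairs of the published accuracy and
# time model-comparison tables, n = 526
published_model_tables <- function() {
  tibble::tibble(
    measure = rep(c("accuracy", "time"), each = 7),
    model = c("Age + Edu + Sex", "Age + Edu", "Age + Sex", "Age",
              "Edu + Sex", "Edu", "Sex",
              "Age", "Age + Sex", "Age + Edu", "Age + Edu + Sex",
              "Edu", "Edu + Sex", "Sex"),
    K = c(5, 4, 4, 3, 4, 3, 3, 3, 4, 4, 5, 3, 4, 3),
    log_lik = c(-1209.8, -1212.09, -1217.64, -1219.47, -1238.61, -1240.32,
                -1267.52,
                -1722.64, -1722.12, -1722.41, -1721.85, -1736.81, -1736.42,
                -1742.19),
    aicc_printed = c(2429.72, 2432.25, 2443.36, 2444.99, 2485.29, 2486.68,
                     2541.07,
                     3451.33, 3452.32, 3452.9, 3453.82, 3479.66, 3480.92,
                     3490.42)
  )
}

# Brute-force binomial oracle for the one-sided tolerance ranks, built
# from the binomial pmf directly (no pbinom), independent of the
# implementation path.
oracle_ranks <- function(n, coverage = 0.95, conf = 0.95) {
  p <- 1 - coverage
  pmf <- exp(lchoose(n, 0:n) + (0:n) * log(p) + (n - 0:n) * log(1 - p))
  cdf <- cumsum(pmf) # cdf[r] = P[Bin <= r - 1]
  list(outer = max(which(cdf <= 1 - conf)), inner = min(which(cdf >= conf)))
}
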