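#' Assemble a GVT norm set
#'
#' A `gvt_norms` object bundles everything needed to score a scoresheet:
#' the line-uniformization corrections, the demographic adjustment models
#' for accuracy and execution time, and for each measure the clinical
#' scales (tolerance limits, percentile table, equivalent-score bands and
#' the banded correction grid).
#'
#' @param line_corrections Tibble with columns `line_id`, `correction_s`
#'   (additive seconds, one row per line).
#' @param models Named list with `gvt_adjustment` elements `accuracy` and
#'   `time`.
#' @param scales Named list with elements `accuracy` and `time`, each a list
#'   with `measure`, `direction`, `tolerance` (named numeric, `outer` and
#'   `inner`), `percentiles` (tibble `level`, `value`), `es_bands` (tibble
#'   as produced by [es_bands()]) and `grid`.
#' @param metadata Named list (source, cohort_n, seed, ...).
#' @return A `gvt_norms` object.
#' @export
gvt_norms <- function(line_corrections, models, scales, metadata = list()) {
  lc <- tibble::as_tibble(line_corrections)
  stopifnot(all(c("line_id", "correction_s") %in% names(lc)))
  missing <- setdiff(gvt_line_ids(), lc$line_id)
  if (length(missing) > 0) {
    stop("line corrections missing for: ", paste(missing, collapse = ", "))
  }
  stopifnot(all(c("accuracy", "time") %in% names(models)),
            all(c("accuracy", "time") %in% names(scales)))
  for (m in c("accuracy", "time")) {
    stopifnot(inherits(models[[m]], "gvt_adjustment"))
    sc <- scales[[m]]
    stopifnot(sc$direction %in% c("higher_better", "lower_better"),
              all(c("outer", "inner") %in% names(sc$tolerance)))
    sc$percentiles <- tibble::as_tibble(sc$percentiles)
    sc$es_bands <- tibble::as_tibble(sc$es_bands)
    if (!is.null(sc$grid)) sc$grid <- tibble::as_tibble(sc$grid)
    scales[[m]] <- sc
  }
  structure(list(metadata = metadata,
                 line_corrections = lc[match(gvt_line_ids(), lc$line_id), ],
                 models = models, scales = scales),
            class = "gvt_norms")
}

#' Published adult norms for the GVT
#'
#' Loads the packaged norm set: the published line-uniformization
#' corrections, adjustment equations, correction grids, tolerance limits
#' (accuracy: outer 1.6, inner 2.1; time: outer 37.4 s, inner 34 s),
#' percentile tables and equivalent-score bands for a normative sample of
#' 526 adults aged 20--79.
#'
#' @return A `gvt_norms` object.
#' @export
#' @examples
#' norms <- gvt_published_norms()
#' norms$scales$accuracy$tolerance
gvt_published_norms <- function() {
  path <- system.file("extdata", "gvt_published_norms.json",
                      package = "gvtnorms", mustWork = TRUE)
  read_norms(path)
}

# ---- JSON (de)serialization ----------------------------------------------

norms_to_list <- function(norms) {
  band_out <- function(b) {
    lapply(seq_len(nrow(b)), function(i) list(
      es = b$es[i],
      lower = if (is.finite(b$lower[i])) b$lower[i] else NULL,
      upper = if (is.finite(b$upper[i])) b$upper[i] else NULL,
      lower_inc = b$lower_inc[i],
      upper_inc = b$upper_inc[i]
    ))
  }
  scale_out <- function(sc) {
    list(
      measure = sc$measure,
      direction = sc$direction,
      tolerance = list(outer = unname(sc$tolerance[["outer"]]),
                       inner = unname(sc$tolerance[["inner"]])),
      percentiles = as.data.frame(sc$percentiles),
      es_bands = band_out(sc$es_bands),
      grid = if (is.null(sc$grid)) NULL else as.data.frame(sc$grid)
    )
  }
  model_out <- function(m) {
    list(measure = m$measure,
         terms = as.data.frame(m$terms),
         stats = m$stats)
  }
  list(
    format = "gvt-norms",
    format_version = "1.0",
    metadata = norms$metadata,
    line_corrections = as.data.frame(norms$line_corrections),
    models = list(accuracy = model_out(norms$models$accuracy),
                  time = model_out(norms$models$time)),
    scales = list(accuracy = scale_out(norms$scales$accuracy),
                  time = scale_out(norms$scales$time))
  )
}

norms_from_list <- function(x) {
  if (is.null(x$format) || x$format != "gvt-norms") {
    stop("not a gvt-norms document")
  }
  band_in <- function(b) {
    tibble::tibble(
      es = vapply(b, function(e) as.integer(e$es), integer(1)),
      lower = vapply(b, function(e) if (is.null(e$lower)) -Inf else
        as.numeric(e$lower), numeric(1)),
      upper = vapply(b, function(e) if (is.null(e$upper)) Inf else
        as.numeric(e$upper), numeric(1)),
      lower_inc = vapply(b, function(e) isTRUE(e$lower_inc), logical(1)),
      upper_inc = vapply(b, function(e) isTRUE(e$upper_inc), logical(1))
    )
  }
  scale_in <- function(sc) {
    list(
      measure = sc$measure,
      direction = sc$direction,
      tolerance = c(outer = as.numeric(sc$tolerance$outer),
                    inner = as.numeric(sc$tolerance$inner)),
      percentiles = tibble::as_tibble(sc$percentiles),
      es_bands = band_in(sc$es_bands),
      grid = if (is.null(sc$grid)) NULL else tibble::as_tibble(sc$grid)
    )
  }
  model_in <- function(m) {
    terms <- tibble::as_tibble(m$terms)
    terms$k <- as.numeric(terms$k)
    terms$s <- as.numeric(terms$s)
    adjustment_model(terms, measure = m$measure,
                     stats = if (is.null(m$stats)) list() else m$stats)
  }
  gvt_norms(
    line_corrections = tibble::as_tibble(x$line_corrections),
    models = list(accuracy = model_in(x$models$accuracy),
                  time = model_in(x$models$time)),
    scales = list(accuracy = scale_in(x$scales$accuracy),
                  time = scale_in(x$scales$time)),
    metadata = x$metadata
  )
}

#' Read and write norm documents
#'
#' Norm sets are stored as a JSON document carrying the line corrections,
#' adjustment models, grids and scales. The document is structurally
#' validated on load; writing is atomic (temporary file in the same
#' directory, then rename) and deterministic, so `load -> save -> load`
#' round-trips byte-identically.
#'
#' @param path Path to a `.json` norms document.
#' @return `read_norms()`: a `gvt_norms` object.
#' @export
read_norms <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  # es_bands must stay a list of records (nullable bounds)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  x$scales$accuracy$es_bands <- raw$scales$accuracy$es_bands
  x$scales$time$es_bands <- raw$scales$time$es_bands
  norms_from_list(x)
}

#' @rdname read_norms
#' @param norms A `gvt_norms` object.
#' @export
write_norms <- function(norms, path) {
  stopifnot(inherits(norms, "gvt_norms"))
  json <- jsonlite::toJSON(norms_to_list(norms), pretty = TRUE,
                           auto_unbox = TRUE, digits = NA, na = "null",
                           null = "null", dataframe = "rows")
  write_atomic(paste0(json, "\n"), path)
  invisible(path)
}

# Atomic text write: temp file in the target directory, then rename.
write_atomic <- function(text, path) {
  dir <- dirname(path)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(text, tmp, sep = "", useBytes = TRUE)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

#' @export
print.gvt_norms <- function(x, ...) {
  md <- x$metadata
  cat("<gvt_norms>",
      if (!is.null(md$source)) paste0("source: ", md$source) else "",
      if (!is.null(md$cohort_n)) paste0(" (n = ", md$cohort_n, ")") else "",
      "\n", sep = "")
  for (m in c("accuracy", "time")) {
    sc <- x$scales[[m]]
    cat(sprintf("  %s: tolerance outer %s / inner %s (%s)\n",
                m, format(sc$tolerance[["outer"]]),
                format(sc$tolerance[["inner"]]), sc$direction))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.gvt_norms <- function(x, ...) {
  tibble::tibble(
    source = x$metadata$source %||% NA_character_,
    cohort_n = x$metadata$cohort_n %||% NA_integer_,
    accuracy_outer = x$scales$accuracy$tolerance[["outer"]],
    accuracy_inner = x$scales$accuracy$tolerance[["inner"]],
    time_outer = x$scales$time$tolerance[["outer"]],
    time_inner = x$scales$time$tolerance[["inner"]]
  )
}
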