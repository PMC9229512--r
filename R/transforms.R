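#' Predictor transformation families
#'
#' The nine candidate transformations tried for each demographic predictor
#' during norm derivation: linear `x`, reverse `k - x`, quadratic `x^2`,
#' logarithmic `ln x`, logarithmic reverse `ln(k - x)`, square root `sqrt(x)`,
#' geometrical `x^3`, inverse `1/x`, and exponential `exp(x/s)`.
#'
#' The reverse families need a shift constant `k` larger than the largest
#' observed predictor value; the exponential family is scaled by
#' `s = range(x)/10` so that it stays finite for ages in years.
#'
#' @return Character vector of family names, in the fixed tie-break order.
#' @export
transform_families <- function() {
  c("linear", "reverse", "quadratic", "logarithmic", "logarithmic_reverse",
    "square_root", "geometrical", "inverse", "exponential")
}

#' Construct a transformation specification
#'
#' @param family One of [transform_families()].
#' @param k Shift constant for the reverse families (`k - x`, `ln(k - x)`);
#'   must exceed every value the transform is applied to.
#' @param s Scale constant for the exponential family (`exp(x/s)`).
#' @return A `gvt_transform` object.
#' @export
#' @examples
#' tr <- transform_spec("logarithmic_reverse", k = 86.9)
#' transform_eval(tr, 24.5)  # ln(62.4)
transform_spec <- function(family = "linear", k = NA_real_, s = NA_real_) {
  family <- match.arg(family, transform_families())
  if (family %in% c("reverse", "logarithmic_reverse") && is.na(k)) {
    stop("family '", family, "' requires a shift constant k")
  }
  if (family == "exponential" && is.na(s)) {
    stop("family 'exponential' requires a scale constant s")
  }
  structure(list(family = family, k = as.numeric(k), s = as.numeric(s)),
            class = "gvt_transform")
}

#' @rdname transform_spec
#' @param spec A `gvt_transform` object.
#' @param x Numeric vector of predictor values.
#' @export
transform_eval <- function(spec, x) {
  stopifnot(inherits(spec, "gvt_transform"))
  switch(spec$family,
    linear = x,
    reverse = spec$k - x,
    quadratic = x^2,
    logarithmic = {
      if (any(x <= 0)) stop("logarithmic transform needs positive values")
      log(x)
    },
    logarithmic_reverse = {
      if (any(x >= spec$k)) {
        stop("logarithmic reverse transform needs values below k = ", spec$k)
      }
      log(spec$k - x)
    },
    square_root = {
      if (any(x < 0)) stop("square-root transform needs non-negative values")
      sqrt(x)
    },
    geometrical = x^3,
    inverse = {
      if (any(x == 0)) stop("inverse transform needs non-zero values")
      1 / x
    },
    exponential = exp(x / spec$s)
  )
}

# Is the family applicable over the observed range of x?
transform_applicable <- function(family, x) {
  switch(family,
    logarithmic = all(x > 0),
    square_root = all(x >= 0),
    inverse = all(x != 0),
    TRUE
  )
}

#' @export
format.gvt_transform <- function(x, ...) {
  switch(x$family,
    linear = "x",
    reverse = sprintf("%.4g - x", x$k),
    quadratic = "x^2",
    logarithmic = "ln(x)",
    logarithmic_reverse = sprintf("ln(%.4g - x)", x$k),
    square_root = "sqrt(x)",
    geometrical = "x^3",
    inverse = "1/x",
    exponential = sprintf("exp(x/%.4g)", x$s)
  )
}

#' @export
print.gvt_transform <- function(x, ...) {
  cat("<gvt_transform> ", format(x), "\n", sep = "")
  invisible(x)
}
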