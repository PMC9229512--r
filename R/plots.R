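#' Plot a norm set
#'
#' Draws the percentile curve of corrected scores for each measure, with
#' the equivalent-score bands shaded and the tolerance limits marked
#' (dashed: outer; dotted: inner).
#'
#' @param object A `gvt_norms` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gvt_norms <- function(object, ...) {
  ptab <- dplyr::bind_rows(
    dplyr::mutate(object$scales$accuracy$percentiles, measure = "accuracy"),
    dplyr::mutate(object$scales$time$percentiles, measure = "time")
  )
  bands <- dplyr::bind_rows(
    dplyr::mutate(object$scales$accuracy$es_bands, measure = "accuracy"),
    dplyr::mutate(object$scales$time$es_bands, measure = "time")
  ) |>
    dplyr::mutate(
      lower = ifelse(is.finite(.data$lower), .data$lower, NA_real_),
      upper = ifelse(is.finite(.data$upper), .data$upper, NA_real_)
    )
  lims <- dplyr::bind_rows(
    tibble::tibble(measure = "accuracy",
                   limit = c("outer", "inner"),
                   value = unname(object$scales$accuracy$tolerance)),
    tibble::tibble(measure = "time",
                   limit = c("outer", "inner"),
                   value = unname(object$scales$time$tolerance))
  )
  ggplot2::ggplot(ptab, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                   fill = factor(.data$es)),
      xmin = -Inf, xmax = Inf, alpha = 0.25, inherit.aes = FALSE
    ) +
    ggplot2::geom_hline(
      data = lims,
      ggplot2::aes(yintercept = .data$value, linetype = .data$limit),
      linewidth = 0.4
    ) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::scale_linetype_manual(values = c(outer = "dashed",
                                              inner = "dotted")) +
    ggplot2::labs(x = "percentile", y = "corrected score",
                  fill = "ES", linetype = "tolerance limit") +
    ggplot2::theme_minimal()
}

#' Plot scored participants against the norms
#'
#' Corrected accuracy against corrected execution time, coloured by the
#' accuracy classification; participants without an assessable time score
#' are omitted.
#'
#' @param object A `gvt_scored` tibble.
#' @param norms Optional `gvt_norms` to draw the tolerance limits of both
#'   measures.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gvt_scored <- function(object, norms = NULL, ...) {
  dat <- dplyr::filter(object, !is.na(.data$corrected_time))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$corrected_time,
                                         y = .data$corrected_accuracy,
                                         colour = .data$class_accuracy)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "corrected execution time (s)",
                  y = "corrected accuracy", colour = "classification") +
    ggplot2::theme_minimal()
  if (!is.null(norms)) {
    p <- p +
      ggplot2::geom_hline(yintercept = norms$scales$accuracy$tolerance,
                          linetype = c("dashed", "dotted"),
                          linewidth = 0.4) +
      ggplot2::geom_vline(xintercept = norms$scales$time$tolerance,
                          linetype = c("dashed", "dotted"),
                          linewidth = 0.4)
  }
  p
}

#' @export
plot.gvt_norms <- function(x, ...) print(autoplot.gvt_norms(x, ...))

#' @export
plot.gvt_scored <- function(x, ...) print(autoplot.gvt_scored(x, ...))
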