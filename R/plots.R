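#' Plot a relaxation fit
#'
#' Measured points with the fitted mono-exponential curve overlaid.
#'
#' @param object A `relaxation_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot relaxation_fit
#' @export
autoplot.relaxation_fit <- function(object, ...) {
  d <- tibble::as_tibble(object$data)
  tt <- seq(min(d$time_ms), max(d$time_ms), length.out = 200)
  yy <- if (object$kind == "inversion_recovery") {
    object$amplitude * (1 - 2 * exp(-tt / object$relaxation_time))
  } else {
    object$amplitude * exp(-tt / object$relaxation_time)
  }
  lab <- if (object$kind == "inversion_recovery") "T1" else "T2"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$signal)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(
      data = tibble::tibble(time_ms = tt, signal = yy),
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "time (ms)", y = "signal (a.u.)",
      title = sprintf("%s fit: %s = %.2f ms", object$kind, lab,
                      object$relaxation_time)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an OIT determination
#'
#' The DSC trace with the baseline level, the maximum-slope tangent and
#' the detected oxidation induction time.
#'
#' @param object An `oit_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oit_result
#' @export
autoplot.oit_result <- function(object, ...) {
  d <- tibble::as_tibble(object$trace)
  t0 <- object$tangent_point[["time"]]
  y0 <- object$tangent_point[["heat_flow"]]
  s <- object$tangent_slope
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$heat_flow)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$baseline_level,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_abline(intercept = y0 - s * t0, slope = s,
                         colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$oit, colour = "steelblue",
                        linetype = "dotted") +
    ggplot2::labs(
      x = "time (min)", y = "heat flow (a.u.)",
      title = sprintf("OIT = %.2f min (tangent method)", object$oit)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a standardised PCA
#'
#' Score plot for the first two dimensions with loading directions
#' overlaid (scaled), explained variance in the axis labels.
#'
#' @param object A `pca_std`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pca_std
#' @export
autoplot.pca_std <- function(object, ...) {
  sc <- tibble::as_tibble(object$scores, rownames = "sample")
  ld <- tibble::as_tibble(object$loadings, rownames = "variable")
  r <- max(abs(sc$Dim1), abs(sc$Dim2))
  ld <- dplyr::mutate(ld, Dim1 = .data$Dim1 * r, Dim2 = .data$Dim2 * r)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$Dim1, y = .data$Dim2)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$Dim1, yend = .data$Dim2),
      colour = "firebrick", alpha = 0.6,
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(
      data = ld, ggplot2::aes(label = .data$variable),
      colour = "firebrick", size = 3, vjust = -0.5
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample),
                       size = 3, vjust = 1.6) +
    ggplot2::labs(
      x = sprintf("Dim1 (%.1f%%)", object$explained[1]),
      y = sprintf("Dim2 (%.1f%%)", object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of fatty-acid class shares
#'
#' @param shares A class-shares tibble from [class_shares()].
#' @return A ggplot of SFA/MUFA/PUFA composition per blend.
#' @examples
#' oil_blend_profiles() |> class_shares() |> plot_class_shares()
#' @export
plot_class_shares <- function(shares) {
  long <- shares |>
    dplyr::select("blend", "sfa", "mufa", "pufa") |>
    tidyr::pivot_longer(-"blend", names_to = "class",
                        values_to = "percent") |>
    dplyr::mutate(class = factor(toupper(.data$class),
                                 levels = c("SFA", "MUFA", "PUFA")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$blend, y = .data$percent,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of total fatty acids", fill = NULL) +
    ggplot2::theme_minimal()
}
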