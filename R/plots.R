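#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the simulated (GR, FV) response space
#'
#' Points of the simulated grid coloured by relative death rate, with the
#' three boundary responses overlaid: arrest-only (FV = 1), death-only
#' (right) and biphasic (left). Every attainable drug response lies inside
#' these boundaries.
#'
#' @param object A `grade_simgrid` from [simulate_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grade_simgrid <- function(object, ...) {
  b <- dplyr::bind_rows(
    dplyr::mutate(object$boundaries$arrest_only, boundary = "arrest-only"),
    dplyr::mutate(object$boundaries$death_only, boundary = "death-only"),
    dplyr::mutate(object$boundaries$biphasic, boundary = "biphasic")
  )
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$gr, y = .data$fv)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$d_rel), size = 0.6, alpha = 0.6) +
    ggplot2::geom_path(data = b, ggplot2::aes(linetype = .data$boundary),
                       linewidth = 0.7) +
    ggplot2::scale_colour_viridis_c(name = "relative\ndeath rate") +
    ggplot2::labs(x = "GR value", y = "Fractional viability (FV)",
                  title = sprintf("Simulated response space (t_c = %g dbl/h, %g h)",
                                  object$t_c, object$duration)) +
    ggplot2::theme_minimal()
}

#' GR-FV plot of a dose-response profile
#'
#' The central GRADE visualisation: per-dose (GR, FV) points connected in
#' dose order, with the fitted GRADE line over the GR \[0, 1\] window when
#' it can be computed.
#'
#' @param object A `dose_response_profile`.
#' @param show_fit Draw the windowed least-squares line (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_response_profile <- function(object, show_fit = TRUE, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gr, y = .data$fv)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = log10(.data$dose)), colour = "steelblue") +
    ggplot2::scale_size_continuous(name = "log10 dose (M)", range = c(1.5, 4)) +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::labs(x = "GR value", y = "Fractional viability (FV)",
                  title = sprintf("%s / %s at %g h", attr(object, "drug"),
                                  attr(object, "cell_line"),
                                  attr(object, "assay_duration"))) +
    ggplot2::theme_minimal()
  if (show_fit) {
    g <- tryCatch(compute_grade(object), error = function(e) NULL)
    if (!is.null(g)) {
      p <- p +
        ggplot2::geom_abline(intercept = g$intercept, slope = g$m_drug,
                             colour = "firebrick") +
        ggplot2::labs(subtitle = sprintf("GRADE = %.1f (m_drug = %.3f, m_max = %.3f)",
                                         g$grade, g$m_drug, g$m_max))
    }
  }
  p
}

#' Dose-response curve of a 4PL fit
#'
#' @param object A `grade_4pl`.
#' @param ... Unused.
#' @return A ggplot of the data and the fitted curve on log10 dose.
#' @export
autoplot.grade_4pl <- function(object, ...) {
  xs <- seq(min(object$data$log10_dose), max(object$data$log10_dose),
            length.out = 200)
  curve <- tibble::tibble(log10_dose = xs, response = predict(object, xs))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_dose, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "log10 dose (M)", y = toupper(object$variant)) +
    ggplot2::theme_minimal()
}

#' GRADE stability over assay time
#'
#' @param grade_series Output of [grade_over_time()].
#' @return A ggplot of GRADE versus evaluation time with the 48 h stability
#'   guide.
#' @export
plot_grade_over_time <- function(grade_series) {
  ggplot2::ggplot(grade_series, ggplot2::aes(x = .data$time, y = .data$grade)) +
    ggplot2::geom_vline(xintercept = 48, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "Assay time (h)", y = "GRADE") +
    ggplot2::theme_minimal()
}
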