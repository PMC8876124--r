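#' Plot a mean stress-strain curve with its confidence band
#'
#' @param object A [mean_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot: mean stress versus strain with the 95 % band shaded.
#' @export
autoplot.mean_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$strain, y = .data$mean_stress)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_stress - .data$ci_half_width,
                                      ymax = .data$mean_stress + .data$ci_half_width),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Engineering strain (-)", y = "Stress (MPa)",
                  title = "Mean stress-strain curve (95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot a finite-element force-displacement curve
#'
#' @param object A `fem_result`.
#' @param closed_form Optional [neo_hooke_params()]; when given, the
#'   closed-form homogeneous prediction
#'   `A_mesh * lambda * |S33(lambda)|` is overlaid.
#' @param ... Unused.
#' @return A ggplot of stamp reaction versus travel.
#' @export
autoplot.fem_result <- function(object, closed_form = NULL, ...) {
  df <- tidy.fem_result(object)
  df$source <- "FEM"
  if (!is.null(closed_form)) {
    p <- as_nh_params(closed_form)
    L0 <- object$mesh$L0
    lam <- pmax(1 - df$displacement_mm / L0, 1e-6)
    cf <- tibble(displacement_mm = df$displacement_mm,
                 force_N = mesh_cross_section_area(object$mesh) * lam *
                   abs(uniaxial_stress(lam, p)),
                 source = "closed form")
    cf$force_N[df$displacement_mm == 0] <- 0
    df <- bind_rows(df, cf)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$displacement_mm, y = .data$force_N,
                                   colour = .data$source,
                                   linetype = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Stamp travel (mm)", y = "Reaction force (N)",
                  title = "Simulated compression test") +
    ggplot2::theme_minimal()
}

#' Plot a Feret-ratio histogram
#'
#' @param object A [ratio_histogram()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of min/max Feret ratio counts with the modal
#'   ratio marked.
#' @export
autoplot.feret_summary_hist <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$bin_lo[1:2]) * 0.95) +
    ggplot2::geom_vline(xintercept = object$modal_ratio, linetype = 2) +
    ggplot2::labs(x = "min/max Feret ratio", y = "Particles",
                  title = sprintf("Feret-ratio distribution (n = %d, mode %.2f)",
                                  object$n, object$modal_ratio)) +
    ggplot2::theme_minimal()
}

#' Per-condition summary plot of modulus and strength
#'
#' @param condition_table The `condition_table` of a [run_pipeline()]
#'   report.
#' @return A ggplot with one panel per summary statistic (mean +/- sd).
#' @export
plot_condition_summary <- function(condition_table) {
  long <- condition_table |>
    tidyr::pivot_longer(cols = c("modulus_mean", "strength_20_mean"),
                        names_to = "stat", values_to = "mean") |>
    mutate(sd = ifelse(.data$stat == "modulus_mean", .data$modulus_sd,
                       .data$strength_20_sd),
           stat = ifelse(.data$stat == "modulus_mean",
                         "Elastic modulus (MPa)",
                         "Compressive strength at 20% strain (MPa)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
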