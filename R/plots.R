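#' Plot a biaxial stress-stretch curve
#'
#' Longitudinal and circumferential true stress against the stretch in the
#' respective loading direction.
#'
#' @param curve A biaxial curve tibble (`lambda_L`, `lambda_C`,
#'   `sigma_LL_MPa`, `sigma_CC_MPa`).
#' @return A ggplot object.
#' @export
plot_biaxial_curve <- function(curve) {
  df <- dplyr::bind_rows(
    tibble::tibble(direction = "longitudinal", stretch = curve$lambda_L,
                   stress = curve$sigma_LL_MPa),
    tibble::tibble(direction = "circumferential", stretch = curve$lambda_C,
                   stress = curve$sigma_CC_MPa)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$stretch, .data$stress,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stretch (-)", y = "Cauchy stress (MPa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-layer damage evolution along a path
#'
#' @param traj A [run_path()] result (columns `lambda_L`, `D_lm`, `D_cm`,
#'   `D_sm`).
#' @return A ggplot object.
#' @export
plot_damage_trajectory <- function(traj) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(traj)[c("lambda_L", "D_lm", "D_cm", "D_sm")],
    cols = -"lambda_L", names_to = "layer", values_to = "D",
    names_prefix = "D_"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda_L, .data$D,
                                   colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "longitudinal stretch (-)", y = "damage D (-)",
                  colour = "layer") +
    ggplot2::theme_minimal()
}

#' Plot a fit against its data
#'
#' @param object A [fit_biaxial()] result.
#' @param ... Unused.
#' @return A ggplot object overlaying the measured points and the fitted
#'   curves in both directions.
#' @method autoplot biaxial_fit
#' @export
autoplot.biaxial_fit <- function(object, ...) {
  data_df <- dplyr::bind_rows(
    tibble::tibble(direction = "longitudinal",
                   stretch = object$curve$lambda_L,
                   stress = object$curve$sigma_LL_MPa),
    tibble::tibble(direction = "circumferential",
                   stretch = object$curve$lambda_C,
                   stress = object$curve$sigma_CC_MPa)
  )
  fit_df <- dplyr::bind_rows(
    tibble::tibble(direction = "longitudinal",
                   stretch = object$curve$lambda_L,
                   stress = object$fitted$sigma_LL),
    tibble::tibble(direction = "circumferential",
                   stretch = object$curve$lambda_C,
                   stress = object$fitted$sigma_CC)
  )
  ggplot2::ggplot(data_df, ggplot2::aes(.data$stretch, .data$stress,
                                        colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = fit_df) +
    ggplot2::labs(x = "stretch (-)", y = "Cauchy stress (MPa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
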