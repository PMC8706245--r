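#' Plot a jump trial
#'
#' Two stacked panels: PSIS-midpoint height (mm) and summed vertical GRF
#' (N) against time, with the five phases shaded when `phases` is supplied.
#'
#' @param object A [jump_trial()].
#' @param phases Optional [segment_phases()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.jump_trial <- function(object, phases = NULL, ...) {
  psis <- tibble::tibble(time_s = object$markers$time_s,
                         value = psis_midpoint_z(object$markers),
                         channel = "PSIS height (mm)")
  fz <- total_vertical_grf(object$grf)
  fz <- tibble::tibble(time_s = fz$time_s, value = fz$fz_total,
                       channel = "vertical GRF (N)")
  dat <- dplyr::bind_rows(psis, fz)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste("jump trial", object$subject_id)) +
    ggplot2::theme_minimal()
  if (!is.null(phases)) {
    rate <- series_rate(object$markers)
    bands <- dplyr::mutate(phases$phases,
                           xmin = (.data$start - 1) / rate,
                           xmax = (.data$end - 1) / rate)
    p <- p + ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$phase),
      alpha = 0.12) +
      ggplot2::scale_fill_brewer(palette = "Set2")
  }
  p + ggplot2::geom_line()
}

#' Plot net joint moments
#'
#' @param object An [inverse_dynamics()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.joint_moments <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("ankle_nm", "knee_nm", "hip_nm"),
                              names_to = "joint", values_to = "moment_nm")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$moment_nm,
                                     colour = .data$joint)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "net moment (N m, extensor +)") +
    ggplot2::theme_minimal()
}

#' Plot peak normalized muscle forces
#'
#' @param object A [muscle_forces()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.muscle_forces <- function(object, ...) {
  dat <- dplyr::arrange(tibble::as_tibble(object), .data$peak_force_bw)
  dat$muscle <- factor(dat$muscle, levels = dat$muscle)
  ggplot2::ggplot(dat, ggplot2::aes(.data$peak_force_bw, .data$muscle)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "peak force (N/BW)", y = NULL) +
    ggplot2::theme_minimal()
}
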