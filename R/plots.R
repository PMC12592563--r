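# ggplot2 visualisations for the main result types.

#' Plot a fragment ion chromatogram
#'
#' @param xic An `xic` from [extract_xic()], or a named list of them.
#' @param smooth Overlay the Savitzky-Golay smoothed trace.
#' @return A ggplot object.
#' @export
plot_xic <- function(xic, smooth = TRUE) {
  xics <- if (inherits(xic, "xic")) list(fragment = xic) else xic
  df <- purrr::imap_dfr(xics, function(x, nm) {
    tibble::tibble(fragment = nm, time = x$times, intensity = x$values,
                   smoothed = smooth_xic(x)$values)
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$intensity,
                                        colour = .data$fragment)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "retention time (min)", y = "intensity") +
    ggplot2::theme_minimal()
  if (smooth) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8)
  }
  p
}

#' @describeIn tidy.trained_model Training-loss curve.
#' @export
autoplot.trained_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "masked L1 loss",
                  title = paste(object$kind, "model training")) +
    ggplot2::theme_minimal()
}

#' Plot an NCE calibration curve
#'
#' @param object An `nce_calibration` from [calibrate_nce()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nce_calibration <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$nce, y = .data$median_similarity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$optimal_nce, linetype = "dashed") +
    ggplot2::labs(x = "NCE", y = "median spectral entropy similarity") +
    ggplot2::theme_minimal()
}

#' Plot FDP bound curves
#'
#' @param sweep Tibble from [fdp_sweep()].
#' @return A ggplot object.
#' @export
plot_fdp_sweep <- function(sweep) {
  df <- tidyr::pivot_longer(sweep, c("lower", "upper"),
                            names_to = "bound", values_to = "fdp")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$fdp,
                                   linetype = .data$bound)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "score cutoff", y = "estimated FDP") +
    ggplot2::theme_minimal()
}
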