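#' Plot an ROI-mean-vs-offset curve
#'
#' Line-and-point plot of the ROI mean signal across the frequency sweep;
#' flat curves indicate successful banding suppression. Requires ggplot2.
#'
#' @param curves a named list of `eval_curve` objects (e.g.
#'   `list(original = ..., suppressed = ...)`) or a single `eval_curve`.
#' @return a ggplot object.
#' @export
plot_eval_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_eval_curves requires ggplot2")
  }
  if (inherits(curves, "eval_curve")) curves <- list(signal = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cbind(curves[[nm]]$curve, series = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = offset_hz, y = mean_intensity,
                                   colour = series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "centre-frequency offset (Hz)",
                  y = "ROI mean signal (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Display one cardiac phase of a movie as an image
#'
#' Base-graphics grayscale display, mainly for quick phantom inspection.
#'
#' @param movie a `cine_movie`, `vi_map`, `spc_label` or array.
#' @param phase_index cardiac phase to show.
#' @param ... passed to [graphics::image()].
#' @export
show_phase <- function(movie, phase_index = 1, ...) {
  arr <- if (inherits(movie, c("vi_map", "spc_label"))) movie$data
         else as_movie_array(movie)
  img <- t(arr[phase_index, rev(seq_len(dim(arr)[2])), ])
  graphics::image(img, col = grDevices::grey.colors(256, 0, 1), asp = 1,
                  axes = FALSE, ...)
}
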