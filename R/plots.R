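# ggplot2 methods for the package's result types.

#' @method autoplot rmsf_profile
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resid, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue", y = "RMSF (Å)")
}

#' @method autoplot dccm_matrix
#' @export
autoplot.dccm_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$resid_i, y = .data$resid_j,
                               fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Residue", y = "Residue", fill = "C_ij")
}

#' @method autoplot distance_series
#' @export
autoplot.distance_series <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$frame, y = .data$distance)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Frame", y = "Distance (Å)")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' @method autoplot one_site_fit
#' @export
autoplot.one_site_fit <- function(object, ...) {
  grid <- tibble(concentration = seq(0, max(object$data$concentration),
                                     length.out = 200))
  grid$response <- one_site_response(pmax(grid$concentration, 0),
                                     object$bmax, object$kd)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "Concentration (µM)", y = "Response (R.U.)")
}
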