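#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Display an attenuation image
#'
#' @param object a [ct_image()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ct_image <- function(object, ...) {
  v <- object$values
  df <- data.frame(
    x = as.vector(col(v)) * object$pixel_size,
    y = -as.vector(row(v)) * object$pixel_size,
    value = as.vector(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = expression(mu ~ (mm^-1))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Display a sinogram
#'
#' @param object a [ct_sinogram()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ct_sinogram <- function(object, ...) {
  v <- object$values
  df <- data.frame(
    angle = rep(object$angles, times = ncol(v)),
    bin = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$angle, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "line integral") +
    ggplot2::labs(x = "detector bin", y = "view angle (deg)") +
    ggplot2::theme_minimal()
}

#' Convergence history of a reconstruction
#'
#' @param object a `piccs_fit`.
#' @param ... unused.
#' @return A ggplot of data residual and relative change per outer cycle.
#' @export
autoplot.piccs_fit <- function(object, ...) {
  h <- tidy(object)
  df <- rbind(
    data.frame(iteration = h$iteration, quantity = "data residual",
               value = h$data_residual),
    data.frame(iteration = h$iteration, quantity = "relative change",
               value = h$rel_change)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "outer cycle", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname reconstruct_l2piccs
#' @param x a `piccs_fit`.
#' @param ... unused.
#' @export
tidy.piccs_fit <- function(x, ...) {
  tibble::as_tibble(x$history)
}

#' @rdname reconstruct_l2piccs
#' @export
glance.piccs_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    iterations = x$iterations,
    final_objective = h$objective[nrow(h)],
    final_data_residual = h$data_residual[nrow(h)],
    final_rel_change = h$rel_change[nrow(h)],
    mu = x$hp$mu, lam = x$hp$lam, alpha = x$hp$alpha, gamma = x$hp$gamma
  )
}

#' @importFrom rlang .data
NULL
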