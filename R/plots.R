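#' Plot a per-residue displacement profile
#'
#' @param profile a [displacement_profile()] result.
#' @param highlight optional list of named residue ranges
#'   (`list(label = c(start, end))`) shaded on the plot.
#' @return A ggplot object.
#' @export
plot_displacement_profile <- function(profile, highlight = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$resno, y = .data$displacement)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue (author numbering)",
                  y = sprintf("displacement of %s (Å)",
                              attr(profile, "atom_used") %||% "P")) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    bands <- dplyr::bind_rows(lapply(names(highlight), function(nm) {
      tibble(label = nm, xmin = highlight[[nm]][1], xmax = highlight[[nm]][2])
    }))
    p <- p + ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.15)
  }
  p
}

#' Heatmap of a pairwise RMSD matrix
#'
#' @param m matrix from [pairwise_rmsd_matrix()].
#' @return A ggplot object.
#' @export
plot_rmsd_matrix <- function(m) {
  df <- as_tibble(as.data.frame.table(m, responseName = "rmsd"))
  names(df)[1:2] <- c("frame_i", "frame_j")
  df$frame_i <- factor(df$frame_i, levels = rownames(m))
  df$frame_j <- factor(df$frame_j, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame_i, .data$frame_j,
                                   fill = .data$rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "RMSD (Å)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scatter-line plot of a descriptor series
#'
#' @param series tibble from [descriptor_series()].
#' @param descriptor column to plot (default `"angle_A"`).
#' @return A ggplot object.
#' @export
plot_descriptor_series <- function(series, descriptor = "angle_A") {
  if (!descriptor %in% names(series)) {
    abort(paste0("series has no column '", descriptor, "'"))
  }
  unit <- if (grepl("^angle", descriptor)) "(°)" else "(Å)"
  ggplot2::ggplot(series, ggplot2::aes(x = .data$frame,
                                       y = .data[[descriptor]])) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sub-state", y = paste(descriptor, unit)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot.two_step_fit()` overlays the fitted precursor / intermediate /
#' product curves on the observed fractions; `autoplot.mm_fit()` draws the
#' Michaelis-Menten saturation curve through the rate data.
#'
#' @param object a fitted object.
#' @param ... unused.
#' @return A ggplot object.
#' @name rnagate-autoplot
NULL

#' @rdname rnagate-autoplot
#' @export
autoplot.two_step_fit <- function(object, ...) {
  tgrid <- seq(min(object$data$time), max(object$data$time), length.out = 200)
  curves <- two_step_populations(object$k1, object$k2, tgrid, p0 = object$p0)
  curves <- tidyr::pivot_longer(curves, -"time", names_to = "species",
                                values_to = "fraction")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$time, .data$fraction,
                               color = .data$species)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = "time (min)", y = "population fraction",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname rnagate-autoplot
#' @export
autoplot.mm_fit <- function(object, ...) {
  sgrid <- seq(0, max(object$data$S), length.out = 200)
  curve <- tibble(S = sgrid, v = object$vmax * sgrid / (object$km + sgrid))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$S, .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::labs(x = "substrate (nmol/L)", y = "initial rate (nmol/L/min)") +
    ggplot2::theme_minimal()
}
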