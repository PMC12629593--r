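#' Plot methods
#'
#' `autoplot()` methods give quick-look ggplots: a density trace for
#' [ibi_density] objects (with the refractory floor marked), a flash
#' raster for [flash_series()], and the KS surface with best-fit
#' couplings for `beta_sweep` results.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name firesync-plots
NULL

#' @rdname firesync-plots
#' @method autoplot ibi_density
#' @export
autoplot.ibi_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s, y = .data$density)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = t_min(object), linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(
      x = "interval (s)", y = "density",
      title = attr(object, "label"),
      subtitle = sprintf("support [%.2f, %.2f] s", t_min(object), t_max(object))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname firesync-plots
#' @method autoplot flash_series
#' @export
autoplot.flash_series <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$t_start, xend = .data$t_end,
                   y = .data$agent_id, yend = .data$agent_id),
      linewidth = 2, color = "#fec44f"
    ) +
    ggplot2::labs(x = "time (s)", y = "agent") +
    ggplot2::theme_minimal()
}

#' @rdname firesync-plots
#' @method autoplot beta_sweep
#' @export
autoplot.beta_sweep <- function(object, ...) {
  ggplot2::ggplot(object$sweep,
                  ggplot2::aes(x = .data$beta, y = factor(.data$N),
                               fill = .data$ks_D)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = object$best,
      ggplot2::aes(x = .data$best_beta, y = factor(.data$N)),
      inherit.aes = FALSE, shape = 4, size = 3, stroke = 1.2
    ) +
    ggplot2::scale_fill_viridis_c(name = "KS D") +
    ggplot2::labs(x = expression(beta), y = "N") +
    ggplot2::theme_minimal()
}

#' Standard-deviation sharpening plot
#'
#' Line plot of the analytic group-interval standard deviation against
#' group size, the signature of emergent periodicity.
#'
#' @param density An [ibi_density] for one individual.
#' @param Ns Integer vector of group sizes (default 1..30).
#' @return A ggplot.
#' @export
plot_std_vs_N <- function(density, Ns = 1:30) {
  tbl <- std_vs_N(density, Ns)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$N, y = .data$sd_s)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "group size N", y = "sd of group interval (s)") +
    ggplot2::theme_minimal()
}
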