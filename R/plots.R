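#' Plot a stability-region grid
#'
#' Renders the scanned lattice in the style of the standard stability-region
#' figure: stable cells shaded grey, unstable cells white, with the
#' framework's critical-\eqn{f_p} boundary and the shared necessary-condition
#' line \eqn{1 + f_h + f_p = 0} drawn on top.
#'
#' @param object A `region_grid` from [scan_region()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_grid <- function(object, ...) {
  grid <- object$grid
  fh_axis <- object$fh_axis
  bline <- tibble::tibble(
    fh = fh_axis,
    fp = if (object$framework == "continuous")
      boundary_fp_continuous(fh_axis, object$params$r, object$params$gamma)
    else boundary_fp_discrete(fh_axis, object$params$R))
  nline <- tibble::tibble(fh = fh_axis, fp = -1 - fh_axis)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$fh, y = .data$fp)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$verdict)) +
    ggplot2::scale_fill_manual(values = c(stable = "grey60",
                                          marginal = "grey25",
                                          unstable = "white"),
                               name = NULL) +
    ggplot2::geom_line(data = bline, linetype = "solid") +
    ggplot2::geom_line(data = nline, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = range(object$fp_axis), expand = FALSE) +
    ggplot2::labs(
      x = expression(f[h] ~ "(attack-rate sensitivity to host density)"),
      y = expression(f[p] ~ "(attack-rate sensitivity to parasitoid density)"),
      title = paste0(object$framework, "-time stability region"),
      subtitle = paste(names(object$params), signif(unlist(object$params), 4),
                       sep = " = ", collapse = ", ")) +
    ggplot2::theme_minimal()
}

#' Plot a simulated trajectory
#'
#' Host and parasitoid densities against time (continuous framework) or
#' generation (discrete framework).
#'
#' @param object A `parastab_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom rlang .data
#' @export
autoplot.parastab_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  xvar <- if ("time" %in% names(df)) "time" else "generation"
  names(df)[names(df) == "H"] <- "host"
  names(df)[names(df) == "P"] <- "parasitoid"
  long <- tidyr::pivot_longer(df, c("host", "parasitoid"),
                              names_to = "species", values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$density,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xvar, y = "population density", colour = NULL) +
    ggplot2::theme_minimal()
}
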