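# ggplot2 autoplot methods for the package's result types.

#' @rdname autoplots
#' @title Plot methods
#' @description `autoplot()` methods for the package's tabular result types.
#' @param object An object produced by the package.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot epithelium_profile
#' @export
autoplot.epithelium_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("z_mid", "respiratory", "olfactory", "nonabsorbing")],
    cols = -"z_mid", names_to = "epithelium", values_to = "area"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$z_mid * 1e3, .data$area * 1e4,
                                     colour = .data$epithelium)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from naris tip (mm)",
                  y = expression("wall area per bin" ~ (cm^2)),
                  colour = NULL)
}

#' @rdname autoplots
#' @method autoplot solubility_sweep
#' @export
autoplot.solubility_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("total_fraction", "olfactory_fraction"),
    names_to = "mucosa", values_to = "fraction"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$beta, .data$fraction,
                                     colour = .data$mucosa)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(beta ~ "(air-mucus partition coefficient)"),
                  y = "deposited fraction of entering odorant", colour = NULL)
}

#' @rdname autoplots
#' @method autoplot plate_curve
#' @export
autoplot.plate_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$u, .data$N)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "u_opt"),
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "carrier velocity u (m/s)",
                  y = "theoretical plate number N")
}

#' @rdname autoplots
#' @method autoplot deposition_curve
#' @export
autoplot.deposition_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$impaction_factor, .data$efficiency)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.05) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(rho * d[p]^2 * Q ~ (g ~ mu * m^2 / s)),
                  y = "deposition efficiency")
}

#' @rdname autoplots
#' @method autoplot absorption_map
#' @export
autoplot.absorption_map <- function(object, ...) {
  dat <- as_tibble(object)
  dat <- dat[dat$flux_per_area > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$z_mid * 1e3,
                                    .data$flux_per_area)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from naris tip (mm)",
                  y = expression("absorbed flux per wall area" ~ (m^-2)))
}

#' @rdname tidiers
#' @title Broom-style tidiers
#' @description `tidy()` returns the per-unit table of a result object;
#'   `glance()` a one-row summary.
#' @param x An object produced by the package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL
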