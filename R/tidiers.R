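#' @describeIn solve_footprint Profile as a tibble (`s`, `r`, `h`, `psi`,
#'   `H`).
#' @param x A `footprint_profile`.
#' @param ... Unused.
#' @export
tidy.footprint_profile <- function(x, ...) x$profile

#' @describeIn solve_footprint One-row summary: parameters, energy
#'   decomposition, solver diagnostics.
#' @export
glance.footprint_profile <- function(x, ...) {
  e <- footprint_energy(x)
  tibble::tibble(
    radius = x$cap$radius, area = x$cap$area,
    bending_modulus = x$membrane$bending_modulus,
    tension = x$membrane$tension,
    compartment = x$compartment$mode, L = x$compartment$L,
    gm = e$gm, bending_part = e$bending_part, tension_part = e$tension_part,
    excess_area = e$excess_area,
    method = x$diagnostics$method, residual = x$diagnostics$residual,
    iterations = x$diagnostics$iterations)
}

#' Cross-section plot of a membrane footprint
#'
#' Draws the mid-bilayer cross section through the symmetry axis (profile
#' mirrored to negative radii), with the dome cap drawn over its own extent.
#' Height is plotted positive toward the cell interior, the side the dome
#' bulges into.
#'
#' @param object A `footprint_profile`.
#' @param dome Draw the spherical-cap dome as well.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.footprint_profile <- function(object, dome = TRUE, ...) {
  pr <- object$profile
  h0 <- pr$h[1]
  both <- dplyr::bind_rows(
    dplyr::mutate(pr, side = 1), dplyr::mutate(pr, side = -1, r = -.data$r))
  p <- ggplot2::ggplot(both,
                       ggplot2::aes(x = .data$r, y = .data$h,
                                    group = .data$side)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r (nm)", y = "height toward cell interior (nm)") +
    ggplot2::theme_minimal()
  cap <- object$cap
  if (dome && !is_flat_cap(cap)) {
    th <- seq(-cap$alpha, cap$alpha, length.out = 101)
    dome_df <- tibble::tibble(
      r = cap$radius * sin(th),
      h = h0 + cap$radius * (cos(th) - cos(cap$alpha)))
    p <- p + ggplot2::geom_path(data = dome_df,
                                ggplot2::aes(x = .data$r, y = .data$h),
                                inherit.aes = FALSE, colour = "grey40")
  }
  p
}

#' @describeIn monge_footprint Cross-section plot of the linearized
#'   footprint (profile mirrored about the axis).
#' @param object A `monge_footprint`.
#' @export
autoplot.monge_footprint <- function(object, ...) {
  pr <- tidy(object)
  both <- dplyr::bind_rows(
    dplyr::mutate(pr, side = 1), dplyr::mutate(pr, side = -1, r = -.data$r))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$r, y = .data$h,
                                     group = .data$side)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "r (nm)", y = "h (nm)",
                  title = "Small-gradient footprint h(r) = C K0(r/lambda)") +
    ggplot2::theme_minimal()
}

#' Activation and sensitivity plot of a gating curve
#'
#' @param object A [gating_curve()] tibble.
#' @param what `"po"` for the activation curve, `"sensitivity"` for
#'   dPo/dgamma, `"energy"` for the gating energy.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gating_curve <- function(object,
                                  what = c("po", "sensitivity", "energy"),
                                  ...) {
  what <- match.arg(what)
  ycol <- switch(what, po = "po", sensitivity = "dpo_dgamma", energy = "d_g")
  ylab <- switch(what, po = "open probability Po",
                 sensitivity = "dPo/dgamma (nm^2/kBT)",
                 energy = "gating energy (kBT)")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$gamma, y = .data[[ycol]],
                               linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "membrane tension (kBT/nm^2)", y = ylab,
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.gating_curve <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.gating_curve <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$model),
    midpoint_gamma = {
      cross <- which(diff(sign(.data$d_g)) != 0)
      if (length(cross) == 0) NA_real_ else {
        i <- cross[1]
        g1 <- .data$gamma[i]; g2 <- .data$gamma[i + 1]
        e1 <- .data$d_g[i]; e2 <- .data$d_g[i + 1]
        g1 - e1 * (g2 - g1) / (e2 - e1)
      }
    },
    max_dpo_dgamma = max(.data$dpo_dgamma),
    .groups = "drop")
}
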