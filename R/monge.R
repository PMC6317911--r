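#' Small-gradient (Monge) footprint solution
#'
#' In the Monge parametrization the mid-bilayer surface outside the dome is a
#' height function h(r) over the reference plane, and for small gradients the
#' Helfrich energy linearizes to the biharmonic tension-bending equation
#' `Kb laplacian(laplacian h) - gamma laplacian h = 0` on `r >= r0`. The only
#' axisymmetric solution that is bounded, decays to a flat far field, and
#' carries no net vertical force is `h(r) = C K0(r / lambda)` with
#' `lambda = sqrt(Kb/gamma)` the decay length and K0 the zeroth-order
#' modified Bessel function of the second kind. The amplitude follows from
#' matching the meridional slope at the dome rim,
#' `|h'(r0)| = tan(alpha)` (or `sin(alpha)`, see `slope_match`), giving
#' `C = lambda * tan(alpha) / K1(r0/lambda)`.
#'
#' Heights are reported relative to the flat far field (`h -> 0`), measured
#' positive toward the cell interior, the side the dome bulges into; height
#' continuity with the dome fixes only an additive gauge. The linearization
#' is only trustworthy for small slopes; a warning of class
#' `piezodome_large_slope` is raised when the matched rim slope exceeds 0.3,
#' as for the highly curved closed Piezo dome, where the full arclength
#' solver ([solve_footprint()]) is the authoritative method.
#'
#' @param cap A [cap_geometry()].
#' @param membrane A [membrane_spec()]; the tension must be positive (at
#'   zero tension the linear operator is degenerate, with a logarithmic far
#'   field — use [catenoid_reference()] instead).
#' @param slope_match Match the rim slope with `tan(alpha)` (the true
#'   meridional slope dh/dr of the cap, the default) or `sin(alpha)`.
#' @return An object of class `monge_footprint` with fields `amplitude`
#'   (C, nm), `lambda` (nm), `r0` (nm), `slope0` (rim slope magnitude),
#'   `alpha`, `membrane`, `cap`, and sampler functions `h(r)`, `dh(r)`,
#'   `lap(r)` (the surface Laplacian h'' + h'/r).
#' @examples
#' sol <- monge_footprint(cap_geometry(100), membrane_spec(20, 0.1))
#' glance(sol)
#' @export
monge_footprint <- function(cap, membrane, slope_match = c("tan", "sin")) {
  stopifnot(inherits(cap, "cap_geometry"), inherits(membrane, "membrane_spec"))
  slope_match <- match.arg(slope_match)
  if (membrane$tension <= 0) {
    abort(paste0("the linearized problem is degenerate at zero tension ",
                 "(logarithmic far field); use catenoid_reference()."),
          class = "piezodome_zero_tension")
  }
  lambda <- sqrt(membrane$bending_modulus / membrane$tension)
  s0 <- if (slope_match == "tan") tan(cap$alpha) else sin(cap$alpha)
  if (s0 > 0.3) {
    warn(sprintf(
      "rim slope %.3f exceeds 0.3: the small-gradient (Monge) expansion is unreliable here; prefer solve_footprint().",
      s0), class = "piezodome_large_slope")
  }
  x0 <- cap$r0 / lambda
  C <- if (cap$alpha == 0) 0 else lambda * s0 / besselK(x0, 1)
  obj <- list(
    amplitude = C, lambda = lambda, r0 = cap$r0, slope0 = s0,
    alpha = cap$alpha, slope_match = slope_match,
    membrane = membrane, cap = cap,
    h   = function(r) C * besselK(r / lambda, 0),
    dh  = function(r) -(C / lambda) * besselK(r / lambda, 1),
    lap = function(r) (C / lambda^2) * besselK(r / lambda, 0)
  )
  class(obj) <- "monge_footprint"
  obj
}

#' @export
print.monge_footprint <- function(x, ...) {
  cat(sprintf(
    "<monge_footprint> h(r) = C K0(r/lambda), C = %.4g nm, lambda = %.4g nm\n  r0 = %.4g nm, rim slope = %.4g (%s-matched)%s\n",
    x$amplitude, x$lambda, x$r0, x$slope0, x$slope_match,
    if (x$slope0 > 0.3) "  [outside small-gradient regime]" else ""))
  invisible(x)
}

#' Footprint energy in the small-gradient limit
#'
#' Evaluates the linearized Helfrich energy of a [monge_footprint()],
#' `GM = int_{r0}^{inf} [ (Kb/2) (h'' + h'/r)^2 + (gamma/2) h'^2 ] 2 pi r dr`,
#' by adaptive quadrature on `[r0, r0 + 20 lambda]` (the exponential tail
#' beyond is bounded analytically and is negligible at the 1e-8 relative
#' tolerance used).
#'
#' @param sol A `monge_footprint`.
#' @param membrane Optional [membrane_spec()] override; defaults to the one
#'   the solution was built with.
#' @return Energy GM in kBT.
#' @examples
#' monge_energy(monge_footprint(cap_geometry(100), membrane_spec(20, 0.1)))
#' @export
monge_energy <- function(sol, membrane = sol$membrane) {
  stopifnot(inherits(sol, "monge_footprint"))
  if (sol$amplitude == 0) return(0)
  kb <- membrane$bending_modulus
  g <- membrane$tension
  integrand <- function(r) {
    (0.5 * kb * sol$lap(r)^2 + 0.5 * g * sol$dh(r)^2) * 2 * pi * r
  }
  upper <- sol$r0 + 20 * sol$lambda
  q <- integrate(integrand, sol$r0, upper, rel.tol = 1e-10, abs.tol = 0,
                 subdivisions = 400L)
  if (q$message != "OK") {
    abort(sprintf("quadrature failed: %s (abs.error %.3g)", q$message,
                  q$abs.error))
  }
  # analytic tail bound: K0, K1 < sqrt(pi/(2x)) e^-x for x >~ 1, so the
  # neglected tail is < integrand(upper) * lambda; e^-40 makes it irrelevant.
  q$value
}

#' @describeIn monge_footprint Sampled profile as a tibble with columns
#'   `r` (nm), `h` (nm), `slope`, `mean_curv` (1/nm; half the surface
#'   Laplacian in the linearized geometry).
#' @param x A `monge_footprint`.
#' @param n Number of sample points.
#' @param r_max Outer sampling radius; default `r0 + 6 lambda`.
#' @param ... Unused.
#' @export
tidy.monge_footprint <- function(x, n = 201, r_max = x$r0 + 6 * x$lambda, ...) {
  r <- seq(x$r0, r_max, length.out = n)
  tibble::tibble(
    r = r, h = x$h(r), slope = x$dh(r), mean_curv = 0.5 * x$lap(r))
}

#' @describeIn monge_footprint One-row summary: amplitude, decay length,
#'   rim slope, and energy GM.
#' @export
glance.monge_footprint <- function(x, ...) {
  tibble::tibble(
    amplitude = x$amplitude, lambda = x$lambda, r0 = x$r0,
    slope0 = x$slope0, gm = monge_energy(x),
    small_gradient = x$slope0 <= 0.3)
}
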