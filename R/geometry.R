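#' Mechanical state of the lipid bilayer
#'
#' Bundles the two membrane material parameters that control the shape and
#' energy of the membrane footprint: the bending modulus `Kb` and the lateral
#' tension `gamma`. Internally all energies are expressed in units of the
#' thermal energy kBT and all lengths in nm, so `Kb` is in kBT and `gamma` in
#' kBT/nm^2; the temperature enters only when converting tension to mN/m.
#'
#' @param bending_modulus Membrane bending modulus Kb, in kBT. Around 20 kBT
#'   for common phosphatidylcholine bilayers.
#' @param tension Membrane tension gamma, in kBT/nm^2. For orientation,
#'   1 kBT/nm^2 is about 4.114 mN/m at 298 K and bilayer lysis occurs near
#'   3.5 kBT/nm^2; tensions relevant to mechanosensitive gating are well
#'   below that.
#' @param temperature Absolute temperature in kelvin; used only for unit
#'   conversion, never inside the mechanics.
#'
#' @return An object of class `membrane_spec`.
#' @examples
#' membrane_spec(bending_modulus = 20, tension = 0.1)
#' @export
membrane_spec <- function(bending_modulus = 20, tension = 0.1,
                          temperature = 298) {
  if (!is.numeric(bending_modulus) || length(bending_modulus) != 1 ||
      !is.finite(bending_modulus) || bending_modulus <= 0) {
    abort("`bending_modulus` must be a single positive number (kBT).")
  }
  if (!is.numeric(tension) || length(tension) != 1 ||
      !is.finite(tension) || tension < 0) {
    abort("`tension` must be a single non-negative number (kBT/nm^2).")
  }
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be a single positive number (K).")
  }
  structure(
    list(bending_modulus = bending_modulus, tension = tension,
         temperature = temperature),
    class = "membrane_spec"
  )
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf("<membrane_spec> Kb = %g kBT, gamma = %g kBT/nm^2 (%.4g mN/m at %g K)\n",
              x$bending_modulus, x$tension,
              tension_to_mN_per_m(x$tension, x$temperature), x$temperature))
  invisible(x)
}

#' Spherical-cap geometry of the Piezo dome
#'
#' The curved mid-bilayer surface of the Piezo channel (protein plus enclosed
#' lipids) is idealized as a spherical cap of fixed area `area` and radius of
#' curvature `radius`. All derived contact-line quantities follow in closed
#' form: the cap half-angle `alpha` at the contact line from
#' `area = 2 pi radius^2 (1 - cos alpha)`, the in-plane contact radius
#' `r0 = radius sin(alpha)`, the cap height, the projected (in-plane) area
#' `pi r0^2`, and the excess area `area - pi r0^2` — the in-plane area the
#' dome gives up by being curved, on which tension does work.
#'
#' Only sub-hemispherical caps (`area <= 2 pi radius^2`, i.e. `alpha <= pi/2`)
#' are admitted: the contact-line geometry is single-valued there and the
#' closed conformation of Piezo (alpha about 66 degrees) lies safely inside.
#' A planar state (open conformation with infinite radius of curvature) is
#' represented exactly by `radius = Inf` (or [cap_flat()]), not by a large
#' finite radius.
#'
#' @param radius Radius of curvature R of the dome mid-bilayer surface, nm.
#'   `Inf` gives the flat (planar) state.
#' @param area Cap surface area, nm^2. Defaults to 390 nm^2, the measured
#'   area of the closed Piezo dome, and is treated as exactly conserved
#'   between conformations.
#'
#' @return An object of class `cap_geometry` (additionally `flat_cap` when
#'   `radius` is infinite) with fields `radius`, `area`, `alpha`, `r0`,
#'   `height`, `projected_area`, `excess_area`.
#' @examples
#' cap_geometry(10.2)           # closed Piezo dome
#' cap_geometry(Inf)            # flat open state
#' @export
cap_geometry <- function(radius, area = 390) {
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) ||
      radius <= 0) {
    abort("`radius` must be a single positive number (nm), or Inf for a flat state.")
  }
  if (!is.numeric(area) || length(area) != 1 || !is.finite(area) || area <= 0) {
    abort("`area` must be a single positive number (nm^2).")
  }
  if (is.infinite(radius)) return(cap_flat(area))
  if (area > 2 * pi * radius^2 * (1 + 1e-12)) {
    abort(sprintf(
      paste0("cap exceeds a hemisphere: area = %g nm^2 > 2*pi*R^2 = %g nm^2; ",
             "for this area the radius of curvature must be at least %g nm."),
      area, 2 * pi * radius^2, sqrt(area / (2 * pi))))
  }
  # alpha from area = 4 pi R^2 sin^2(alpha/2): stable for near-flat caps,
  # where 1 - cos(alpha) would cancel
  alpha <- 2 * asin(min(sqrt(area / (4 * pi * radius^2)), 1))
  r0 <- radius * sin(alpha)
  structure(
    list(radius = radius, area = area, alpha = alpha, r0 = r0,
         height = 2 * radius * sin(alpha / 2)^2,
         projected_area = pi * r0^2,
         excess_area = max(area - pi * r0^2, 0)),
    class = "cap_geometry"
  )
}

#' @rdname cap_geometry
#' @export
cap_flat <- function(area = 390) {
  r0 <- sqrt(area / pi)
  structure(
    list(radius = Inf, area = area, alpha = 0, r0 = r0, height = 0,
         projected_area = area, excess_area = 0),
    class = c("flat_cap", "cap_geometry")
  )
}

is_flat_cap <- function(cap) inherits(cap, "flat_cap") || cap$alpha == 0

#' @export
print.cap_geometry <- function(x, ...) {
  if (is_flat_cap(x)) {
    cat(sprintf("<cap_geometry> flat state, area = %g nm^2, r0 = %.4g nm\n",
                x$area, x$r0))
  } else {
    cat(sprintf(
      "<cap_geometry> R = %g nm, area = %g nm^2\n  alpha = %.4f rad (%.1f deg), r0 = %.4f nm, height = %.4f nm\n  projected area = %.2f nm^2, excess area = %.2f nm^2\n",
      x$radius, x$area, x$alpha, 180 * x$alpha / pi, x$r0, x$height,
      x$projected_area, x$excess_area))
  }
  invisible(x)
}

#' Dome bending energy
#'
#' Helfrich bending energy of the spherical cap treated as lipid membrane of
#' uniform mean curvature 1/R: `GDb = (Kb/2) (2/R)^2 A = 2 Kb A / R^2`. For
#' the closed Piezo dome (A = 390 nm^2, R = 10.2 nm) this evaluates to about
#' 2.4 pi Kb. Zero for the flat state.
#'
#' @param cap A [cap_geometry()].
#' @param bending_modulus Kb in kBT, or a [membrane_spec()].
#' @return Energy in kBT.
#' @examples
#' dome_bending_energy(cap_geometry(10.2), 20)
#' @export
dome_bending_energy <- function(cap, bending_modulus) {
  stopifnot(inherits(cap, "cap_geometry"))
  kb <- if (inherits(bending_modulus, "membrane_spec")) {
    bending_modulus$bending_modulus
  } else bending_modulus
  if (is_flat_cap(cap)) return(0)
  2 * kb * cap$area / cap$radius^2
}

#' Dome tension energy
#'
#' Work done against membrane tension to form the dome from a planar state:
#' `GDgamma = gamma * excess_area`, the tension times the in-plane area
#' decrease of the cap relative to its flattened shape.
#'
#' @param cap A [cap_geometry()].
#' @param tension gamma in kBT/nm^2, or a [membrane_spec()].
#' @return Energy in kBT.
#' @examples
#' dome_tension_energy(cap_geometry(10.2), 0.1)
#' @export
dome_tension_energy <- function(cap, tension) {
  stopifnot(inherits(cap, "cap_geometry"))
  g <- if (inherits(tension, "membrane_spec")) tension$tension else tension
  if (g < 0) abort("`tension` must be non-negative.")
  g * cap$excess_area
}

#' Characteristic decay length of membrane shape deformations
#'
#' `lambda = sqrt(Kb / gamma)`, the lateral scale over which a deformation
#' of a tense membrane relaxes back to the plane. For Kb = 20 kBT and
#' gamma = 0.1 kBT/nm^2 this is about 14 nm, larger than the Piezo channel
#' itself. At zero tension the linear problem has no finite decay length;
#' `Inf` is returned with a condition of class `piezodome_zero_tension` so
#' callers can switch to the catenoid (zero-tension) description.
#'
#' @param bending_modulus Kb in kBT, or a [membrane_spec()] (in which case
#'   `tension` is taken from it too).
#' @param tension gamma in kBT/nm^2.
#' @return Decay length in nm (`Inf` at zero tension).
#' @examples
#' decay_length(20, 0.1)
#' @export
decay_length <- function(bending_modulus, tension = NULL) {
  if (inherits(bending_modulus, "membrane_spec")) {
    if (is.null(tension)) tension <- bending_modulus$tension
    bending_modulus <- bending_modulus$bending_modulus
  }
  stopifnot(is.numeric(bending_modulus), bending_modulus > 0,
            is.numeric(tension), tension >= 0)
  if (tension == 0) {
    warn("zero membrane tension: decay length is infinite; the footprint approaches a catenoid.",
         class = "piezodome_zero_tension")
    return(Inf)
  }
  sqrt(bending_modulus / tension)
}

#' Convert membrane tension from kBT/nm^2 to mN/m
#'
#' Uses the exact SI Boltzmann constant; at 298 K, 1 kBT/nm^2 = 4.114 mN/m.
#'
#' @param tension gamma in kBT/nm^2 (vectorized).
#' @param temperature Kelvin.
#' @return Tension in mN/m.
#' @examples
#' tension_to_mN_per_m(1)      # 4.114
#' @export
tension_to_mN_per_m <- function(tension, temperature = 298) {
  stopifnot(is.numeric(tension), all(tension >= 0), temperature > 0)
  # kBT [J] / nm^2 -> N/m is a factor 1e18; a further 1e3 gives mN/m.
  tension * .kB * temperature * 1e21
}

#' Membrane compartment diameter
#'
#' Cytoskeleton-bounded membrane compartments constrain the membrane to
#' planarity at their rim. Given the unconstrained membrane arc length `L`
#' between the dome perimeter and the compartment edge (measured radially
#' along the membrane), the compartment diameter is approximated by the
#' in-plane distance, `S = 2 (r0 + L)`. For the closed Piezo dome, L = 5 nm
#' and 10 nm correspond to S of roughly 30 nm and 40 nm. The difference
#' between the arc and its in-plane projection is O(slope^2); when a solved
#' [footprint_profile] is supplied the exact in-plane radius at arc length
#' `L` is used instead.
#'
#' @param cap A [cap_geometry()].
#' @param arc_length Unconstrained arc length L beyond the dome rim, nm.
#' @param profile Optional solved footprint profile; if given, `S` is
#'   computed as twice the profile's in-plane radius at `s = L`.
#' @return Compartment diameter S in nm.
#' @examples
#' compartment_diameter(cap_geometry(10.2), 5)
#' @export
compartment_diameter <- function(cap, arc_length, profile = NULL) {
  stopifnot(inherits(cap, "cap_geometry"), is.numeric(arc_length),
            arc_length >= 0)
  if (!is.null(profile)) {
    tb <- if (inherits(profile, "footprint_profile")) profile$profile else profile
    r_at <- approx(tb$s, tb$r, xout = arc_length, rule = 2)$y
    return(2 * r_at)
  }
  2 * (cap$r0 + arc_length)
}

#' Geometry and dome-energy report for a grid of dome states
#'
#' Tabulates the derived spherical-cap geometry and the closed-form dome
#' energy terms for each row of a parameter grid, in the layout written by
#' the `geometry` CLI subcommand.
#'
#' @param params A data frame with columns `R_nm` and optionally `A_nm2`
#'   (default 390), `Kb_kBT` (default 20), `gamma_kBT_nm2` (default 0.1).
#' @return A tibble with one row per input state: `R_nm, A_nm2, alpha_rad,
#'   r0_nm, height_nm, projArea_nm2, excessArea_nm2, GDb_kBT, GDgamma_kBT`.
#' @examples
#' geometry_table(data.frame(R_nm = c(10.2, 11.2, 20)))
#' @export
geometry_table <- function(params) {
  stopifnot(is.data.frame(params), "R_nm" %in% names(params))
  if (is.null(params$A_nm2)) params$A_nm2 <- 390
  if (is.null(params$Kb_kBT)) params$Kb_kBT <- 20
  if (is.null(params$gamma_kBT_nm2)) params$gamma_kBT_nm2 <- 0.1
  purrr::pmap_dfr(
    params[c("R_nm", "A_nm2", "Kb_kBT", "gamma_kBT_nm2")],
    function(R_nm, A_nm2, Kb_kBT, gamma_kBT_nm2) {
      cap <- cap_geometry(R_nm, A_nm2)
      tibble::tibble(
        R_nm = R_nm, A_nm2 = A_nm2,
        alpha_rad = cap$alpha, r0_nm = cap$r0, height_nm = cap$height,
        projArea_nm2 = cap$projected_area, excessArea_nm2 = cap$excess_area,
        GDb_kBT = dome_bending_energy(cap, Kb_kBT),
        GDgamma_kBT = dome_tension_energy(cap, gamma_kBT_nm2))
    })
}
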