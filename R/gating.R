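#' Two-state gating scenario
#'
#' Pairs a closed and an open dome conformation with a membrane state and an
#' (unknown, externally supplied or calibrated) protein energy difference
#' `delta_gdp`. The total gating energy at tension gamma decomposes as
#' `dG = delta_gdp + dGDb + dGDgamma + dGM`, each membrane term being the
#' open-state value minus the closed-state value of the corresponding term
#' of `G = GDP + GDb + GDgamma + GM`. A flat open state (`Ro -> Inf`,
#' [cap_flat()]) has all membrane terms identically zero.
#'
#' @param closed_cap Closed-state [cap_geometry()] (radius Rc).
#' @param open_cap Open-state [cap_geometry()]; use [cap_flat()] for a flat
#'   open state. The closed state must be the more curved one (Rc < Ro).
#' @param membrane A [membrane_spec()] (its `tension` field is ignored;
#'   tension is always passed per evaluation).
#' @param delta_gdp Protein energy difference open minus closed, kBT.
#' @param compartment A [compartment_spec()].
#' @param control A [footprint_control()].
#' @return An object of class `gating_scenario`.
#' @examples
#' gating_scenario(cap_geometry(10.2), cap_flat(), membrane_spec(20, 0.1))
#' @export
gating_scenario <- function(closed_cap, open_cap, membrane, delta_gdp = 0,
                            compartment = compartment_infinite(),
                            control = footprint_control()) {
  stopifnot(inherits(closed_cap, "cap_geometry"),
            inherits(open_cap, "cap_geometry"),
            inherits(membrane, "membrane_spec"))
  if (closed_cap$radius >= open_cap$radius) {
    abort("the closed state must be more curved than the open state (Rc < Ro).")
  }
  structure(list(closed = closed_cap, open = open_cap, membrane = membrane,
                 delta_gdp = delta_gdp, compartment = compartment,
                 control = control),
            class = "gating_scenario")
}

#' @export
print.gating_scenario <- function(x, ...) {
  ro <- if (is_flat_cap(x$open)) "Inf (flat)" else sprintf("%g nm", x$open$radius)
  cat(sprintf(
    "<gating_scenario> Rc = %g nm -> Ro = %s, A = %g nm^2\n  Kb = %g kBT, deltaGDP = %g kBT, compartment: %s\n",
    x$closed$radius, ro, x$closed$area, x$membrane$bending_modulus,
    x$delta_gdp, if (x$compartment$mode == "finite")
      sprintf("finite (L = %g nm)", x$compartment$L) else "infinite"))
  invisible(x)
}

.membrane_at <- function(scenario, gamma) {
  membrane_spec(scenario$membrane$bending_modulus, gamma,
                scenario$membrane$temperature)
}

# Footprint energy breakdown of one state at one tension, with the gamma = 0
# catenoid limit (GM = 0) handled analytically.
.state_footprint <- function(cap, membrane, compartment, control) {
  if (is_flat_cap(cap)) {
    return(tibble::tibble(gm = 0, bending_part = 0, tension_part = 0,
                          excess_area = 0))
  }
  if (membrane$tension == 0 && compartment$mode == "infinite") {
    # catenoid limit: zero mean curvature everywhere and no tension work
    return(tibble::tibble(gm = 0, bending_part = 0, tension_part = 0,
                          excess_area = NA_real_))
  }
  footprint_energy(solve_footprint(cap, membrane, compartment, control))
}

#' Gating energy decomposition at one tension
#'
#' Applies the total-energy decomposition `G = GDP + GDb + GDgamma + GM` to
#' the open and closed conformations and differences them. At zero tension
#' on an infinite membrane the footprint is of no energetic consequence
#' (`dGM = 0`, catenoid limit) and `dGDgamma = 0`.
#'
#' @param scenario A [gating_scenario()].
#' @param gamma Membrane tension, kBT/nm^2 (vectorized).
#' @return A tibble with one row per tension: `gamma`, per-state energies
#'   (`gdb_closed`, `gdgamma_closed`, `gm_closed` and open analogues), the
#'   differences `d_gdb`, `d_gdgamma`, `d_gm`, and total `d_g` (including
#'   `delta_gdp`).
#' @examples
#' \donttest{
#' sc <- gating_scenario(cap_geometry(10.2), cap_flat(), membrane_spec(20))
#' gating_energy(sc, 0.1)
#' }
#' @export
gating_energy <- function(scenario, gamma) {
  stopifnot(inherits(scenario, "gating_scenario"), is.numeric(gamma),
            all(gamma >= 0))
  kb <- scenario$membrane$bending_modulus
  # solve in decreasing tension order so the continuation is warm-started
  ord <- order(gamma, decreasing = TRUE)
  rows <- vector("list", length(gamma))
  for (i in ord) {
    g <- gamma[i]
    mem <- .membrane_at(scenario, g)
    fc <- .state_footprint(scenario$closed, mem, scenario$compartment,
                           scenario$control)
    fo <- .state_footprint(scenario$open, mem, scenario$compartment,
                           scenario$control)
    gdb_c <- dome_bending_energy(scenario$closed, kb)
    gdb_o <- dome_bending_energy(scenario$open, kb)
    gdg_c <- dome_tension_energy(scenario$closed, g)
    gdg_o <- dome_tension_energy(scenario$open, g)
    rows[[i]] <- tibble::tibble(
      gamma = g,
      gdb_closed = gdb_c, gdgamma_closed = gdg_c, gm_closed = fc$gm,
      gdb_open = gdb_o, gdgamma_open = gdg_o, gm_open = fo$gm,
      dam_closed = fc$excess_area, dam_open = fo$excess_area,
      d_gdb = gdb_o - gdb_c,
      d_gdgamma = gdg_o - gdg_c,
      d_gm = fo$gm - fc$gm,
      d_g = scenario$delta_gdp + (gdb_o - gdb_c) + (gdg_o - gdg_c) +
        (fo$gm - fc$gm))
  }
  dplyr::bind_rows(rows)
}

#' Two-state open probability
#'
#' Boltzmann open probability of the two-state gating equilibrium,
#' `Po / (1 - Po) = exp(-dG / kBT)`, i.e. `Po = 1 / (1 + exp(dG))` with dG
#' in kBT. Evaluated in the log domain, numerically stable for |dG| of
#' hundreds of kBT.
#'
#' @param d_g Gating energy difference open minus closed, kBT (vectorized).
#' @return Open probability in (0, 1).
#' @examples
#' open_probability(0)        # 0.5
#' open_probability(log(9))   # 0.1
#' @export
open_probability <- function(d_g) {
  stopifnot(is.numeric(d_g), all(is.finite(d_g)))
  stats::plogis(-d_g)
}

#' Tension sensitivity of gating
#'
#' How steeply the gating energy changes with tension, `d(dG)/dgamma`
#' (nm^2), and the resulting slope of the activation curve,
#' `dPo/dgamma = -Po (1 - Po) d(dG)/dgamma` (nm^2/kBT). The dome part is
#' exactly the constant `-(excess_closed - excess_open)` of the cap
#' geometries. The footprint part uses, by default, the envelope identity
#' `dGM/dgamma = DeltaA_M` of the minimizing profile (exact at the minimum);
#' `method = "fd"` verifies it by central finite differences of the solved
#' energies.
#'
#' @param scenario A [gating_scenario()].
#' @param gamma Tension(s), kBT/nm^2; positive.
#' @param method `"envelope"` (default) or `"fd"`.
#' @param step Relative step for the finite-difference mode.
#' @return A tibble: `gamma`, `d_dg_dgamma` (nm^2), its `dome_part` and
#'   `footprint_part`, `po`, `dpo_dgamma`.
#' @export
tension_sensitivity <- function(scenario, gamma, method = c("envelope", "fd"),
                                step = 1e-2) {
  method <- match.arg(method)
  stopifnot(all(gamma > 0))
  dome_part <- scenario$open$excess_area - scenario$closed$excess_area
  en <- gating_energy(scenario, gamma)
  if (method == "envelope") {
    foot_part <- ifelse(is.na(en$dam_open), 0, en$dam_open) -
      ifelse(is.na(en$dam_closed), 0, en$dam_closed)
  } else {
    if (any(gamma * (1 - step) <= 0)) {
      abort("finite-difference step too large: gamma - step must stay positive.")
    }
    ep <- gating_energy(scenario, gamma * (1 + step))
    em <- gating_energy(scenario, gamma * (1 - step))
    foot_part <- (ep$d_gm - em$d_gm) / (2 * gamma * step)
  }
  sens <- dome_part + foot_part
  po <- open_probability(en$d_g)
  tibble::tibble(gamma = gamma, d_dg_dgamma = sens, dome_part = dome_part,
                 footprint_part = foot_part, po = po,
                 dpo_dgamma = -po * (1 - po) * sens)
}

#' Calibrate the protein energy offset
#'
#' The protein contribution `deltaGDP` to the gating energy is not known
#' independently, so the gating midpoint is not a model prediction; instead
#' `deltaGDP` is chosen so that the activation curve crosses Po = 0.5 at a
#' user-supplied tension `gamma_half`. Because `deltaGDP` enters the gating
#' energy additively, the calibration is exact:
#' `deltaGDP = -(dGDb + dGDgamma + dGM)` evaluated at `gamma_half` (for a
#' dome-only model, without the `dGM` term).
#'
#' @param scenario A [gating_scenario()] (its current `delta_gdp` is
#'   ignored).
#' @param gamma_half Desired midpoint tension, kBT/nm^2; positive.
#' @param include_footprint Calibrate the full model (default) or the
#'   dome-only model.
#' @return The calibrated `deltaGDP` in kBT.
#' @examples
#' \donttest{
#' sc <- gating_scenario(cap_geometry(10.2), cap_flat(), membrane_spec(20))
#' calibrate_delta_gdp(sc, 0.05)
#' }
#' @export
calibrate_delta_gdp <- function(scenario, gamma_half,
                                include_footprint = TRUE) {
  stopifnot(inherits(scenario, "gating_scenario"), is.numeric(gamma_half),
            length(gamma_half) == 1, gamma_half > 0)
  en <- gating_energy(scenario, gamma_half)
  membrane_part <- en$d_gdb + en$d_gdgamma +
    if (include_footprint) en$d_gm else 0
  -membrane_part
}

#' Gating curve over a tension grid
#'
#' Evaluates the full gating energetics, open probability and tension
#' sensitivity over a tension grid, side by side for the model with the
#' membrane footprint included and for the dome-only model (footprint term
#' dropped), both using the same `delta_gdp`.
#'
#' @param scenario A [gating_scenario()].
#' @param gamma Positive, increasing tension grid, kBT/nm^2.
#' @param models Which variants to evaluate.
#' @return A tibble of class `gating_curve` with one row per (tension,
#'   model): `gamma`, `model`, `d_gdb`, `d_gdgamma`, `d_gm`, `d_g`, `po`,
#'   `d_dg_dgamma`, `dpo_dgamma`. The scenario is attached as attribute
#'   `"scenario"`.
#' @examples
#' \donttest{
#' sc <- gating_scenario(cap_geometry(10.2), cap_flat(), membrane_spec(20),
#'                       delta_gdp = 150)
#' gating_curve(sc, c(0.02, 0.05, 0.1))
#' }
#' @export
gating_curve <- function(scenario, gamma,
                         models = c("with_footprint", "dome_only")) {
  stopifnot(inherits(scenario, "gating_scenario"), is.numeric(gamma),
            all(gamma > 0), !is.unsorted(gamma))
  models <- match.arg(models, several.ok = TRUE)
  en <- gating_energy(scenario, gamma)
  sens <- tension_sensitivity(scenario, gamma)
  out <- purrr::map_dfr(models, function(mod) {
    with_fp <- mod == "with_footprint"
    d_g <- scenario$delta_gdp + en$d_gdb + en$d_gdgamma +
      if (with_fp) en$d_gm else 0
    sl <- sens$dome_part + if (with_fp) sens$footprint_part else 0
    po <- open_probability(d_g)
    tibble::tibble(
      gamma = gamma, model = mod,
      d_gdb = en$d_gdb, d_gdgamma = en$d_gdgamma,
      d_gm = if (with_fp) en$d_gm else 0,
      d_g = d_g, po = po,
      d_dg_dgamma = sl, dpo_dgamma = -po * (1 - po) * sl)
  })
  class(out) <- c("gating_curve", class(out))
  attr(out, "scenario") <- scenario
  out
}
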