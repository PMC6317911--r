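# Two-state gating energetics, open probability, sensitivities.

sc_flat <- gating_scenario(closed_cap, cap_flat(390), membrane_spec(20),
                           control = ctl_fast)

test_that("the Boltzmann relation and its inversion hold over a wide range", {
  expect_identical(open_probability(0), 0.5)
  expect_equal(open_probability(log(9)), 0.1, tolerance = 1e-12)
  expect_equal(open_probability(-log(9)), 0.9, tolerance = 1e-12)
  # inversion identity, checked on the numerically faithful (Po < 1/2)
  # branch; the Po -> 1 branch follows by the symmetry asserted below
  dg <- seq(0, 50, by = 2.5)
  po <- open_probability(dg)
  expect_equal(log(po / (1 - po)), -dg, tolerance = 1e-10)
  expect_equal(open_probability(-dg), 1 - po, tolerance = 1e-12)
  expect_gt(open_probability(700), 0)
  expect_lt(open_probability(700), 1e-100)
})

test_that("gating energy differences combine dome and footprint terms", {
  en <- gating_energy(sc_flat, 0.1)
  expect_equal(en$d_gdb, -dome_bending_energy(closed_cap, 20),
               tolerance = 1e-12)          # about -149.9 kBT
  expect_equal(en$d_gdgamma, -0.1 * closed_cap$excess_area,
               tolerance = 1e-12)          # about -11.6 kBT
  expect_lt(en$d_gm, 0)                    # flat open state has GM = 0
  expect_equal(en$d_g, en$d_gdb + en$d_gdgamma + en$d_gm, tolerance = 1e-12)
  # at zero tension the footprint is of no energetic consequence
  en0 <- gating_energy(sc_flat, 0)
  expect_identical(en0$d_gdgamma, 0)
  expect_identical(en0$d_gm, 0)
})

test_that("identical closed and open states gate on the protein term alone", {
  sc <- gating_scenario(closed_cap, cap_geometry(10.2001, 390),
                        membrane_spec(20), delta_gdp = 3, control = ctl_fast)
  en <- gating_energy(sc, 0.1)
  expect_equal(en$d_gdb, 0, tolerance = 1e-2)
  expect_equal(en$d_gdgamma, 0, tolerance = 1e-3)
  expect_equal(en$d_gm, 0, tolerance = 0.05)
  expect_equal(en$d_g, 3, tolerance = 0.06)
  sens <- tension_sensitivity(sc, 0.1)
  expect_equal(sens$d_dg_dgamma, 0, tolerance = 1)
  expect_error(gating_scenario(closed_cap, cap_geometry(9, 390),
                               membrane_spec(20)))
})

test_that("tension sensitivity: constant dome part, diverging footprint part", {
  sens <- tension_sensitivity(sc_flat, c(0.005, 0.05))
  expect_equal(sens$dome_part, rep(-closed_cap$excess_area, 2),
               tolerance = 1e-12)
  # footprint sensitivity magnitude larger at the smaller tension
  expect_gt(abs(sens$footprint_part[1]), abs(sens$footprint_part[2]))
  expect_true(all(sens$d_dg_dgamma < 0))   # tension favors the open state
  # envelope identity against finite differences of the solved energies
  s_env <- tension_sensitivity(sc_flat, 0.05, method = "envelope")
  s_fd <- tension_sensitivity(sc_flat, 0.05, method = "fd")
  expect_equal(s_env$d_dg_dgamma, s_fd$d_dg_dgamma, tolerance = 0.01)
  # monotone divergence toward gamma -> 0 on a log grid
  gg <- 10^seq(-3, -1, length.out = 7)
  sl <- tension_sensitivity(sc_flat, gg)
  expect_true(all(diff(abs(sl$footprint_part)) < 0))
})

test_that("calibration pins the activation midpoint exactly", {
  for (gh in c(0.03, 0.08)) {
    dgp <- calibrate_delta_gdp(sc_flat, gh)
    sc <- sc_flat
    sc$delta_gdp <- dgp
    expect_equal(open_probability(gating_energy(sc, gh)$d_g), 0.5,
                 tolerance = 1e-6)
    # membrane terms favor the open state, so the protein must stabilize
    # the closed state
    expect_gt(dgp, 0)
  }
  # a higher midpoint tension needs a larger protein offset
  expect_gt(calibrate_delta_gdp(sc_flat, 0.08),
            calibrate_delta_gdp(sc_flat, 0.03))
})

test_that("the membrane footprint left-shifts and steepens the activation curve", {
  dgp <- calibrate_delta_gdp(sc_flat, 0.06, include_footprint = FALSE)
  sc <- sc_flat
  sc$delta_gdp <- dgp    # dome-only model calibrated to gate at 0.06
  gg <- seq(0.005, 0.12, by = 0.005)
  curve <- gating_curve(sc, gg)
  gl <- glance(curve)
  mid_fp <- gl$midpoint_gamma[gl$model == "with_footprint"]
  mid_dome <- gl$midpoint_gamma[gl$model == "dome_only"]
  expect_lt(mid_fp, mid_dome)              # left shift
  expect_gt(gl$max_dpo_dgamma[gl$model == "with_footprint"],
            gl$max_dpo_dgamma[gl$model == "dome_only"])   # steepening
  # Po is monotone in tension and within (0, 1)
  for (mod in unique(curve$model)) {
    po <- curve$po[curve$model == mod]
    expect_true(all(po > 0 & po <= 1))
    expect_true(all(diff(po) >= 0))
  }
  expect_true(all(curve$dpo_dgamma >= 0))
})

test_that("there is a tension range where the footprint term rivals the dome term", {
  scenarios <- list(
    gating_scenario(closed_cap, cap_flat(390), membrane_spec(20),
                    control = ctl_fast),
    gating_scenario(closed_cap, cap_geometry(11.2, 390), membrane_spec(20),
                    control = ctl_fast),
    gating_scenario(cap_geometry(20, 390), cap_flat(390), membrane_spec(20),
                    control = ctl_fast))
  for (sc in scenarios) {
    en <- gating_energy(sc, c(0.01, 0.05, 0.1))
    expect_true(any(abs(en$d_gm) >= abs(en$d_gdgamma)))
  }
})

test_that("membrane stiffness modulates the gating midpoint", {
  mids <- vapply(c(10, 20, 40), function(kb) {
    sc <- gating_scenario(closed_cap, cap_flat(390), membrane_spec(kb),
                          delta_gdp = 310, control = ctl_fast)
    gg <- seq(0.01, 1.2, by = 0.04)
    gl <- glance(gating_curve(sc, gg, models = "with_footprint"))
    gl$midpoint_gamma
  }, numeric(1))
  expect_true(all(is.finite(mids)))
  expect_equal(length(unique(round(mids, 4))), 3)   # midpoint depends on Kb
  # stiffer membranes store more dome bending energy, gating at lower tension
  expect_true(all(diff(mids) < 0))
})
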