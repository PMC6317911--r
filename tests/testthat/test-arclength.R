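# Nonlinear arclength solver: residuals, limits, invariants, compartments.

test_that("the converged profile satisfies the shape-equation system", {
  fp <- solve_footprint(closed_cap, mem_ref, control = ctl_fast)
  expect_lt(fp$diagnostics$residual, 1e-6)
  pr <- fp$profile
  # geometric closure, checked independently of the solver internals
  dr_ds <- diff(pr$r) / diff(pr$s)
  cos_mid <- cos((pr$psi[-1] + pr$psi[-nrow(pr)]) / 2)
  expect_lt(max(abs(dr_ds - cos_mid)), 1e-4)
  dh_ds <- diff(pr$h) / diff(pr$s)
  sin_mid <- sin((pr$psi[-1] + pr$psi[-nrow(pr)]) / 2)
  expect_lt(max(abs(dh_ds + sin_mid)), 1e-4)
  # boundary conditions: smooth attachment at the rim, flat far field
  expect_equal(pr$psi[1], closed_cap$alpha, tolerance = 1e-10)
  expect_equal(pr$r[1], closed_cap$r0, tolerance = 1e-10)
  n <- nrow(pr)
  expect_lt(abs(pr$psi[n]), 1e-8)
  expect_lt(abs(pr$H[n]), 1e-8)
  expect_equal(pr$h[n], 0)
  # footprint decays within a few decay lengths of the rim (the K0 tail
  # of the linear theory predicts ~2% at 3 lambda, <1% at 4 lambda)
  lam <- decay_length(20, 0.1)
  i3 <- which.min(abs(pr$s - 3 * lam))
  expect_lt(abs(pr$h[i3]), 0.05 * abs(pr$h[1]))
  i4 <- which.min(abs(pr$s - 4 * lam))
  expect_lt(abs(pr$h[i4]), 0.015 * abs(pr$h[1]))
})

test_that("a flat dome induces no footprint", {
  fp <- solve_footprint(cap_flat(390), mem_ref, control = ctl_fast)
  expect_true(all(fp$profile$h == 0))
  expect_equal(footprint_energy(fp)$gm, 0)
  expect_error(solve_footprint(closed_cap, membrane_spec(20, 0)),
               class = "piezodome_zero_tension")
})

test_that("the low-tension footprint approaches the catenoid", {
  cc <- closed_cap$r0 * sin(closed_cap$alpha)   # neck constant 8.540 nm
  expect_equal(cc, 8.540151, tolerance = 1e-6)
  devs <- vapply(c(1e-2, 1e-3, 1e-4), function(g) {
    fp <- solve_footprint(closed_cap, membrane_spec(20, g),
                          control = ctl_fast)
    pr <- fp$profile
    i <- pr$s <= 2 * closed_cap$r0
    max(abs(pr$r[i] * sin(pr$psi[i]) - cc))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))          # conservation law tightens
  expect_lt(devs[3], 0.05)                  # r sin(psi) ~ const near the dome
  expect_lt(gm_of(10.2, 1e-4), 0.15)        # and GM -> 0
})

test_that("the catenoid reference is an exact minimal surface", {
  cat_fp <- catenoid_reference(closed_cap)
  pr <- cat_fp$profile
  expect_equal(pr$psi[1], closed_cap$alpha, tolerance = 1e-12)
  # defining property c1 + c2 = 0: azimuthal curvature must cancel the
  # meridional one computed by independent finite differences
  c2 <- sin(pr$psi) / pr$r
  dpsi <- diff(pr$psi) / diff(pr$s)
  c1_mid <- dpsi
  c2_mid <- (c2[-1] + c2[-nrow(pr)]) / 2
  expect_lt(max(abs(c1_mid + c2_mid)), 1e-4)
  expect_true(all(pr$H == 0))
  # conservation law holds to near machine precision
  expect_lt(max(abs(pr$r * sin(pr$psi) - pr$r[1] * sin(pr$psi[1]))), 1e-10)
  e <- footprint_energy(cat_fp, membrane_spec(20, 0))
  expect_identical(e$bending_part, 0)
  expect_identical(e$gm, 0)
})

test_that("GM is non-negative, decreasing in R and increasing in gamma", {
  gm_R <- vapply(c(10.2, 11.2, 15, 20, 40), gm_of, numeric(1), gamma = 0.1)
  expect_true(all(gm_R >= 0))
  expect_true(all(diff(gm_R) < 0))
  gm_g <- vapply(c(0.01, 0.1, 1), function(g) gm_of(10.2, g), numeric(1))
  expect_true(all(diff(gm_g) > 0))
})

test_that("dGM/dgamma equals the footprint excess area (envelope identity)", {
  for (g in c(0.03, 0.1)) {
    dg <- 1e-3
    gp <- gm_of(10.2, g + dg)
    gm <- gm_of(10.2, g - dg)
    fp <- solve_footprint(closed_cap, membrane_spec(20, g),
                          control = ctl_fast)
    dam <- footprint_energy(fp)$excess_area
    expect_equal((gp - gm) / (2 * dg), dam, tolerance = 0.01)
  }
})

test_that("bending energy is scale invariant (lengths x k, gamma / k^2)", {
  gm1 <- gm_of(10.2, 0.2, A = 390)
  gm2 <- gm_of(20.4, 0.05, A = 4 * 390)
  expect_equal(gm2, gm1, tolerance = 1e-6)
})

test_that("Monge overestimates at high curvature and matches at low curvature", {
  # high curvature (closed dome), across the tension range
  for (g in c(0.01, 0.1, 1)) {
    mem <- membrane_spec(20, g)
    gm_m <- monge_energy(suppressWarnings(monge_footprint(closed_cap, mem)))
    expect_gte(gm_m, gm_of(10.2, g))
  }
  for (R in c(10.2, 15.3, 20.4)) {
    mem <- membrane_spec(20, 0.1)
    gm_m <- monge_energy(suppressWarnings(
      monge_footprint(cap_geometry(R, 390), mem)))
    expect_gte(gm_m, gm_of(R, 0.1))
  }
  # small-slope regime: the two solvers agree within 5%
  cmp <- compare_parametrizations(cap_geometry(100, 390), mem_ref,
                                  control = ctl_fast)
  expect_lt(abs(cmp$rel_diff), 0.05)
  expect_identical(cmp$larger, "monge")
  expect_lt(cmp$max_h_dev, 0.05)
})

test_that("finite compartments raise GM, more so when smaller and at low tension", {
  res <- expand.grid(gamma = c(0.01, 0.5), L = c(5, 10, Inf))
  res$gm <- mapply(function(g, L) gm_of(10.2, g, L = L), res$gamma, res$L)
  for (g in c(0.01, 0.5)) {
    gm5 <- res$gm[res$gamma == g & res$L == 5]
    gm10 <- res$gm[res$gamma == g & res$L == 10]
    gminf <- res$gm[res$gamma == g & is.infinite(res$L)]
    expect_gte(gm5, gm10)
    expect_gte(gm10, gminf)
  }
  # compartment effect (excess over the infinite membrane) is larger in the
  # low-tension regime
  excess <- function(g, L) res$gm[res$gamma == g & res$L == L] -
    res$gm[res$gamma == g & is.infinite(res$L)]
  expect_gt(excess(0.01, 5), excess(0.5, 5))
  expect_gt(excess(0.01, 10), excess(0.5, 10))
})

test_that("a large finite compartment converges to the infinite solution", {
  g <- 0.5   # lambda = 6.3 nm, so L = 60 nm is ~10 decay lengths
  gm_fin <- gm_of(10.2, g, L = 60,
                  control = footprint_control(n_finite = 240L))
  gm_inf <- gm_of(10.2, g)
  expect_equal(gm_fin, gm_inf, tolerance = 0.02)
})

test_that("zero tension is admissible in a compartment and costs bending energy", {
  gm0 <- gm_of(10.2, 0, L = 5)
  expect_gt(gm0, 0)       # clamped planarity frustrates the catenoid
  expect_gt(gm0, gm_of(10.2, 0, L = 10))
})

test_that("multistart minimization is reproducible and records candidates", {
  ctl <- footprint_control(n_finite = 40L, starts = 3L, seed = 7L)
  fp1 <- solve_footprint(closed_cap, membrane_spec(20, 0.1),
                         compartment_finite(5), ctl)
  fp2 <- solve_footprint(closed_cap, membrane_spec(20, 0.1),
                         compartment_finite(5), ctl)
  expect_identical(fp1$profile, fp2$profile)
  expect_length(fp1$diagnostics$candidates, 3L)
  spread <- diff(range(fp1$diagnostics$candidates))
  expect_lt(spread / min(fp1$diagnostics$candidates), 1e-4)
})
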