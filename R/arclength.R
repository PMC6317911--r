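#' Compartment specification
#'
#' The footprint is solved either on an effectively infinite membrane that
#' flattens far from the channel, or inside a finite membrane compartment
#' (e.g. a cytoskeletal corral) whose rim, an unconstrained arc length `L`
#' beyond the dome perimeter, clamps the membrane to planarity.
#'
#' @param mode `"infinite"` or `"finite"`.
#' @param L Unconstrained arc length beyond the dome rim, nm (finite mode).
#' @return An object of class `compartment_spec`.
#' @examples
#' compartment_infinite()
#' compartment_finite(5)
#' @export
compartment_spec <- function(mode = c("infinite", "finite"), L = NULL) {
  mode <- match.arg(mode)
  if (mode == "finite") {
    if (!is.numeric(L) || length(L) != 1 || !is.finite(L) || L <= 0) {
      abort("finite compartments need a positive unconstrained arc length `L` (nm).")
    }
  } else {
    L <- Inf
  }
  structure(list(mode = mode, L = L), class = "compartment_spec")
}

#' @rdname compartment_spec
#' @export
compartment_infinite <- function() compartment_spec("infinite")

#' @rdname compartment_spec
#' @export
compartment_finite <- function(L) compartment_spec("finite", L = L)

#' Solver settings for the footprint solvers
#'
#' @param n Number of mesh intervals for the infinite-membrane relaxation
#'   solver (graded mesh, fine at the dome rim).
#' @param n_finite Number of mesh intervals for the finite-compartment
#'   direct minimizer (uniform mesh).
#' @param cutoff Domain cutoff for the infinite case, in units of the decay
#'   length lambda; the domain is `s_max = max(cutoff * lambda, 5 * r0)`.
#' @param tol Convergence tolerance on the maximum residual of the
#'   discretized shape-equation system (tension-scaled variables).
#' @param max_iter Maximum damped-Newton iterations per continuation step.
#' @param starts Number of starts for the finite-compartment direct
#'   minimizer; starts beyond the first perturb the initial profile.
#' @param seed Seed used for the multistart perturbations; recorded in the
#'   solution metadata.
#' @return A list of class `footprint_control`.
#' @export
footprint_control <- function(n = 600L, n_finite = 80L, cutoff = 12,
                              tol = 1e-10, max_iter = 40L, starts = 1L,
                              seed = 1L) {
  stopifnot(n >= 20, n_finite >= 10, cutoff > 0, tol > 0, max_iter >= 1,
            starts >= 1)
  structure(list(n = as.integer(n), n_finite = as.integer(n_finite),
                 cutoff = cutoff, tol = tol, max_iter = as.integer(max_iter),
                 starts = as.integer(starts), seed = as.integer(seed)),
            class = "footprint_control")
}

# ---------------------------------------------------------------------------
# Tension-scaled first-order system for the axisymmetric shape equation.
# Variables y = (rho, psi, m, u) with rho = r/lambda, m = H*lambda,
# u = dm/dt, t = s/lambda:
#   rho' = cos psi
#   psi' = 2 m - sin(psi)/rho
#   m'   = u
#   u'   = -(cos psi / rho) u + m + 2 m (m^2 - kg),
# where kg = psi' * sin(psi)/rho is the scaled Gaussian curvature. This is
# the zero-pressure, zero-spontaneous-curvature Helfrich shape equation
# surface_laplacian(H) = (gamma/Kb) H - 2 H (H^2 - K) written in arclength.
# ---------------------------------------------------------------------------

.shape_rhs <- function(y) {
  rho <- y[, 1]; psi <- y[, 2]; m <- y[, 3]; u <- y[, 4]
  sp <- sin(psi); cp <- cos(psi)
  f2 <- 2 * m - sp / rho
  kg <- f2 * sp / rho
  cbind(cp, f2, u, -cp * u / rho + m - 2 * m * (m^2 - kg))
}

# Per-node 4x4 Jacobian entries of .shape_rhs, returned as a list of
# vectors J[[k]][[l]] = d f_k / d y_l.
.shape_jac <- function(y) {
  rho <- y[, 1]; psi <- y[, 2]; m <- y[, 3]; u <- y[, 4]
  sp <- sin(psi); cp <- cos(psi)
  kg <- (2 * m - sp / rho) * sp / rho
  dkg_rho <- -2 * m * sp / rho^2 + 2 * sp^2 / rho^3
  dkg_psi <- 2 * m * cp / rho - 2 * sp * cp / rho^2
  dkg_m <- 2 * sp / rho
  z <- numeric(length(rho))
  list(
    list(z, -sp, z, z),
    list(sp / rho^2, -cp / rho, z + 2, z),
    list(z, z, z, z + 1),
    list(cp * u / rho^2 + 2 * m * dkg_rho,
         sp * u / rho + 2 * m * dkg_psi,
         1 - 6 * m^2 + 2 * kg + 2 * m * dkg_m,
         -cp / rho)
  )
}

# Residual of the trapezoidal collocation system plus boundary conditions.
# Y: (n+1) x 4 matrix of node values; returns vector of length 4(n+1).
.collocation_residual <- function(Y, tmesh, rho0, alpha) {
  n <- length(tmesh) - 1L
  if (any(Y[, 1] <= 0)) return(rep(Inf, 4L * (n + 1L)))
  FF <- .shape_rhs(Y)
  h <- diff(tmesh)
  D <- Y[-1L, , drop = FALSE] - Y[-(n + 1L), , drop = FALSE] -
    (h / 2) * (FF[-1L, , drop = FALSE] + FF[-(n + 1L), , drop = FALSE])
  c(t(D), Y[1L, 1L] - rho0, Y[1L, 2L] - alpha, Y[n + 1L, 2L], Y[n + 1L, 3L])
}

.collocation_jacobian <- function(Y, tmesh) {
  n <- length(tmesh) - 1L
  h <- diff(tmesh)
  J <- .shape_jac(Y)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  idx <- seq_len(n)             # interval index 1..n
  for (k in 1:4) {
    rows <- 4L * (idx - 1L) + k
    for (l in 1:4) {
      Jkl <- J[[k]][[l]]
      # d R_i / d y_i  = -I - (h/2) J(y_i)
      ii <- c(ii, rows); jj <- c(jj, 4L * (idx - 1L) + l)
      xx <- c(xx, -(k == l) - (h / 2) * Jkl[idx])
      # d R_i / d y_{i+1} = I - (h/2) J(y_{i+1})
      ii <- c(ii, rows); jj <- c(jj, 4L * idx + l)
      xx <- c(xx, (k == l) - (h / 2) * Jkl[idx + 1L])
    }
  }
  nr <- 4L * (n + 1L)
  ii <- c(ii, nr - 3L, nr - 2L, nr - 1L, nr)
  jj <- c(jj, 1L, 2L, 4L * n + 2L, 4L * n + 3L)
  xx <- c(xx, 1, 1, 1, 1)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nr, nr))
}

# Damped Newton on the collocation system. Returns list(Y, residual,
# iterations, converged).
.newton_solve <- function(Y, tmesh, rho0, alpha, tol, max_iter) {
  res <- .collocation_residual(Y, tmesh, rho0, alpha)
  rnorm <- max(abs(res))
  iter <- 0L
  while (rnorm > tol && iter < max_iter) {
    iter <- iter + 1L
    J <- .collocation_jacobian(Y, tmesh)
    step <- tryCatch(as.numeric(Matrix::solve(J, -res)),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    Sm <- matrix(step, ncol = 4, byrow = TRUE)
    d <- 1
    improved <- FALSE
    for (ls in 1:14) {
      Ytry <- Y + d * Sm
      rtry <- .collocation_residual(Ytry, tmesh, rho0, alpha)
      rtnorm <- max(abs(rtry))
      if (is.finite(rtnorm) && rtnorm < rnorm) {
        Y <- Ytry; res <- rtry; rnorm <- rtnorm; improved <- TRUE
        break
      }
      d <- d / 2
    }
    if (!improved) break
  }
  list(Y = Y, residual = rnorm, iterations = iter, converged = rnorm <= tol)
}

# Graded mesh on [0, T], geometric-like refinement near t = 0 with inner
# scale min(rho0, 1).
.graded_mesh <- function(rho0, T, n) {
  g <- min(rho0, 1)
  v <- seq(0, log1p(T / g), length.out = n + 1L)
  t <- g * expm1(v)
  t[1L] <- 0
  t[n + 1L] <- T
  t
}

# Initial guess on a mesh: exponentially decaying tangent angle with a
# catenoid-like 1/r factor, then consistent rho, m, u.
.initial_guess <- function(tmesh, rho0, alpha) {
  psi <- alpha * exp(-tmesh) * rho0 / (rho0 + tmesh)
  .state_from_psi(tmesh, psi, rho0)
}

# Build a consistent (rho, psi, m, u) state from a tangent-angle profile.
.state_from_psi <- function(tmesh, psi, rho0) {
  cp <- cos(psi)
  rho <- rho0 + cumsum(c(0, diff(tmesh) * (cp[-1] + cp[-length(cp)]) / 2))
  dpsi <- .fd_gradient(psi, tmesh)
  m <- (dpsi + sin(psi) / rho) / 2
  u <- .fd_gradient(m, tmesh)
  cbind(rho, psi, m, u)
}

# Central finite-difference gradient on a nonuniform grid.
.fd_gradient <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

# Solve the scaled infinite-membrane problem at contact radius rho0 (in
# units of lambda), with continuation from rho0 = 1 when rho0 is small and
# in the contact angle when the direct guess fails.
.solve_scaled_infinite <- function(rho0, alpha, control) {
  Tdom <- function(r0s) max(control$cutoff, 5 * r0s)
  solve_at <- function(rho0k, alpha_k, Y0, tmesh) {
    .newton_solve(Y0, tmesh, rho0k, alpha_k, control$tol, control$max_iter)
  }
  # continuation schedule in rho0 (from 1 down, factors of 2)
  rho_seq <- if (rho0 >= 0.8) rho0 else {
    k <- floor(log2(1 / rho0))
    unique(c(2^-(0:k), rho0))
  }
  sol <- NULL
  tprev <- NULL
  total_iter <- 0L
  for (rk in rho_seq) {
    tmesh <- .graded_mesh(rk, Tdom(rk), control$n)
    if (is.null(sol)) {
      Y0 <- .initial_guess(tmesh, rk, alpha)
      out <- solve_at(rk, alpha, Y0, tmesh)
      if (!out$converged) {
        # fall back to continuation in the contact angle
        Yc <- .initial_guess(tmesh, rk, alpha / 4)
        for (ak in alpha * c(0.25, 0.5, 0.75, 1)) {
          out <- solve_at(rk, ak, Yc, tmesh)
          total_iter <- total_iter + out$iterations
          if (!out$converged) break
          Yc <- out$Y
        }
      }
    } else {
      # warm start: interpolate previous scaled solution onto the new mesh
      psi <- approx(tprev, sol$Y[, 2], xout = tmesh, rule = 2)$y
      psi[length(psi)] <- 0
      Y0 <- .state_from_psi(tmesh, psi, rk)
      out <- solve_at(rk, alpha, Y0, tmesh)
    }
    total_iter <- total_iter + out$iterations
    if (!out$converged) {
      abort(sprintf(
        paste0("footprint solver did not converge (residual %.3g at ",
               "rho0 = %.4g after %d iterations); try a finer mesh or more ",
               "iterations via footprint_control()."),
        out$residual, rk, out$iterations),
        class = "piezodome_solver_error")
    }
    if (any(out$Y[, 1] <= 0)) {
      abort("geometric failure: in-plane radius pinched to zero (neck pinch).",
            class = "piezodome_neck_pinch")
    }
    sol <- out
    tprev <- tmesh
  }
  list(tmesh = tprev, Y = sol$Y, residual = sol$residual,
       iterations = total_iter)
}

#' Minimum-energy membrane footprint (nonlinear arclength solver)
#'
#' Computes the shape of the lipid membrane surrounding the Piezo dome that
#' minimizes the Helfrich energy
#' `GM = (Kb/2) int (c1 + c2)^2 dA + gamma * DeltaA`
#' in the axisymmetric arclength parametrization, which remains valid at the
#' large membrane slopes produced by a highly curved dome. The membrane
#' attaches smoothly to the dome rim (`psi(0) = alpha`, `r(0) = r0`).
#'
#' For an infinite membrane the Euler-Lagrange (shape) equation
#' `surface_laplacian(H) = (gamma/Kb) H - 2 H (H^2 - K)` is solved as a
#' first-order system in tension-scaled variables by damped-Newton
#' relaxation on a graded trapezoidal collocation mesh, with far-field
#' conditions `psi = 0`, `H = 0` at a cutoff of several decay lengths and
#' continuation in `r0/lambda` into the stiff low-tension regime.
#'
#' For a finite compartment the energy functional is minimized directly over
#' endpoint-constrained tangent-angle profiles (`psi(0) = alpha`,
#' `psi(L) = 0`, rim clamped to the plane; the dome's vertical position is
#' free, so the remaining boundary behaviour emerges from the variational
#' principle). Zero tension is admissible there; on an infinite membrane
#' zero tension has no finite-energy minimizer with a flat far field (the
#' shape approaches a catenoid, see [catenoid_reference()]) and is refused.
#'
#' Heights are measured from the far-field (or rim) plane, positive toward
#' the cell interior, the side the dome bulges into.
#'
#' @param cap A [cap_geometry()].
#' @param membrane A [membrane_spec()].
#' @param compartment A [compartment_spec()]; default infinite.
#' @param control A [footprint_control()].
#' @return An object of class `footprint_profile`: list with `profile` (a
#'   tibble with columns `s`, `r`, `h` in nm, `psi` in radians, `H` in 1/nm),
#'   the inputs, and `diagnostics` (method, residual or gradient norm,
#'   iterations, seed, candidate energies for multistarts).
#' @examples
#' \donttest{
#' fp <- solve_footprint(cap_geometry(10.2), membrane_spec(20, 0.1))
#' glance(fp)
#' }
#' @export
solve_footprint <- function(cap, membrane,
                            compartment = compartment_infinite(),
                            control = footprint_control()) {
  stopifnot(inherits(cap, "cap_geometry"), inherits(membrane, "membrane_spec"),
            inherits(compartment, "compartment_spec"),
            inherits(control, "footprint_control"))
  if (is_flat_cap(cap)) {
    return(.planar_profile(cap, membrane, compartment, control))
  }
  if (compartment$mode == "infinite") {
    if (membrane$tension <= 0) {
      abort(paste0("an infinite membrane at zero tension has no finite-energy ",
                   "minimizer with a flat far field; the footprint approaches ",
                   "a catenoid (see catenoid_reference())."),
            class = "piezodome_zero_tension")
    }
    .solve_infinite(cap, membrane, control)
  } else {
    .solve_finite(cap, membrane, compartment, control)
  }
}

.planar_profile <- function(cap, membrane, compartment, control) {
  smax <- if (compartment$mode == "finite") compartment$L else {
    if (membrane$tension > 0) {
      control$cutoff * decay_length(membrane$bending_modulus, membrane$tension)
    } else 5 * cap$r0
  }
  s <- seq(0, smax, length.out = 201L)
  structure(list(
    profile = tibble::tibble(s = s, r = cap$r0 + s, h = 0 * s, psi = 0 * s,
                             H = 0 * s),
    cap = cap, membrane = membrane, compartment = compartment,
    diagnostics = list(method = "planar", residual = 0, iterations = 0L,
                       seed = control$seed, candidates = 0)),
    class = "footprint_profile")
}

.solve_infinite <- function(cap, membrane, control) {
  lambda <- sqrt(membrane$bending_modulus / membrane$tension)
  rho0 <- cap$r0 / lambda
  sc <- .solve_scaled_infinite(rho0, cap$alpha, control)
  s <- sc$tmesh * lambda
  r <- sc$Y[, 1] * lambda
  psi <- sc$Y[, 2]
  H <- sc$Y[, 3] / lambda
  # height by integrating dh/ds = -sin(psi) inward from the flat far field
  sp <- sin(psi)
  seg <- diff(s) * (sp[-1] + sp[-length(sp)]) / 2
  h <- rev(cumsum(rev(c(seg, 0))))
  structure(list(
    profile = tibble::tibble(s = s, r = r, h = h, psi = psi, H = H),
    cap = cap, membrane = membrane, compartment = compartment_infinite(),
    diagnostics = list(method = "arclength-relaxation", residual = sc$residual,
                       iterations = sc$iterations, seed = control$seed,
                       candidates = NULL)),
    class = "footprint_profile")
}

# Discrete energy of a tangent-angle profile on a uniform mesh over [0, L]
# (midpoint scheme). psi: full node vector including endpoints.
.finite_energy <- function(psi, ds, r0, kb, g) {
  pm <- (psi[-1] + psi[-length(psi)]) / 2
  dpsi <- diff(psi) / ds
  cm <- cos(pm)
  redge <- r0 + cumsum(c(0, ds * cm))
  rm <- (redge[-1] + redge[-length(redge)]) / 2
  sum(ds * (pi * kb * (dpsi + sin(pm) / rm)^2 * rm +
              2 * pi * g * rm * (1 - cm)))
}

.solve_finite <- function(cap, membrane, compartment, control) {
  L <- compartment$L
  n <- control$n_finite
  ds <- L / n
  kb <- membrane$bending_modulus
  g <- membrane$tension
  alpha <- cap$alpha
  r0 <- cap$r0
  obj <- function(theta) {
    psi <- c(alpha, theta, 0)
    redge <- r0 + cumsum(c(0, ds * cos((psi[-1] + psi[-length(psi)]) / 2)))
    if (any(redge <= 0)) return(1e12)
    .finite_energy(psi, ds, r0, kb, g)
  }
  base_guess <- alpha * (1 - seq_len(n - 1) / n)
  guesses <- list(base_guess)
  if (control$starts > 1L) {
    seed_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(control$seed)
    for (k in seq_len(control$starts - 1L)) {
      guesses[[k + 1L]] <- pmax(pmin(
        base_guess + stats::rnorm(n - 1, sd = 0.1 * alpha), pi / 2 - 1e-3), 0)
    }
    if (!is.null(seed_state)) assign(".Random.seed", seed_state,
                                     envir = globalenv())
  }
  fits <- lapply(guesses, function(g0) {
    optim(g0, obj, method = "L-BFGS-B",
          lower = rep(-pi / 2 + 1e-6, n - 1), upper = rep(pi / 2 - 1e-6, n - 1),
          control = list(maxit = 500L, factr = 1e4,
                         ndeps = rep(1e-7, n - 1)))
  })
  energies <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(energies)]]
  psi <- c(alpha, best$par, 0)
  s <- seq(0, L, length.out = n + 1L)
  cp <- cos(psi)
  r <- r0 + cumsum(c(0, ds * (cp[-1] + cp[-length(cp)]) / 2))
  sp <- sin(psi)
  seg <- ds * (sp[-1] + sp[-length(sp)]) / 2
  h <- rev(cumsum(rev(c(seg, 0))))
  dpsi <- .fd_gradient(psi, s)
  H <- (dpsi + sp / r) / 2
  structure(list(
    profile = tibble::tibble(s = s, r = r, h = h, psi = psi, H = H),
    cap = cap, membrane = membrane, compartment = compartment,
    diagnostics = list(method = "arclength-direct", residual = NA_real_,
                       iterations = best$counts[["function"]],
                       convergence = best$convergence,
                       seed = control$seed, candidates = energies)),
    class = "footprint_profile")
}

#' @export
print.footprint_profile <- function(x, ...) {
  e <- footprint_energy(x)
  comp <- if (x$compartment$mode == "finite")
    sprintf("finite compartment, L = %g nm", x$compartment$L) else
      "infinite membrane"
  cat(sprintf(
    "<footprint_profile> %s (%s)\n  R = %g nm, A = %g nm^2, Kb = %g kBT, gamma = %g kBT/nm^2\n  GM = %.4g kBT (bending %.4g + tension %.4g), excess area %.4g nm^2\n",
    x$diagnostics$method, comp, x$cap$radius, x$cap$area,
    x$membrane$bending_modulus, x$membrane$tension,
    e$gm, e$bending_part, e$tension_part, e$excess_area))
  invisible(x)
}

#' Helfrich energy of a footprint profile
#'
#' Evaluates the footprint part of the membrane-Piezo energy on a solved (or
#' constructed) profile: the bending part
#' `int (Kb/2) (c1 + c2)^2 2 pi r ds` with `c1 + c2 = 2H`, the excess area
#' `DeltaA_M = int 2 pi r (1 - cos psi) ds` (the in-plane area the footprint
#' releases on flattening), and the tension part `gamma * DeltaA_M`.
#'
#' @param profile A `footprint_profile`, or a data frame with columns
#'   `s`, `r`, `psi`, `H`.
#' @param membrane A [membrane_spec()]; defaults to the profile's own.
#' @return A one-row tibble: `gm`, `bending_part`, `tension_part`,
#'   `excess_area` (nm^2).
#' @examples
#' cat <- catenoid_reference(cap_geometry(10.2))
#' footprint_energy(cat, membrane_spec(20, 0))   # pure catenoid: gm = 0
#' @export
footprint_energy <- function(profile, membrane = NULL) {
  if (inherits(profile, "footprint_profile")) {
    if (is.null(membrane)) membrane <- profile$membrane
    tb <- profile$profile
  } else {
    tb <- profile
    if (is.null(membrane)) abort("`membrane` must be given for a bare profile table.")
  }
  stopifnot(all(c("s", "r", "psi", "H") %in% names(tb)))
  kb <- membrane$bending_modulus
  g <- membrane$tension
  fb <- 4 * pi * kb * tb$H^2 * tb$r          # (Kb/2)(2H)^2 * 2 pi r
  fa <- 2 * pi * tb$r * (1 - cos(tb$psi))
  trapz <- function(y) sum(diff(tb$s) * (y[-1] + y[-length(y)]) / 2)
  bending <- trapz(fb)
  dA <- trapz(fa)
  tibble::tibble(gm = bending + g * dA, bending_part = bending,
                 tension_part = g * dA, excess_area = dA)
}

#' Catenoid reference surface
#'
#' The zero-tension limit of the membrane footprint: the axisymmetric
#' minimal surface with `c1 + c2 = 0` everywhere that attaches to the dome
#' rim with `psi(0) = alpha`. It obeys the first integral
#' `r sin(psi) = r0 sin(alpha)` (the neck constant) and carries exactly zero
#' bending energy, which is why `GM -> 0` as `gamma -> 0` even though the
#' membrane stays strongly curved. Heights are gauged to zero at the outer
#' sampling edge (a catenoid never flattens; its height grows
#' logarithmically).
#'
#' @param cap A non-flat [cap_geometry()].
#' @param s_max Outer arc length of the sampled profile, nm.
#' @param n Number of sample points.
#' @return A `footprint_profile` with `H = 0` identically.
#' @examples
#' catenoid_reference(cap_geometry(10.2))
#' @export
catenoid_reference <- function(cap, s_max = 4 * cap$r0, n = 201L) {
  stopifnot(inherits(cap, "cap_geometry"))
  cc <- cap$r0 * sin(cap$alpha)
  if (cc <= 0) abort("catenoid reference needs a curved cap (r0 sin(alpha) > 0).")
  b <- cap$r0 * cos(cap$alpha)
  s <- seq(0, s_max, length.out = n)
  r <- sqrt(cc^2 + (s + b)^2)
  psi <- asin(cc / r)
  h <- cc * (asinh((s_max + b) / cc) - asinh((s + b) / cc))
  structure(list(
    profile = tibble::tibble(s = s, r = r, h = h, psi = psi, H = 0 * s),
    cap = cap,
    membrane = membrane_spec(bending_modulus = 1, tension = 0),
    compartment = compartment_infinite(),
    diagnostics = list(method = "catenoid", residual = 0, iterations = 0L,
                       seed = NA_integer_, candidates = NULL)),
    class = "footprint_profile")
}

#' Compare the Monge and arclength solutions
#'
#' Solves the same footprint problem with the small-gradient (Monge)
#' analytic solution and the nonlinear arclength solver and reports both
#' energies, their relative difference, and the maximum height deviation of
#' the two profiles over the common radial range. At large dome curvature
#' the linearized solution overestimates the footprint and its energy; in
#' the small-slope regime the two agree closely.
#'
#' @inheritParams solve_footprint
#' @return A one-row tibble: `gm_monge`, `gm_arclength`, `rel_diff`
#'   (`(gm_monge - gm_arclength)/gm_arclength`), `max_h_dev` (nm),
#'   `larger` (which parametrization gives the larger energy).
#' @examples
#' \donttest{
#' compare_parametrizations(cap_geometry(100), membrane_spec(20, 0.1))
#' }
#' @export
compare_parametrizations <- function(cap, membrane,
                                     control = footprint_control()) {
  if (membrane$tension <= 0) {
    abort("comparison requires positive tension.", class = "piezodome_zero_tension")
  }
  if (is_flat_cap(cap)) {
    return(tibble::tibble(gm_monge = 0, gm_arclength = 0, rel_diff = 0,
                          max_h_dev = 0, larger = "equal"))
  }
  ms <- suppressWarnings(monge_footprint(cap, membrane))
  gm_m <- monge_energy(ms)
  fp <- solve_footprint(cap, membrane, control = control)
  gm_a <- footprint_energy(fp)$gm
  rmax <- min(max(fp$profile$r), ms$r0 + 10 * ms$lambda)
  rg <- seq(cap$r0, rmax, length.out = 301L)
  h_a <- approx(fp$profile$r, fp$profile$h, xout = rg, rule = 2)$y
  dev <- max(abs(ms$h(rg) - h_a))
  tibble::tibble(
    gm_monge = gm_m, gm_arclength = gm_a,
    rel_diff = (gm_m - gm_a) / gm_a, max_h_dev = dev,
    larger = if (gm_m >= gm_a) "monge" else "arclength")
}

#' Footprint energies over a parameter grid
#'
#' Solves the footprint for each row of a parameter grid and tabulates the
#' energy decomposition, in the layout written by the `footprint` CLI
#' subcommand.
#'
#' @param params Data frame with columns `R_nm`, `gamma_kBT_nm2` and
#'   optionally `A_nm2` (390), `Kb_kBT` (20), `L_nm` (`Inf` for an infinite
#'   membrane).
#' @param control A [footprint_control()].
#' @return A tibble: `R_nm, A_nm2, Kb_kBT, gamma_kBT_nm2, L_nm, GM_kBT,
#'   bending_kBT, tension_kBT, dAm_nm2`.
#' @export
footprint_sweep <- function(params, control = footprint_control()) {
  stopifnot(is.data.frame(params),
            all(c("R_nm", "gamma_kBT_nm2") %in% names(params)))
  if (is.null(params$A_nm2)) params$A_nm2 <- 390
  if (is.null(params$Kb_kBT)) params$Kb_kBT <- 20
  if (is.null(params$L_nm)) params$L_nm <- Inf
  purrr::pmap_dfr(
    params[c("R_nm", "A_nm2", "Kb_kBT", "gamma_kBT_nm2", "L_nm")],
    function(R_nm, A_nm2, Kb_kBT, gamma_kBT_nm2, L_nm) {
      comp <- if (is.finite(L_nm)) compartment_finite(L_nm) else
        compartment_infinite()
      fp <- solve_footprint(cap_geometry(R_nm, A_nm2),
                            membrane_spec(Kb_kBT, gamma_kBT_nm2),
                            comp, control)
      e <- footprint_energy(fp)
      tibble::tibble(R_nm = R_nm, A_nm2 = A_nm2, Kb_kBT = Kb_kBT,
                     gamma_kBT_nm2 = gamma_kBT_nm2, L_nm = L_nm,
                     GM_kBT = e$gm, bending_kBT = e$bending_part,
                     tension_kBT = e$tension_part, dAm_nm2 = e$excess_area)
    })
}
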