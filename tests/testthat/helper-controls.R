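# Shared solver settings for the test suite: a somewhat coarser mesh than
# the default keeps individual solves around 50 ms while leaving energies
# converged to well below the tolerances asserted here.
ctl_fast <- piezodome::footprint_control(n = 300L, n_finite = 60L)

closed_cap <- piezodome::cap_geometry(10.2, 390)
mem_ref <- piezodome::membrane_spec(20, 0.1)

gm_of <- function(R, gamma, kb = 20, A = 390, L = Inf,
                  control = ctl_fast) {
  comp <- if (is.finite(L)) piezodome::compartment_finite(L) else
    piezodome::compartment_infinite()
  fp <- piezodome::solve_footprint(piezodome::cap_geometry(R, A),
                                   piezodome::membrane_spec(kb, gamma),
                                   comp, control)
  piezodome::footprint_energy(fp)$gm
}

withr_local_file <- function(name) {
  tempfile(pattern = sub("\\..*$", "", name),
           fileext = sub("^[^.]*", "", name))
}

withr_local_dir <- function(name) tempfile(pattern = name)

# independent numerical oracle for the spherical-cap areas: integrate the
# surface of revolution r(theta) = R sin(theta) instead of using the
# closed forms under test
cap_area_oracle <- function(R, alpha) {
  stats::integrate(function(th) 2 * pi * R^2 * sin(th), 0, alpha,
                   rel.tol = 1e-12)$value
}
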