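# Self-describing CSV output: every file opens with commented metadata
# lines ("# key: value") so a result can always be traced back to the
# parameters that produced it.

.write_csv_with_header <- function(df, path, meta) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a piezodome CSV (metadata header plus table)
#'
#' @param path File written by one of the `write_*_csv()` functions or the
#'   CLI.
#' @return A tibble; the parsed `# key: value` header is attached as
#'   attribute `"metadata"`.
#' @export
read_piezodome_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in hdr) {
    kv <- sub("^#\\s*", "", ln)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    meta[[k]] <- v
  }
  tb <- tibble::as_tibble(read.csv(text = lines[!grepl("^#", lines)]))
  attr(tb, "metadata") <- meta
  tb
}

#' Write a footprint profile CSV
#'
#' Columns `s_nm, r_nm, h_nm, psi_rad, H_per_nm`; the header records the
#' method, all physical parameters, the seed and the solver residual.
#'
#' @param profile A `footprint_profile`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "footprint_profile"))
  tb <- profile$profile
  out <- tibble::tibble(s_nm = tb$s, r_nm = tb$r, h_nm = tb$h,
                        psi_rad = tb$psi, H_per_nm = tb$H)
  .write_csv_with_header(out, path, list(
    method = profile$diagnostics$method,
    R_nm = profile$cap$radius, A_nm2 = profile$cap$area,
    Kb_kBT = profile$membrane$bending_modulus,
    gamma_kBT_nm2 = profile$membrane$tension,
    compartment = profile$compartment$mode, L_nm = profile$compartment$L,
    seed = profile$diagnostics$seed,
    residual = profile$diagnostics$residual))
}

#' Write a Monge profile CSV
#'
#' Columns `r_nm, h_nm, slope, meanCurv_per_nm`; header records Kb, gamma,
#' R, A and `method: monge`.
#'
#' @param sol A `monge_footprint`.
#' @param path Output file.
#' @param n,r_max Sampling of the profile, as in [tidy.monge_footprint()].
#' @return The path, invisibly.
#' @export
write_monge_csv <- function(sol, path, n = 201,
                            r_max = sol$r0 + 6 * sol$lambda) {
  stopifnot(inherits(sol, "monge_footprint"))
  tb <- tidy(sol, n = n, r_max = r_max)
  out <- tibble::tibble(r_nm = tb$r, h_nm = tb$h, slope = tb$slope,
                        meanCurv_per_nm = tb$mean_curv)
  .write_csv_with_header(out, path, list(
    method = "monge", R_nm = sol$cap$radius, A_nm2 = sol$cap$area,
    Kb_kBT = sol$membrane$bending_modulus,
    gamma_kBT_nm2 = sol$membrane$tension))
}

#' Write an energy-sweep CSV
#'
#' @param sweep Output of [footprint_sweep()].
#' @param path Output file.
#' @param meta Named list of extra header entries.
#' @return The path, invisibly.
#' @export
write_energy_csv <- function(sweep, path, meta = list()) {
  .write_csv_with_header(sweep, path, c(list(kind = "footprint-energies"),
                                        meta))
}

#' Write a gating-curve CSV
#'
#' Columns `gamma_kBT_nm2, model, dGDb_kBT, dGDgamma_kBT, dGM_kBT, dG_kBT,
#' Po, dGdgamma_nm2, dPodgamma`; the header records Rc, Ro, A, Kb, deltaGDP
#' and the compartment.
#'
#' @param curve A [gating_curve()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_gating_csv <- function(curve, path) {
  stopifnot(inherits(curve, "gating_curve"))
  sc <- attr(curve, "scenario")
  out <- tibble::tibble(
    gamma_kBT_nm2 = curve$gamma, model = curve$model,
    dGDb_kBT = curve$d_gdb, dGDgamma_kBT = curve$d_gdgamma,
    dGM_kBT = curve$d_gm, dG_kBT = curve$d_g, Po = curve$po,
    dGdgamma_nm2 = curve$d_dg_dgamma, dPodgamma = curve$dpo_dgamma)
  .write_csv_with_header(out, path, list(
    Rc_nm = sc$closed$radius, Ro_nm = sc$open$radius, A_nm2 = sc$closed$area,
    Kb_kBT = sc$membrane$bending_modulus, deltaGDP_kBT = sc$delta_gdp,
    compartment = sc$compartment$mode, L_nm = sc$compartment$L,
    seed = sc$control$seed))
}

#' Read a run configuration (YAML or JSON)
#'
#' Configuration files mirror the function arguments: top-level keys
#' `R`, `A`, `Kb`, `gamma` (scalar or vector), optional `L`, `Rc`, `Ro`,
#' `deltaGDP`, `gamma_half`, `seed`, and a `control` block passed to
#' [footprint_control()].
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Regenerate the golden reference fixtures
#'
#' Solves a small reference set of footprint problems (R in {10.2, 20, 100}
#' nm, Kb = 20 kBT, gamma in {0.01, 0.1} kBT/nm^2) and writes their energy
#' table and profiles, plus MD5 hashes of every file, for use as regression
#' fixtures. Regeneration is deterministic: the same seed and tolerances
#' reproduce the files bit for bit.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in every header and used by the solvers.
#' @return Invisibly, a tibble of written files and their MD5 hashes.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctl <- footprint_control(seed = seed)
  grid <- expand.grid(R_nm = c(10.2, 20, 100), gamma_kBT_nm2 = c(0.01, 0.1))
  grid$Kb_kBT <- 20
  sweep <- footprint_sweep(grid, control = ctl)
  paths <- file.path(dir, "fixture_energies.csv")
  write_energy_csv(sweep, paths, meta = list(seed = seed))
  for (i in seq_len(nrow(grid))) {
    fp <- solve_footprint(cap_geometry(grid$R_nm[i]),
                          membrane_spec(20, grid$gamma_kBT_nm2[i]),
                          control = ctl)
    p <- file.path(dir, sprintf("fixture_profile_R%g_g%g.csv",
                                grid$R_nm[i], grid$gamma_kBT_nm2[i]))
    write_profile_csv(fp, p)
    paths <- c(paths, p)
  }
  hashes <- tools::md5sum(paths)
  hash_tb <- tibble::tibble(file = basename(paths), md5 = unname(hashes))
  write.csv(hash_tb, file.path(dir, "fixture_hashes.csv"), row.names = FALSE)
  invisible(hash_tb)
}
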