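#' Scenario configuration
#'
#' A flat key-value description of one solve scenario, serializable to a
#' YAML config file. All defaults reproduce the standard microtubule model:
#' KCl at 298 K with a 0.33 nm Stern distance, the full variable
#' permittivity, and the 13-protofilament / 8 nm-repeat geometry.
#'
#' @param geometry `"lumen"`, `"smt-outer"` or `"ct"`.
#' @param kcl_mM Bulk KCl concentration (mM).
#' @param temperature_K,eps_w,eps_K,permittivity_mode,stern_nm,c_max_M
#'   Physics knobs; see [pb_constants()], [permittivity_model()],
#'   [buffer_spec()].
#' @param lambda_K_Sm2permol,lambda_Cl_Sm2permol Limiting molar
#'   conductivities (SI).
#' @param r_inner_nm,r_outer_nm,r_ct_nm,q_inner_e,q_outer_e,q_ct_e,include_ct
#'   Geometry overrides; see [microtubule_spec()].
#' @param n_grid,r_max_factor Solver overrides; see [solver_options()].
#' @param tag Free-text label (e.g. `"brb80"` for the 160 mM case).
#' @return A named list of class `cylpb_config`.
#' @export
scenario_config <- function(geometry = "smt-outer", kcl_mM = 160,
                            temperature_K = 298, eps_w = 78.5, eps_K = 5,
                            permittivity_mode = "full", stern_nm = 0.33,
                            lambda_K_Sm2permol = 7.352e-3,
                            lambda_Cl_Sm2permol = 7.634e-3,
                            c_max_M = 15.9,
                            r_inner_nm = 8.4, r_outer_nm = 12.5,
                            r_ct_nm = 0.5,
                            q_inner_e = -5, q_outer_e = -25, q_ct_e = -11,
                            include_ct = TRUE,
                            n_grid = 2000, r_max_factor = 40,
                            tag = "") {
  cfg <- as.list(environment())
  structure(cfg, class = c("cylpb_config", "list"))
}

#' @rdname scenario_config
#' @param cfg A `cylpb_config`.
#' @param path File path.
#' @export
write_scenario_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname scenario_config
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(scenario_config, raw)
}

#' Materialize a configuration into model objects
#'
#' @param cfg A [scenario_config()].
#' @return A list: `geometry` (tag), `buffer`, `perm`, `mt`, `opts`,
#'   `constants`.
#' @export
config_to_inputs <- function(cfg) {
  constants <- pb_constants(cfg$temperature_K)
  buffer <- buffer_spec(cfg$kcl_mM,
                        lambda_cation = cfg$lambda_K_Sm2permol,
                        lambda_anion = cfg$lambda_Cl_Sm2permol,
                        d_stern = cfg$stern_nm * 1e-9,
                        c_max = cfg$c_max_M * 1e3)
  perm <- permittivity_model(cfg$permittivity_mode, eps_w = cfg$eps_w,
                             eps_K = cfg$eps_K)
  mt <- microtubule_spec(include_ct = cfg$include_ct,
                         r_inner = cfg$r_inner_nm * 1e-9,
                         r_outer = cfg$r_outer_nm * 1e-9,
                         r_ct = cfg$r_ct_nm * 1e-9,
                         q_inner_e = cfg$q_inner_e,
                         q_outer_e = cfg$q_outer_e,
                         q_ct_e = cfg$q_ct_e,
                         constants = constants)
  opts <- solver_options(n_grid = cfg$n_grid,
                         r_max_factor = cfg$r_max_factor)
  list(geometry = cfg$geometry, buffer = buffer, perm = perm, mt = mt,
       opts = opts, constants = constants)
}

#' Export a solved profile as CSV
#'
#' Columns: `r_m`, `dist_from_surface_m`, `V_volts`, `E_V_per_m`, `eps_r`,
#' `c_cation_M`, `c_anion_M`. Scenario metadata and the convergence report
#' are embedded as `#`-prefixed header lines.
#'
#' @param profile A `cylpb_profile`.
#' @param path Output file path.
#' @export
write_profile_csv <- function(profile, path) {
  gl <- generics::glance(profile)
  hdr <- paste0("# ", names(gl), " = ",
                vapply(gl, function(v) format(v, digits = 15), character(1)))
  out <- dplyr::transmute(
    profile$data,
    r_m = .data$r,
    dist_from_surface_m = .data$dist,
    V_volts = .data$V, E_V_per_m = .data$E, eps_r = .data$eps,
    c_cation_M = .data$c_cation / 1e3, c_anion_M = .data$c_anion / 1e3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}
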