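# Oracle scenarios for validating the nonlinear solver. Each case embeds
# all of its parameters and a closed-form expectation computed here, by
# code that never touches the finite-volume solver, so agreement between
# the two routes is evidence rather than tautology.

#' Planar Gouy-Chapman oracle case
#'
#' In the planar limit (cylinder radius much larger than the Debye length,
#' no Stern offset) the nonlinear problem has the classical closed form:
#' the Grahame relation
#' `sigma = sqrt(8 c_s N_A eps eps0 k_B T) sinh(e V0 / 2 k_B T)` fixes the
#' surface potential, and the profile follows
#' `tanh(eV/4kT) = tanh(eV0/4kT) exp(-x/lambda_D)`. The case packages a
#' cylinder with `R = radius_factor * lambda_D` and a zero-Stern buffer
#' together with the expected surface potential and a profile function.
#'
#' @param c_s_mM Bulk concentration (mM).
#' @param sigma Surface charge density (C/m^2).
#' @param eps_r Constant relative permittivity.
#' @param radius_factor Cylinder radius in Debye lengths (>= 1000 for the
#'   planar limit to hold to ~0.1%).
#' @param constants A [pb_constants()].
#' @return An `oracle_case` list: `kind`, `cyl`, `buffer`, `perm`,
#'   `expected` (list with `V0` and `profile(x)`), `tol_rel`.
#' @export
make_gouy_chapman_case <- function(c_s_mM = 100, sigma = -0.083,
                                   eps_r = 78.5, radius_factor = 1000,
                                   constants = pb_constants()) {
  stopifnot(radius_factor >= 1000)
  buffer <- buffer_spec(c_s_mM, d_stern = 0)
  lD <- debye_length(buffer, eps_r, constants)
  Vt <- thermal_voltage(constants)
  cap <- sqrt(8 * buffer$c_s * constants$N_A * eps_r * constants$eps0 *
                constants$k_B * constants$T)
  V0 <- 2 * Vt * asinh(sigma / cap)
  profile_fun <- function(x) {
    g <- tanh(V0 / (4 * Vt)) * exp(-x / lD)
    4 * Vt * atanh(g)
  }
  structure(list(
    kind = "gouy_chapman_planar",
    cyl = cylinder_spec(radius_factor * lD, sigma, "exterior"),
    buffer = buffer,
    perm = permittivity_model("constant", eps_w = eps_r),
    expected = list(V0 = V0, profile = profile_fun, lambda_D = lD),
    tol_rel = 5e-3,
    description = sprintf(
      "planar Grahame limit: %.4g mM, sigma = %.3g C/m^2", c_s_mM, sigma)),
    class = "oracle_case")
}

#' Linear-regime Bessel oracle case
#'
#' Scales the surface charge down until the potential is far below the
#' thermal voltage, where the nonlinear solution must match the analytic
#' linearized Bessel solution. The expectation is evaluated here from the
#' modified Bessel functions directly (exponentially scaled ratios), not
#' via the package's linearized-solution functions.
#'
#' @param side `"interior"` or `"exterior"`.
#' @param c_s_mM Bulk concentration (mM).
#' @param sigma Surface charge density; default -1e-4 C/m^2 keeps
#'   `|V| < 0.1 k_B T / e` in all standard geometries.
#' @param R Cylinder radius (m).
#' @param eps_r Constant relative permittivity.
#' @param constants A [pb_constants()].
#' @return An `oracle_case` with an `expected$profile(r)` closure.
#' @export
make_linear_regime_case <- function(side = c("exterior", "interior"),
                                    c_s_mM = 160, sigma = -1e-4,
                                    R = if (side == "exterior") 12.5e-9
                                    else 8.4e-9,
                                    eps_r = 78.5,
                                    constants = pb_constants()) {
  side <- match.arg(side)
  buffer <- buffer_spec(c_s_mM)
  d <- buffer$d_stern
  lD <- sqrt(constants$eps0 * eps_r * constants$k_B * constants$T /
               (2 * constants$N_A * buffer$c_s * constants$e^2))
  pref_ext <- sigma * lD / (constants$eps0 * eps_r) * R / (R + d)
  pref_int <- sigma * lD / (constants$eps0 * eps_r) * R / (R - d)
  profile_fun <- if (side == "exterior") {
    function(r) {
      pref_ext * besselK(r / lD, 0, expon.scaled = TRUE) /
        besselK((R + d) / lD, 1, expon.scaled = TRUE) *
        exp((R + d) / lD - r / lD)
    }
  } else {
    function(r) {
      pref_int * besselI(r / lD, 0, expon.scaled = TRUE) /
        besselI((R - d) / lD, 1, expon.scaled = TRUE) *
        exp(r / lD - (R - d) / lD)
    }
  }
  structure(list(
    kind = "linear_regime",
    cyl = cylinder_spec(R, sigma, side),
    buffer = buffer,
    perm = permittivity_model("constant", eps_w = eps_r),
    expected = list(profile = profile_fun, lambda_D = lD),
    tol_rel = 5e-3,
    description = sprintf("linear regime, %s, %.4g mM", side, c_s_mM)),
    class = "oracle_case")
}

#' Grid/truncation refinement suite
#'
#' Canonical scenarios paired with nested grids `(n, 2n, 4n)` and doubled
#' truncation radii, for Richardson convergence-order and
#' truncation-independence checks. The finite-volume scheme on the smooth
#' exponentially graded mesh is expected to converge at order ~2.
#'
#' @param n_base Coarsest grid size (default 400, kept small because three
#'   nested solves run per case).
#' @return A list of refinement case descriptions.
#' @export
make_refinement_suite <- function(n_base = 400) {
  mt <- microtubule_spec()
  list(
    list(tag = "smt-outer-160mM", cyl = mt$outer, buffer = kcl_buffer(160),
         perm = permittivity_model("full"),
         n_grids = n_base * c(1L, 2L, 4L), r_max_factors = c(40, 80)),
    list(tag = "lumen-160mM", cyl = mt$inner, buffer = kcl_buffer(160),
         perm = permittivity_model("full"),
         n_grids = n_base * c(1L, 2L, 4L), r_max_factors = c(40, 80)),
    list(tag = "ct-10mM", cyl = mt$ct, buffer = kcl_buffer(10),
         perm = permittivity_model("full"),
         n_grids = n_base * c(1L, 2L, 4L), r_max_factors = c(40, 80)))
}

#' Canonical scenario configurations
#'
#' One [scenario_config()] per canonical concentration and geometry, with
#' all standard defaults; the 160 mM rows carry the `brb80` tag (the
#' BRB80-buffer ionic strength). Optionally writes each config as a YAML
#' file.
#'
#' @param dir Optional directory to emit config files into.
#' @return A tibble with columns `name`, `geometry`, `kcl_mM`, `tag` and a
#'   list-column `config`.
#' @export
canonical_scenarios <- function(dir = NULL) {
  grid <- tidyr::expand_grid(
    kcl_mM = canonical_concentrations_mM(),
    geometry = c("lumen", "smt-outer", "ct"))
  out <- dplyr::mutate(
    grid,
    tag = ifelse(.data$kcl_mM == 160, "brb80", ""),
    name = sprintf("%s_%gmM", gsub("-", "_", .data$geometry), .data$kcl_mM),
    config = purrr::pmap(
      list(.data$geometry, .data$kcl_mM, .data$tag),
      function(g, c, t) scenario_config(geometry = g, kcl_mM = c, tag = t)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    purrr::walk2(out$config, out$name, function(cfg, nm)
      write_scenario_config(cfg, file.path(dir, paste0(nm, ".yaml"))))
  }
  out
}
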