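#' Langevin saturation function
#'
#' The dielectric-saturation form `L(x) = 3 (coth(x) - 1/x) / x` used in the
#' Booth model of field-dependent water permittivity. `L(0) = 1` (series
#' limit) and `L(x) -> 0` as `x -> Inf`.
#'
#' Evaluated by its Taylor series `1 - x^2/15 + 2 x^4/315` for `|x| < 0.01`,
#' where the direct form loses digits to cancellation (coth(x) and 1/x are
#' each ~1e2 while their difference is ~3e-3).
#'
#' @param x Numeric vector.
#' @return `L(x)`, same shape as `x`.
#' @export
langevin_saturation <- function(x) {
  x <- as.numeric(x)
  out <- numeric(length(x))
  small <- abs(x) < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 15 + 2 * xs^4 / 315
  xl <- x[!small]
  if (length(xl)) {
    # coth via tanh keeps large arguments finite
    out[!small] <- 3 * (1 / tanh(xl) - 1 / xl) / xl
  }
  out
}

#' Booth field-dependent permittivity
#'
#' Dielectric saturation of water in strong fields:
#' `eps_BE = 1.8 + (eps_l - 1.8) * L(0.08 * E)` with the field `E` in
#' mV/Angstrom and `L` the saturation function [langevin_saturation()].
#' Monotone non-increasing in the field, from `eps_l` at zero field down
#' to the optical-limit value 1.8.
#'
#' @param E_mV_per_A Field magnitude in mV/Angstrom (>= 0). Multiply a field
#'   in V/m by 1e-7 to convert.
#' @param eps_l Zero-field (local) relative permittivity, >= 1.8. For
#'   cylindrical geometry the surface-geometry correction is negligible and
#'   `eps_l` is the bulk water value.
#' @return Relative permittivity, in (1.8, eps_l].
#' @export
booth_permittivity <- function(E_mV_per_A, eps_l = 78.5) {
  if (any(E_mV_per_A < 0)) stop("field magnitude must be >= 0", call. = FALSE)
  stopifnot(all(eps_l >= 1.8))
  1.8 + (eps_l - 1.8) * langevin_saturation(0.08 * E_mV_per_A)
}

#' Cation volume fraction
#'
#' `rho = c_K / (c_K + c_max)` with `c_max` the maximum packing
#' concentration of the (hydrated) cation, 15.9 M for potassium.
#'
#' @param c_K Local cation concentration, mol/m^3 (>= 0).
#' @param c_max Maximum packing concentration, mol/m^3.
#' @return Volume fraction in [0, 1).
#' @export
ion_volume_fraction <- function(c_K, c_max = 15.9e3) {
  if (any(c_K < 0)) stop("concentration must be >= 0", call. = FALSE)
  c_K / (c_K + c_max)
}

#' Concentration-dependent permittivity
#'
#' Dielectric decrement from crowded hydrated cations:
#' `eps = eps_base (1 - rho + 3 alpha rho) / (1 + rho/2)` with
#' `alpha = eps_K / (2 eps_base)`. In pure-concentration mode `eps_base` is
#' bulk water; in the full model it is the Booth value, so saturation and
#' crowding compose.
#'
#' @param eps_base Base relative permittivity (water or Booth-reduced).
#' @param rho Cation volume fraction in [0, 1), see [ion_volume_fraction()].
#' @param eps_K Relative permittivity attributed to the hydrated cation.
#' @return Relative permittivity.
#' @export
concentration_permittivity <- function(eps_base, rho, eps_K = 5) {
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)", call. = FALSE)
  alpha <- eps_K / (2 * eps_base)
  eps_base * (1 - rho + 3 * alpha * rho) / (1 + rho / 2)
}

#' Permittivity model configuration
#'
#' Selects how the local relative permittivity is computed during a solve:
#' \describe{
#'   \item{constant}{`eps_w` everywhere.}
#'   \item{booth_only}{field-dependent saturation only.}
#'   \item{concentration_only}{cation-crowding decrement only.}
#'   \item{full}{Booth base fed into the concentration decrement (default).}
#' }
#'
#' @param mode One of `"constant"`, `"booth_only"`, `"concentration_only"`,
#'   `"full"`.
#' @param eps_w Bulk relative permittivity of water at the working
#'   temperature (default 78.5 at 298 K).
#' @param eps_K Cation permittivity used by the concentration decrement.
#'   Not stated by the underlying dielectric model; default 5, a
#'   representative hydration-shell value, and recorded in all outputs.
#' @return A list of class `pb_permittivity`.
#' @export
permittivity_model <- function(mode = c("full", "constant", "booth_only",
                                        "concentration_only"),
                               eps_w = 78.5, eps_K = 5) {
  mode <- match.arg(mode)
  stopifnot(eps_w > 1.8, eps_K > 0)
  structure(list(mode = mode, eps_w = eps_w, eps_K = eps_K),
            class = "pb_permittivity")
}

#' Local permittivity field on a grid
#'
#' Applies the configured permittivity model to a field magnitude and cation
#' concentration sampled on the radial grid. Called once per outer
#' fixed-point sweep of the nonlinear solver.
#'
#' @param E_V_per_m Field magnitude in V/m (vector).
#' @param c_cation Local cation concentration in mol/m^3 (vector).
#' @param perm A [permittivity_model()].
#' @param c_max Maximum cation packing concentration (mol/m^3).
#' @return Relative permittivity vector.
#' @export
permittivity_field <- function(E_V_per_m, c_cation, perm = permittivity_model(),
                               c_max = 15.9e3) {
  eps_w <- perm$eps_w
  if (perm$mode == "constant") return(rep(eps_w, length(E_V_per_m)))
  E_mVA <- abs(E_V_per_m) * 1e-7   # V/m -> mV/Angstrom
  base <- if (perm$mode %in% c("booth_only", "full"))
    booth_permittivity(E_mVA, eps_l = eps_w) else rep(eps_w, length(E_V_per_m))
  if (perm$mode %in% c("concentration_only", "full")) {
    rho <- ion_volume_fraction(pmax(c_cation, 0), c_max)
    base <- concentration_permittivity(base, rho, eps_K = perm$eps_K)
  }
  base
}
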