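# Analytic solutions of the linearized (Debye-Hueckel) cylindrical problem.
# Bessel ratios are formed from exponentially scaled besselI/besselK so the
# expressions stay finite for arguments far beyond the overflow range
# (needed for planar-limit oracles with R ~ 1000 Debye lengths).

# I_0(x) / I_1(y), numerically stable for large x, y
.bessel_i_ratio <- function(x, y) {
  besselI(x, 0, expon.scaled = TRUE) / besselI(y, 1, expon.scaled = TRUE) *
    exp(x - y)
}

# K_0(x) / K_1(y)
.bessel_k_ratio <- function(x, y) {
  besselK(x, 0, expon.scaled = TRUE) / besselK(y, 1, expon.scaled = TRUE) *
    exp(y - x)
}

#' Linearized potential inside a charged cylinder
#'
#' Closed-form solution of the linear Poisson-Boltzmann equation in the
#' lumen of a charged cylinder with a Stern annulus of thickness `d`:
#' `V(r) = sigma lambda_D / (eps0 eps_r) * R/(R-d) * I0(r/lambda_D) /
#' I1((R-d)/lambda_D)`, valid for `r <= R - d`. Accurate only while
#' `|V| << k_B T / e`; used as a solver oracle and as the Newton initial
#' guess.
#'
#' @param cyl A [cylinder_spec()] (side `"interior"`).
#' @param buffer A [buffer_spec()]; supplies `c_s` and the Stern distance.
#' @param eps_r Constant relative permittivity.
#' @param r Radii (m), `0 <= r <= R - d`.
#' @param constants A [pb_constants()].
#' @return Potential in volts at `r`.
#' @export
lpb_interior_potential <- function(cyl, buffer, eps_r = 78.5, r,
                                   constants = pb_constants()) {
  d <- buffer$d_stern
  if (cyl$R - d <= 0) stop("R - d_stern must be positive", call. = FALSE)
  if (any(r < 0 | r > cyl$R - d + 1e-15))
    stop("r outside the interior domain [0, R - d]", call. = FALSE)
  lD <- debye_length(buffer, eps_r, constants)
  pref <- cyl$sigma * lD / (constants$eps0 * eps_r) * cyl$R / (cyl$R - d)
  pref * .bessel_i_ratio(r / lD, (cyl$R - d) / lD)
}

#' Linearized potential outside a charged cylinder
#'
#' `V(r) = sigma lambda_D / (eps0 eps_r) * R/(R+d) * K0(r/lambda_D) /
#' K1((R+d)/lambda_D)` for `r >= R + d`; decays to zero at infinity. In the
#' planar limit (`R >> lambda_D`, `d = 0`) the surface value reduces to the
#' Debye-Hueckel planar result `sigma lambda_D / (eps0 eps_r)`.
#'
#' @inheritParams lpb_interior_potential
#' @param cyl A [cylinder_spec()] (side `"exterior"`).
#' @param r Radii (m), `r >= R + d`.
#' @export
lpb_exterior_potential <- function(cyl, buffer, eps_r = 78.5, r,
                                   constants = pb_constants()) {
  d <- buffer$d_stern
  if (any(r < cyl$R + d - 1e-15))
    stop("r inside the Stern region: require r >= R + d", call. = FALSE)
  lD <- debye_length(buffer, eps_r, constants)
  pref <- cyl$sigma * lD / (constants$eps0 * eps_r) * cyl$R / (cyl$R + d)
  pref * .bessel_k_ratio(r / lD, (cyl$R + d) / lD)
}
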