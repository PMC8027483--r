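#' Physical constants
#'
#' CODATA values for the elementary charge, Boltzmann constant, Avogadro
#' constant and vacuum permittivity, bundled with an absolute temperature.
#' Every other function in the package takes its constants from one of these
#' objects, so a scenario is fully determined by its inputs.
#'
#' @param temperature_K Absolute temperature in kelvin (default 298).
#' @return A list of class `pb_constants` with elements `e` (C), `k_B` (J/K),
#'   `N_A` (1/mol), `eps0` (F/m) and `T` (K).
#' @examples
#' pb_constants()$T
#' @export
pb_constants <- function(temperature_K = 298) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1,
            temperature_K > 0)
  structure(
    list(
      e    = 1.602176634e-19,
      k_B  = 1.380649e-23,
      N_A  = 6.02214076e23,
      eps0 = 8.8541878128e-12,
      T    = temperature_K
    ),
    class = "pb_constants"
  )
}

#' Thermal voltage k_B T / e
#'
#' The thermal voltage sets the scale separating ions that are thermally
#' free from ions bound in the double layer: ions sitting at potentials below
#' its negative are counted as bound to the polyelectrolyte. At 298 K it is
#' approximately 25.7 mV.
#'
#' @param constants A [pb_constants()] object.
#' @return Thermal voltage in volts (positive magnitude).
#' @examples
#' thermal_voltage() # ~0.0257 V
#' @export
thermal_voltage <- function(constants = pb_constants()) {
  stopifnot(inherits(constants, "pb_constants"), constants$T > 0)
  constants$k_B * constants$T / constants$e
}

#' Electrolyte buffer specification
#'
#' Describes a symmetric monovalent (z = +/-1) electrolyte such as KCl:
#' bulk concentration, limiting molar conductivities of the two ions, the
#' distance of closest approach of the hydrated cation (the Stern-layer
#' thickness) and the maximum packing concentration of the cation used by
#' the concentration-dependent permittivity model.
#'
#' Defaults describe KCl: Stern distance 0.33 nm (hydrated K+ radius),
#' maximum K+ concentration 15.9 M, limiting molar conductivities
#' 7.352 and 7.634 mS m^2/mol for K+ and Cl-.
#'
#' @param c_s Bulk salt concentration in mol/m^3 (1 mM = 1 mol/m^3).
#' @param lambda_cation,lambda_anion Limiting molar conductivities in
#'   S m^2/mol.
#' @param d_stern Distance of closest approach in metres.
#' @param c_max Maximum cation packing concentration in mol/m^3.
#' @return A list of class `pb_buffer`.
#' @examples
#' kcl_buffer(160)        # BRB80-like ionic strength, c in mM
#' buffer_spec(0.01)      # 10 uM in mol/m^3
#' @export
buffer_spec <- function(c_s,
                        lambda_cation = 7.352e-3,
                        lambda_anion  = 7.634e-3,
                        d_stern = 0.33e-9,
                        c_max = 15.9e3) {
  stopifnot(is.numeric(c_s), length(c_s) == 1, c_s > 0,
            lambda_cation >= 0, lambda_anion >= 0,
            d_stern >= 0, c_max > 0)
  structure(
    list(c_s = c_s, z = c(cation = 1, anion = -1),
         lambda_cation = lambda_cation, lambda_anion = lambda_anion,
         d_stern = d_stern, c_max = c_max),
    class = "pb_buffer"
  )
}

#' @rdname buffer_spec
#' @param c_mM Bulk KCl concentration in mM.
#' @param ... Passed on to [buffer_spec()].
#' @export
kcl_buffer <- function(c_mM, ...) buffer_spec(c_s = c_mM, ...)

#' Debye screening length
#'
#' For a symmetric monovalent electrolyte,
#' lambda_D = sqrt(eps0 eps_r k_B T / (2 N_A c_s e^2)).
#' Under physiological conditions (~150 mM, 298 K) it is about 0.8 nm;
#' at 10 uM it grows to about 96 nm.
#'
#' @param buffer A [buffer_spec()] object.
#' @param eps_r Relative permittivity used for screening (default 78.5).
#' @param constants A [pb_constants()] object.
#' @return Debye length in metres.
#' @export
debye_length <- function(buffer, eps_r = 78.5, constants = pb_constants()) {
  stopifnot(inherits(buffer, "pb_buffer"))
  if (!is.numeric(eps_r) || eps_r <= 0)
    stop("`eps_r` must be a positive number", call. = FALSE)
  if (buffer$c_s <= 0) stop("`c_s` must be positive", call. = FALSE)
  with(constants,
       sqrt(eps0 * eps_r * k_B * T / (2 * N_A * buffer$c_s * e^2)))
}

#' Bulk conductivity of the buffer
#'
#' The bulk solution conductivity (lambda_cation + lambda_anion) * c_s,
#' exactly linear in concentration. This is the baseline against which the
#' mean axial conductivity of the protein-ion complex is compared to locate
#' the crossover concentration.
#'
#' @inheritParams debye_length
#' @return Conductivity in S/m.
#' @export
buffer_conductivity <- function(buffer) {
  stopifnot(inherits(buffer, "pb_buffer"))
  (buffer$lambda_cation + buffer$lambda_anion) * buffer$c_s
}

#' Charged cylinder specification
#'
#' A single uniformly charged cylindrical surface: the lumen wall seen from
#' inside (`side = "interior"`), or the outer microtubule wall or a
#' C-terminus seen from outside (`side = "exterior"`).
#'
#' @param R Cylinder radius in metres.
#' @param sigma Surface charge density in C/m^2 (signed; negative for
#'   tubulin surfaces at pH 7).
#' @param side `"interior"` or `"exterior"`.
#' @return A list of class `pb_cylinder`.
#' @export
cylinder_spec <- function(R, sigma, side = c("exterior", "interior")) {
  side <- match.arg(side)
  stopifnot(is.numeric(R), R > 0, is.numeric(sigma))
  structure(list(R = R, sigma = sigma, side = side), class = "pb_cylinder")
}

#' Microtubule geometry and charge model
#'
#' The microtubule (MT) is modelled as two infinite coaxial charged
#' cylinders — the lumen wall (radius 8.4 nm, -5 e per dimer) and the outer
#' wall (radius 12.5 nm, -25 e per dimer) — plus, optionally, the C-termini
#' (CT): flexible tails carrying -11 e each, modelled as infinite cylinders
#' of radius 0.5 nm whose surface charge is spread over a 4 nm length.
#' A 13-protofilament lattice with an 8 nm axial dimer repeat converts
#' per-dimer charges into surface charge densities. Without CT the model
#' describes a subtilisin-digested microtubule (SMT).
#'
#' @param include_ct Include the C-termini (TRUE for an MT, FALSE for an SMT).
#' @param r_inner,r_outer,r_ct Radii in metres.
#' @param q_inner_e,q_outer_e,q_ct_e Charges in units of e (per dimer for the
#'   walls, per C-terminus for `q_ct_e`).
#' @param ct_length CT cylinder length in metres (4 nm).
#' @param ct_per_dimer Number of C-termini per heterodimer (2); enters the
#'   protein charge bookkeeping.
#' @param ct_bound_length_per_dimer Length of effective CT cylinder whose
#'   bound ions are attributed to one heterodimer (default 4 nm, the
#'   tail-bearing segment; see the methods vignette).
#' @param ct_spacing Centre-to-centre CT spacing along a protofilament (4 nm).
#' @param protofilaments Number of protofilaments (13).
#' @param dimer_repeat Axial dimer repeat in metres (8 nm).
#' @param constants A [pb_constants()] object.
#' @return A list of class `pb_microtubule` with `inner`, `outer` and `ct`
#'   [cylinder_spec()]s and the lattice bookkeeping.
#' @examples
#' mt <- microtubule_spec()
#' mt$outer$sigma  # ~ -0.083 C/m^2
#' @export
microtubule_spec <- function(include_ct = TRUE,
                             r_inner = 8.4e-9, r_outer = 12.5e-9,
                             r_ct = 0.5e-9,
                             q_inner_e = -5, q_outer_e = -25, q_ct_e = -11,
                             ct_length = 4e-9, ct_per_dimer = 2,
                             ct_bound_length_per_dimer = 4e-9,
                             ct_spacing = 4e-9,
                             protofilaments = 13, dimer_repeat = 8e-9,
                             constants = pb_constants()) {
  stopifnot(r_inner > 0, r_outer > r_inner, r_ct > 0,
            ct_length > 0, protofilaments >= 1, dimer_repeat > 0)
  geom <- list(r_inner = r_inner, r_outer = r_outer, r_ct = r_ct,
               ct_length = ct_length, ct_per_dimer = ct_per_dimer,
               ct_bound_length_per_dimer = ct_bound_length_per_dimer,
               ct_spacing = ct_spacing,
               protofilaments = protofilaments, dimer_repeat = dimer_repeat)
  sig_in  <- .sigma_from_charge(q_inner_e, "inner", geom, constants)
  sig_out <- .sigma_from_charge(q_outer_e, "outer", geom, constants)
  sig_ct  <- .sigma_from_charge(q_ct_e, "ct", geom, constants)
  structure(
    c(geom,
      list(inner = cylinder_spec(r_inner, sig_in, "interior"),
           outer = cylinder_spec(r_outer, sig_out, "exterior"),
           ct    = cylinder_spec(r_ct, sig_ct, "exterior"),
           q_inner_e = q_inner_e, q_outer_e = q_outer_e, q_ct_e = q_ct_e,
           include_ct = include_ct,
           protein_charge_per_dimer_e =
             q_inner_e + q_outer_e + ct_per_dimer * q_ct_e * include_ct)),
    class = "pb_microtubule"
  )
}

.sigma_from_charge <- function(q_e, surface, geom, constants) {
  area <- switch(surface,
    inner = 2 * pi * geom$r_inner * geom$dimer_repeat / geom$protofilaments,
    outer = 2 * pi * geom$r_outer * geom$dimer_repeat / geom$protofilaments,
    ct    = 2 * pi * geom$r_ct * geom$ct_length,
    stop("unknown surface tag: ", surface, call. = FALSE))
  q_e * constants$e / area
}

#' Surface charge density from a per-dimer charge
#'
#' Spreads a protein charge over the relevant cylindrical surface. Wall
#' charges are per tubulin heterodimer and occupy 1/13 of an 8 nm ring
#' (13 protofilaments, 8 nm axial repeat); the C-terminus charge (-11 e)
#' is spread over the lateral area of a 0.5 nm x 4 nm cylinder.
#'
#' @param charge_e Charge in multiples of the elementary charge.
#' @param surface One of `"inner"`, `"outer"`, `"ct"`.
#' @param geometry A [microtubule_spec()].
#' @param constants A [pb_constants()] object.
#' @return Surface charge density in C/m^2.
#' @examples
#' surface_charge_density(-25, "outer") # ~ -0.083
#' @export
surface_charge_density <- function(charge_e, surface = c("inner", "outer", "ct"),
                                   geometry = microtubule_spec(),
                                   constants = pb_constants()) {
  surface <- match.arg(surface)
  .sigma_from_charge(charge_e, surface, geometry, constants)
}
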