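#' Boltzmann ion concentrations at a potential
#'
#' For a symmetric monovalent salt, `c+ = c_s exp(-eV/k_B T)` and
#' `c- = c_s exp(+eV/k_B T)`; their product is `c_s^2` at any potential.
#'
#' @param V Potential in volts (vector).
#' @param buffer A [buffer_spec()].
#' @param constants A [pb_constants()].
#' @return A tibble with columns `c_cation`, `c_anion` (mol/m^3).
#' @export
concentrations_from_potential <- function(V, buffer,
                                          constants = pb_constants()) {
  Vt <- thermal_voltage(constants)
  tibble::tibble(c_cation = buffer$c_s * exp(-V / Vt),
                 c_anion  = buffer$c_s * exp(V / Vt))
}

# trapezoid of 2*pi*r*f over [r_lo, r_hi], with linear interpolation of f
# at the clipped endpoints
.radial_integral <- function(r, f, r_lo, r_hi) {
  if (r_hi <= r_lo) return(0)
  inside <- r > r_lo & r < r_hi
  xs <- c(r_lo, r[inside], r_hi)
  fs <- c(stats::approx(r, f, xout = r_lo, rule = 2)$y,
          f[inside],
          stats::approx(r, f, xout = r_hi, rule = 2)$y)
  g <- 2 * pi * xs * fs
  sum(diff(xs) * (g[-1] + g[-length(g)]) / 2)
}

#' Thermal-voltage bound layer of a solved profile
#'
#' Ions sitting at potentials below the (negative) threshold — by default
#' minus one thermal voltage, -25.68 mV at 298 K — are counted as bound to
#' the polyelectrolyte. For an exterior profile the bound layer is the
#' annulus from the outer Helmholtz plane (OHP) out to the first radius
#' where `V` rises through the threshold (located by linear interpolation
#' between grid nodes); `extent` is its thickness measured from the OHP.
#' For the lumen the bound region runs from the crossing radius in to the
#' wall, and `extent` is measured from the physical lumen surface, so it
#' saturates at the lumen radius when the entire lumen is bound.
#'
#' Bound charges are `2 pi N_A e integral of c r dr` over the bound region,
#' reported per unit length of cylinder.
#'
#' @param profile A `cylpb_profile` from [solve_nlpb()].
#' @param threshold Binding potential in volts (negative). Default
#'   `-thermal_voltage()` at the profile's temperature.
#' @return A one-row tibble: `side`, `c_s`, `threshold_V`, `extent_m`,
#'   `r_cross_m`, `q_cation_C_per_m`, `q_anion_C_per_m`, `q_net_C_per_m`,
#'   `empty`.
#' @export
bound_layer <- function(profile, threshold = NULL) {
  stopifnot(inherits(profile, "cylpb_profile"))
  if (!profile$converged)
    stop("profile did not converge; refusing to summarize", call. = FALSE)
  if (is.null(threshold)) threshold <- -thermal_voltage(profile$constants)
  stopifnot(threshold < 0)
  d <- profile$data
  e <- profile$constants$e; N_A <- profile$constants$N_A

  if (profile$side == "exterior") {
    if (d$V[1] >= threshold) {
      return(.bound_row(profile, threshold, extent = 0,
                        r_cross = profile$r_ohp, lo = NA, hi = NA))
    }
    ix <- which(d$V >= threshold)[1]       # first node past the crossing
    r_cross <- if (is.na(ix)) profile$r_max else {
      stats::approx(d$V[(ix - 1):ix], d$r[(ix - 1):ix],
                    xout = threshold)$y
    }
    .bound_row(profile, threshold, extent = r_cross - profile$r_ohp,
               r_cross = r_cross, lo = profile$r_ohp, hi = r_cross)
  } else {
    n <- nrow(d)
    if (d$V[n] >= threshold) {             # wall itself above threshold
      return(.bound_row(profile, threshold, extent = 0,
                        r_cross = profile$r_ohp, lo = NA, hi = NA))
    }
    if (d$V[1] < threshold) {              # whole lumen bound
      return(.bound_row(profile, threshold, extent = profile$R,
                        r_cross = 0, lo = 0, hi = profile$r_ohp))
    }
    ix <- which(d$V < threshold)[1]        # first bound node (toward wall)
    r_cross <- stats::approx(d$V[(ix - 1):ix], d$r[(ix - 1):ix],
                             xout = threshold)$y
    .bound_row(profile, threshold, extent = min(profile$R - r_cross,
                                                profile$R),
               r_cross = r_cross, lo = r_cross, hi = profile$r_ohp)
  }
}

.bound_row <- function(profile, threshold, extent, r_cross, lo, hi) {
  e <- profile$constants$e; N_A <- profile$constants$N_A
  d <- profile$data
  if (is.na(lo)) {
    qc <- qa <- 0
  } else {
    qc <- N_A * e * .radial_integral(d$r, d$c_cation, lo, hi)
    qa <- -N_A * e * .radial_integral(d$r, d$c_anion, lo, hi)
  }
  tibble::tibble(
    side = profile$side, c_s = profile$buffer$c_s,
    threshold_V = threshold,
    extent_m = extent, r_cross_m = r_cross,
    q_cation_C_per_m = qc, q_anion_C_per_m = qa,
    q_net_C_per_m = qc + qa,
    empty = is.na(lo))
}

#' Lumen electroneutrality residual
#'
#' The flux boundary condition at the lumen wall implies that the total ion
#' charge per unit length inside the lumen neutralizes the inner-wall
#' surface charge. This residual,
#' `|Q_ion + 2 pi R_i sigma_i| / |2 pi R_i sigma_i|`, verifies that the
#' discrete solution honours that Gauss-law identity; converged solves stay
#' below 1e-3.
#'
#' @param profile An interior `cylpb_profile`.
#' @return Dimensionless relative residual (0 for an uncharged wall).
#' @export
lumen_electroneutrality_residual <- function(profile) {
  stopifnot(inherits(profile, "cylpb_profile"), profile$side == "interior")
  if (profile$sigma == 0) return(0)
  e <- profile$constants$e; N_A <- profile$constants$N_A
  d <- profile$data
  q_ion <- N_A * e *
    .radial_integral(d$r, d$c_cation - d$c_anion, 0, profile$r_ohp)
  q_wall <- 2 * pi * profile$R * profile$sigma
  abs(q_ion + q_wall) / abs(q_wall)
}

#' Local ionic conductivity profile
#'
#' Equates the local conductivity with the local charge-carrier content:
#' `sigma(r) = lambda_K c+(r) + lambda_Cl c-(r)`, assuming the molar
#' conductivity of each ion along an equipotential equals its bulk value.
#'
#' @param profile A `cylpb_profile`.
#' @param buffer A [buffer_spec()] supplying the molar conductivities
#'   (default: the profile's own buffer).
#' @return The profile tibble with an added `sigma_local` column (S/m).
#' @export
local_conductivity <- function(profile, buffer = profile$buffer) {
  stopifnot(inherits(profile, "cylpb_profile"))
  dplyr::mutate(profile$data,
                sigma_local = buffer$lambda_cation * .data$c_cation +
                  buffer$lambda_anion * .data$c_anion)
}

#' Mean axial conductivity of the protein-ion complex
#'
#' Integrates the local ionic conductivity over the mobile-ion regions of
#' the complex — the lumen, the bound annulus outside the outer wall, and
#' (optionally) the bound annuli of the C-termini — and normalizes the
#' summed per-length conductance by the cross-section of the complex:
#' `A_norm = pi r_cross^2`, where `r_cross` is the radius at which the
#' outer-wall potential crosses the binding threshold (the MT cross-section
#' plus its bound layer). The 13 C-termini are treated as independent
#' infinite cylinders electrically in parallel with the SMT; they add
#' conductance but not normalization area. Protein electronic conduction is
#' taken as negligible.
#'
#' The thermal-voltage criterion fixes the outer boundary of the complex.
#' For the lumen — which lies inside the complex whether or not its ions
#' pass the binding criterion — the default (`lumen_region = "fluid"`)
#' counts all lumen electrolyte as carriers; `"bound"` restricts the lumen
#' integral to the sub-region beyond the binding threshold, which zeroes
#' the lumen term at high concentration.
#'
#' @param lumen,outer,ct `cylpb_profile`s solved at the same buffer
#'   (`ct` may be NULL when `mt$include_ct` is FALSE).
#' @param mt A [microtubule_spec()].
#' @param threshold Binding potential (V, negative); default one negative
#'   thermal voltage.
#' @param lumen_region `"fluid"` (default) or `"bound"`; see Details.
#' @return A one-row tibble: per-length conductances `G_lumen`, `G_outer`,
#'   `G_ct_each` (S m), `n_ct_parallel`, `A_norm_m2`, `sigma_mean_S_per_m`,
#'   `sigma_buffer_S_per_m`, `ratio`.
#' @export
mean_axial_conductivity <- function(lumen, outer, ct = NULL,
                                    mt = microtubule_spec(),
                                    threshold = NULL,
                                    lumen_region = c("fluid", "bound")) {
  lumen_region <- match.arg(lumen_region)
  stopifnot(inherits(lumen, "cylpb_profile"), lumen$side == "interior",
            inherits(outer, "cylpb_profile"), outer$side == "exterior")
  if (mt$include_ct && is.null(ct))
    stop("`mt$include_ct` is TRUE but no CT profile supplied", call. = FALSE)
  cs <- c(lumen$buffer$c_s, outer$buffer$c_s,
          if (!is.null(ct)) ct$buffer$c_s)
  if (max(cs) - min(cs) > 1e-12 * max(cs))
    stop("profiles were solved at different buffer concentrations",
         call. = FALSE)
  if (is.null(threshold)) threshold <- -thermal_voltage(lumen$constants)

  G_of <- function(profile) {
    bl <- bound_layer(profile, threshold)
    if (bl$empty) return(0)
    lc <- local_conductivity(profile)
    lo <- if (profile$side == "interior") bl$r_cross_m else profile$r_ohp
    hi <- if (profile$side == "interior") profile$r_ohp else bl$r_cross_m
    .radial_integral(lc$r, lc$sigma_local, lo, hi)
  }
  G_lumen <- if (lumen_region == "fluid") {
    lc <- local_conductivity(lumen)
    .radial_integral(lc$r, lc$sigma_local, 0, lumen$r_ohp)
  } else G_of(lumen)
  G_outer <- G_of(outer)
  G_ct <- if (!is.null(ct)) G_of(ct) else 0
  bl_out <- bound_layer(outer, threshold)
  A_norm <- pi * (if (bl_out$empty) mt$r_outer
                  else max(bl_out$r_cross_m, mt$r_outer))^2
  n_ct <- if (mt$include_ct) mt$protofilaments else 0
  G_tot <- G_lumen + G_outer + n_ct * G_ct
  sig_buf <- buffer_conductivity(outer$buffer)
  tibble::tibble(
    c_s = outer$buffer$c_s,
    G_lumen = G_lumen, G_outer = G_outer, G_ct_each = G_ct,
    n_ct_parallel = n_ct, A_norm_m2 = A_norm,
    sigma_mean_S_per_m = G_tot / A_norm,
    sigma_buffer_S_per_m = sig_buf,
    ratio = G_tot / A_norm / sig_buf)
}

#' Net charge per heterodimer of the microtubule-ion complex
#'
#' Adds the modelled protein charge per dimer (-5 lumen, -25 outer wall,
#' 2 x -11 C-termini = -52 e for a full MT) to the thermally bound ionic
#' charge: wall contributions convert per-length charge through one dimer's
#' share of the lattice (8 nm repeat / 13 protofilaments); the C-terminus
#' contribution is the effective CT cylinder's per-length bound charge
#' attributed over the tail-bearing 4 nm segment per dimer
#' (`mt$ct_bound_length_per_dimer`; the remainder of the infinite model
#' cylinder stands in for tail-free gaps and is not double-counted).
#'
#' @param lumen_bl,outer_bl,ct_bl One-row bound-layer tibbles from
#'   [bound_layer()] (`ct_bl` may be NULL when CT are excluded).
#' @param mt A [microtubule_spec()].
#' @param constants A [pb_constants()].
#' @return A one-row tibble with the protein, per-surface bound, total
#'   bound and net charges, all in multiples of e per heterodimer.
#' @export
net_complex_charge_per_dimer <- function(lumen_bl, outer_bl, ct_bl = NULL,
                                         mt = microtubule_spec(),
                                         constants = pb_constants()) {
  cs <- c(lumen_bl$c_s, outer_bl$c_s, if (!is.null(ct_bl)) ct_bl$c_s)
  if (max(cs) - min(cs) > 1e-12 * max(cs))
    stop("bound layers computed at different buffer concentrations",
         call. = FALSE)
  per_dimer_wall <- mt$dimer_repeat / mt$protofilaments / constants$e
  q_lumen <- lumen_bl$q_net_C_per_m * per_dimer_wall
  q_outer <- outer_bl$q_net_C_per_m * per_dimer_wall
  q_ct <- if (mt$include_ct && !is.null(ct_bl))
    ct_bl$q_net_C_per_m * mt$ct_bound_length_per_dimer / constants$e
  else 0
  q_protein <- mt$protein_charge_per_dimer_e
  tibble::tibble(
    c_s = outer_bl$c_s,
    q_protein_e = q_protein,
    q_bound_lumen_e = q_lumen, q_bound_outer_e = q_outer,
    q_bound_ct_e = q_ct,
    q_bound_total_e = q_lumen + q_outer + q_ct,
    q_net_e = q_protein + q_lumen + q_outer + q_ct)
}

#' C-terminus potential-well overlap
#'
#' Neighbouring C-termini sit about 4 nm apart along a protofilament. Their
#' thermal-voltage potential wells overlap when the bound-layer radius of a
#' single CT (cylinder radius + Stern distance + bound extent) reaches half
#' that spacing. Screening shrinks the well, so the overlap flag can only
#' switch off as concentration rises.
#'
#' @param ct_bl A bound-layer row from [bound_layer()] for a CT profile.
#' @param mt A [microtubule_spec()] (supplies the CT spacing).
#' @return A one-row tibble: `overlap` (logical), `margin_m`
#'   (well radius minus half-spacing), `well_radius_m`.
#' @export
ct_overlap <- function(ct_bl, mt = microtubule_spec()) {
  well <- ct_bl$r_cross_m
  half <- mt$ct_spacing / 2
  tibble::tibble(c_s = ct_bl$c_s,
                 overlap = ct_bl$extent_m > 0 & well >= half,
                 margin_m = well - half,
                 well_radius_m = well)
}
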