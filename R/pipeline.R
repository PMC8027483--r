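#' Solve one surface end-to-end
#'
#' Convenience wrapper that solves a single sub-problem of the microtubule
#' model — the lumen (`"lumen"`), the outer wall of a subtilisin-digested
#' microtubule (`"smt-outer"`), or an isolated C-terminus (`"ct"`) — and
#' attaches its bound-layer summary. Optionally writes the profile as CSV
#' with a JSON metadata sidecar.
#'
#' @param geometry One of `"lumen"`, `"smt-outer"`, `"ct"`.
#' @param buffer A [buffer_spec()] (or use `c_mM` for KCl shorthand).
#' @param c_mM Bulk KCl concentration in mM, used when `buffer` is missing.
#' @param mt A [microtubule_spec()].
#' @param perm A [permittivity_model()].
#' @param opts A [solver_options()].
#' @param threshold Binding potential (V); default minus one thermal voltage.
#' @param out_dir Directory to write `profile_<geometry>.csv` and
#'   `summary_<geometry>.json` into, or NULL (default) to skip writing.
#' @param constants A [pb_constants()].
#' @return A list: `profile` (`cylpb_profile`), `bound` (one-row tibble
#'   from [bound_layer()]), `glance` (one-row solver summary).
#' @export
run_scenario <- function(geometry = c("smt-outer", "lumen", "ct"),
                         buffer = NULL, c_mM = NULL,
                         mt = microtubule_spec(),
                         perm = permittivity_model(),
                         opts = solver_options(),
                         threshold = NULL, out_dir = NULL,
                         constants = pb_constants()) {
  geometry <- match.arg(geometry)
  if (is.null(buffer)) {
    if (is.null(c_mM)) stop("supply `buffer` or `c_mM`", call. = FALSE)
    buffer <- kcl_buffer(c_mM)
  }
  cyl <- switch(geometry, lumen = mt$inner, `smt-outer` = mt$outer,
                ct = mt$ct)
  profile <- solve_nlpb(cyl, buffer, perm, opts, constants)
  bound <- bound_layer(profile, threshold)
  gl <- generics::glance(profile)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- gsub("-", "_", geometry)
    write_profile_csv(profile,
                      file.path(out_dir, paste0("profile_", tag, ".csv")))
    jsonlite::write_json(
      list(geometry = geometry, bound = bound, glance = gl),
      file.path(out_dir, paste0("summary_", tag, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  list(profile = profile, bound = bound, glance = gl)
}

# solve the three sub-problems at one buffer and assemble the per-scenario
# summary row used by sweeps and reports
.solve_complex <- function(buffer, mt, perm, opts, threshold, constants) {
  lumen <- solve_nlpb(mt$inner, buffer, perm, opts, constants)
  outer <- solve_nlpb(mt$outer, buffer, perm, opts, constants)
  ct <- solve_nlpb(mt$ct, buffer, perm, opts, constants)
  bl_l <- bound_layer(lumen, threshold)
  bl_o <- bound_layer(outer, threshold)
  bl_c <- bound_layer(ct, threshold)
  mt_full <- mt; mt_full$include_ct <- TRUE
  mt_full$protein_charge_per_dimer_e <-
    mt$q_inner_e + mt$q_outer_e + mt$ct_per_dimer * mt$q_ct_e
  mt_smt <- mt; mt_smt$include_ct <- FALSE
  cond_mt <- mean_axial_conductivity(lumen, outer, ct, mt_full, threshold)
  cond_smt <- mean_axial_conductivity(lumen, outer, NULL, mt_smt, threshold)
  qn <- net_complex_charge_per_dimer(bl_l, bl_o, bl_c, mt_full, constants)
  ov <- ct_overlap(bl_c, mt)
  summary <- tibble::tibble(
    c_s_M = buffer$c_s / 1e3,
    c_s_mM = buffer$c_s,
    sigma_buffer_S_per_m = cond_mt$sigma_buffer_S_per_m,
    sigma_smt_S_per_m = cond_smt$sigma_mean_S_per_m,
    sigma_mt_S_per_m = cond_mt$sigma_mean_S_per_m,
    t_bound_outer_m = bl_o$extent_m,
    t_bound_lumen_m = bl_l$extent_m,
    t_bound_ct_m = bl_c$extent_m,
    q_bound_per_dimer_e = qn$q_bound_total_e,
    q_net_per_dimer_e = qn$q_net_e,
    ct_overlap = ov$overlap,
    electroneutrality_residual = lumen_electroneutrality_residual(lumen),
    converged = lumen$converged && outer$converged && ct$converged)
  list(lumen = lumen, outer = outer, ct = ct,
       bounds = list(lumen = bl_l, outer = bl_o, ct = bl_c),
       conductivity = list(mt = cond_mt, smt = cond_smt),
       net_charge = qn, summary = summary)
}

#' Concentration sweep over the full complex
#'
#' Solves the lumen, outer-wall and C-terminus problems on a log-spaced
#' concentration grid and tabulates, per concentration, the buffer / SMT /
#' MT conductivities, bound-layer extents, bound and net charge per dimer,
#' the CT overlap flag and the lumen electroneutrality residual.
#'
#' @param c_min_mM,c_max_mM Sweep range in mM (defaults 0.01-500, i.e.
#'   10 uM to 500 mM).
#' @param n_points Number of log-spaced grid points (>= 2).
#' @param include_canonical Insert the canonical study concentrations
#'   (10 uM, 100 uM, 1, 10, 100, 160, 500, 501 mM) that fall inside the
#'   range exactly (default TRUE).
#' @inheritParams run_scenario
#' @return A `cylpb_sweep` tibble, one row per concentration, ordered by
#'   concentration, with a `provenance` attribute recording the model
#'   configuration.
#' @export
run_sweep <- function(c_min_mM = 0.01, c_max_mM = 500, n_points = 25,
                      include_canonical = TRUE,
                      mt = microtubule_spec(),
                      perm = permittivity_model(),
                      opts = solver_options(),
                      threshold = NULL,
                      constants = pb_constants()) {
  stopifnot(c_min_mM > 0, c_max_mM > c_min_mM, n_points >= 2)
  cs <- exp(seq(log(c_min_mM), log(c_max_mM), length.out = n_points))
  if (include_canonical) {
    can <- canonical_concentrations_mM()
    cs <- sort(unique(c(cs, can[can >= c_min_mM & can <= c_max_mM])))
  }
  rows <- purrr::map(cs, function(c_mM) {
    res <- .solve_complex(kcl_buffer(c_mM), mt, perm, opts, threshold,
                          constants)
    res$summary
  })
  out <- dplyr::bind_rows(rows)
  if (any(!out$converged))
    warning("some sweep rows did not converge", call. = FALSE)
  attr(out, "provenance") <- list(
    perm_mode = perm$mode, eps_w = perm$eps_w, eps_K = perm$eps_K,
    stern_m = kcl_buffer(1)$d_stern, n_grid = opts$n_grid,
    r_max_factor = opts$r_max_factor, temperature_K = constants$T,
    include_ct = mt$include_ct)
  class(out) <- c("cylpb_sweep", class(out))
  out
}

#' The canonical study concentrations (mM)
#'
#' Every buffer concentration examined individually in the analysis:
#' 10 uM, 100 uM, 1 mM, 10 mM, 100 mM, 160 mM (BRB80 ionic strength),
#' 500 mM and 501 mM.
#'
#' @return Numeric vector of concentrations in mM.
#' @export
canonical_concentrations_mM <- function() c(0.01, 0.1, 1, 10, 100, 160, 500, 501)

#' Buffer-crossover concentration
#'
#' Finds the buffer concentration at which the mean axial conductivity of
#' the complex equals the bulk buffer conductivity — below it the complex
#' is the better conductor, above it the buffer is. The root of
#' `sigma_mean(c) - sigma_buffer(c)` is bracketed (optionally from a
#' pre-computed sweep) and refined by bisection on log concentration with
#' direct solves.
#'
#' @param structure `"mt"` (with C-termini) or `"smt"` (without).
#' @param sweep Optional `cylpb_sweep` used to narrow the starting bracket.
#' @param bracket_mM Search bracket in mM (default 0.01-500).
#' @param tol Relative tolerance on the crossover concentration (default
#'   1e-3).
#' @inheritParams run_scenario
#' @return A one-row tibble: `structure`, `c_cross_mM`, `n_solves`,
#'   `residual_rel` (relative conductivity mismatch at the root).
#' @export
find_crossover <- function(structure = c("mt", "smt"), sweep = NULL,
                           bracket_mM = c(0.01, 500), tol = 1e-3,
                           mt = microtubule_spec(),
                           perm = permittivity_model(),
                           opts = solver_options(),
                           threshold = NULL,
                           constants = pb_constants()) {
  structure <- match.arg(structure)
  n_solves <- 0L
  fdiff <- function(c_mM) {
    n_solves <<- n_solves + 1L
    res <- .solve_complex(kcl_buffer(c_mM), mt, perm, opts, threshold,
                          constants)
    sm <- if (structure == "mt") res$summary$sigma_mt_S_per_m
    else res$summary$sigma_smt_S_per_m
    sm - res$summary$sigma_buffer_S_per_m
  }
  lo <- bracket_mM[1]; hi <- bracket_mM[2]
  if (!is.null(sweep)) {
    col <- if (structure == "mt") sweep$sigma_mt_S_per_m
    else sweep$sigma_smt_S_per_m
    f <- col - sweep$sigma_buffer_S_per_m
    sgn <- which(f[-1] * f[-length(f)] <= 0)
    if (length(sgn)) {
      lo <- max(lo, sweep$c_s_mM[sgn[1]])
      hi <- min(hi, sweep$c_s_mM[sgn[1] + 1])
    }
  }
  f_lo <- fdiff(lo); f_hi <- fdiff(hi)
  if (f_lo * f_hi > 0)
    stop("no sign change of sigma_mean - sigma_buffer in the bracket [",
         lo, ", ", hi, "] mM", call. = FALSE)
  while (log(hi / lo) > tol) {
    mid <- sqrt(lo * hi)
    f_mid <- fdiff(mid)
    if (f_lo * f_mid <= 0) { hi <- mid; f_hi <- f_mid }
    else { lo <- mid; f_lo <- f_mid }
  }
  root <- sqrt(lo * hi)
  res <- .solve_complex(kcl_buffer(root), mt, perm, opts, threshold,
                        constants)
  sm <- if (structure == "mt") res$summary$sigma_mt_S_per_m
  else res$summary$sigma_smt_S_per_m
  tibble::tibble(structure = structure, c_cross_mM = root,
                 n_solves = n_solves + 1L,
                 residual_rel = abs(sm - res$summary$sigma_buffer_S_per_m) /
                   res$summary$sigma_buffer_S_per_m)
}

#' Full study report
#'
#' Runs the canonical scenario list end-to-end — the per-concentration
#' complex summaries, the 10 uM MT/SMT conductivity pair, and the two
#' crossover concentrations — and returns everything as tibbles. The
#' computation is deterministic: regenerating the report reproduces it
#' exactly.
#'
#' @inheritParams run_scenario
#' @param concentrations_mM Concentrations to tabulate (defaults to
#'   [canonical_concentrations_mM()]).
#' @param crossovers Also locate the MT and SMT crossover concentrations
#'   (default TRUE; the slowest part).
#' @param out_file Optional path for a JSON dump of the report.
#' @return A list of tibbles: `scenarios`, `conductivity_10uM`,
#'   `crossovers` (NULL unless requested), plus `config`.
#' @export
mt_report <- function(concentrations_mM = canonical_concentrations_mM(),
                      crossovers = TRUE,
                      mt = microtubule_spec(),
                      perm = permittivity_model(),
                      opts = solver_options(),
                      threshold = NULL, out_file = NULL,
                      constants = pb_constants()) {
  scen <- purrr::map(concentrations_mM, function(c_mM) {
    .solve_complex(kcl_buffer(c_mM), mt, perm, opts, threshold,
                   constants)$summary
  })
  scen <- dplyr::bind_rows(scen)
  cond10 <- dplyr::filter(scen, abs(.data$c_s_mM - 0.01) < 1e-12)
  cond10 <- tibble::tibble(
    sigma_mt_mS_per_m = cond10$sigma_mt_S_per_m * 1e3,
    sigma_smt_mS_per_m = cond10$sigma_smt_S_per_m * 1e3,
    pct_decrease_without_ct =
      100 * (cond10$sigma_mt_S_per_m - cond10$sigma_smt_S_per_m) /
      cond10$sigma_mt_S_per_m)
  cross <- NULL
  if (crossovers) {
    cross <- dplyr::bind_rows(
      find_crossover("mt", bracket_mM = c(10, 500), mt = mt, perm = perm,
                     opts = opts, threshold = threshold,
                     constants = constants),
      find_crossover("smt", bracket_mM = c(10, 500), mt = mt, perm = perm,
                     opts = opts, threshold = threshold,
                     constants = constants))
  }
  cfg <- tibble::tibble(
    perm_mode = perm$mode, eps_w = perm$eps_w, eps_K = perm$eps_K,
    stern_nm = kcl_buffer(1)$d_stern * 1e9, temperature_K = constants$T,
    n_grid = opts$n_grid, r_max_factor = opts$r_max_factor,
    protein_charge_per_dimer_e = mt$q_inner_e + mt$q_outer_e +
      mt$ct_per_dimer * mt$q_ct_e)
  report <- list(scenarios = scen, conductivity_10uM = cond10,
                 crossovers = cross, config = cfg)
  if (!is.null(out_file)) {
    jsonlite::write_json(report, out_file, auto_unbox = TRUE, digits = NA)
  }
  report
}
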