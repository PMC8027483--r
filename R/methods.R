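#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy cylpb_profile
#' @export
tidy.cylpb_profile <- function(x, ...) x$data

#' One-row summary of a solved profile
#'
#' @param x A `cylpb_profile`.
#' @param ... Unused.
#' @return A one-row tibble with the scenario, the potential, field,
#'   permittivity and cation concentration at the outer Helmholtz plane,
#'   and the convergence report.
#' @method glance cylpb_profile
#' @export
glance.cylpb_profile <- function(x, ...) {
  ohp <- if (x$side == "exterior") 1L else nrow(x$data)
  tibble::tibble(
    side = x$side, R_m = x$R, sigma_C_per_m2 = x$sigma,
    c_s_mM = x$buffer$c_s, d_stern_m = x$d_stern,
    perm_mode = x$perm$mode, eps_w = x$perm$eps_w, eps_K = x$perm$eps_K,
    temperature_K = x$constants$T,
    V_ohp = x$data$V[ohp], E_ohp = x$data$E[ohp],
    eps_ohp = x$data$eps[ohp], c_cation_ohp = x$data$c_cation[ohp],
    lambda_D_m = debye_length(x$buffer, x$perm$eps_w, x$constants),
    n_grid = nrow(x$data), r_max_m = x$r_max,
    outer_iterations = x$iterations[["outer"]],
    newton_iterations = x$iterations[["newton"]],
    residual = x$residual, converged = x$converged,
    far_field_ok = x$far_field_ok)
}

#' @export
print.cylpb_profile <- function(x, ...) {
  cat(sprintf(
    "<cylpb_profile> %s problem, R = %.3g nm, sigma = %.3g C/m^2\n",
    x$side, x$R * 1e9, x$sigma))
  cat(sprintf("  KCl %.4g mM, %s permittivity (eps_w = %.3g, eps_K = %.3g)\n",
              x$buffer$c_s, x$perm$mode, x$perm$eps_w, x$perm$eps_K))
  ohp <- if (x$side == "exterior") 1L else nrow(x$data)
  cat(sprintf("  V(OHP) = %.2f mV, eps(OHP) = %.1f, %s (%d outer / %d Newton)\n",
              x$data$V[ohp] * 1e3, x$data$eps[ohp],
              if (x$converged) "converged" else "NOT converged",
              x$iterations[["outer"]], x$iterations[["newton"]]))
  invisible(x)
}

#' Plot a solved radial profile
#'
#' Facets the potential (mV), field magnitude (V/m), local relative
#' permittivity and the two ion concentrations (mM) against distance from
#' the outer Helmholtz plane in nanometres.
#'
#' @param object A `cylpb_profile`.
#' @param log_dist Log-scale the distance axis (default TRUE for exterior
#'   profiles).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cylpb_profile
#' @export
autoplot.cylpb_profile <- function(object, log_dist = object$side == "exterior",
                                   ...) {
  d <- object$data
  long <- tidyr::pivot_longer(
    dplyr::transmute(d,
                     dist_nm = .data$dist * 1e9,
                     `V (mV)` = .data$V * 1e3,
                     `E (V/m)` = .data$E,
                     `eps_r` = .data$eps,
                     `c+ (mM)` = .data$c_cation,
                     `c- (mM)` = .data$c_anion),
    -"dist_nm", names_to = "quantity", values_to = "value")
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$dist_nm, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 2) +
    ggplot2::labs(
      x = "distance from OHP (nm)", y = NULL,
      title = sprintf("%s profile, KCl %.4g mM", object$side,
                      object$buffer$c_s)) +
    ggplot2::theme_minimal()
  if (log_dist) {
    eps_floor <- max(min(d$dist[d$dist > 0]) * 1e9, 1e-6)
    p <- p + ggplot2::scale_x_log10(
      limits = c(eps_floor, NA))
  }
  p
}

#' Plot a concentration sweep
#'
#' Buffer, SMT and MT mean conductivities against buffer concentration on
#' log-log axes; the crossings with the buffer line are the crossover
#' concentrations.
#'
#' @param object A `cylpb_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cylpb_sweep
#' @export
autoplot.cylpb_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "c_s_mM",
                  buffer = "sigma_buffer_S_per_m",
                  SMT = "sigma_smt_S_per_m", MT = "sigma_mt_S_per_m"),
    -"c_s_mM", names_to = "system", values_to = "sigma")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$c_s_mM, y = .data$sigma,
                                     colour = .data$system)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "KCl concentration (mM)",
                  y = "mean axial conductivity (S/m)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
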