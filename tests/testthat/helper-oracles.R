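# Frozen high-precision oracle values (40-digit arbitrary-precision
# evaluation of the closed forms) and an independent linear-PB solver.

ORACLE <- list(
  thermal_voltage_298 = 0.02567965312119263,      # k_B T / e at 298 K
  langevin_1          = 0.9391058564979939,       # 3(coth(1) - 1)/1
  booth_E10_78.5      = 75.41494442532112,        # 1.8 + 76.7 L(0.8)
  debye_150mM_78.5    = 7.852582257177533e-10,    # m
  debye_10uM_78.5     = 9.617409846658772e-08,    # m
  debye_160mM_78.5    = 7.603230076693108e-10,    # m
  grahame_V0_100mM    = -0.07932515236478149,     # V, sigma = -0.083 C/m^2
  eps_conc_1M         = 72.16379310344828,        # eps_w 78.5, eps_K 5, 1 M
  sigma_inner         = -0.024664630231373865,    # C/m^2, -5 e per dimer
  sigma_outer         = -0.08287315757741619,     # C/m^2, -25 e per dimer
  sigma_ct            = -0.14024688205408893      # C/m^2, -11 e over CT
)

# Independent numeric solver for the *linearized* PB equation
# (1/r) d/dr (r dV/dr) = V / lambda_D^2 on a uniform grid with second-order
# central differences and a dense solve. Shares no code with the package's
# finite-volume Newton path; used as the numeric-BVP oracle for the
# analytic Bessel solutions.
lpb_fd_solve <- function(R, sigma, c_s_mM, eps_r = 78.5, d = 0.33e-9,
                         side = "exterior", n = 2400, r_max_factor = 20,
                         constants = pb_constants()) {
  buf <- buffer_spec(c_s_mM, d_stern = d)
  lD <- debye_length(buf, eps_r, constants)
  if (side == "exterior") {
    r <- seq(R + d, R + d + r_max_factor * lD, length.out = n)
  } else {
    r <- seq(0, R - d, length.out = n)
  }
  h <- r[2] - r[1]
  # rows are scaled (interior by h^2, boundary by h) to keep the dense
  # system well-conditioned at nanometre grid spacings
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- 1 - h / (2 * r[i])
    A[i, i + 1] <- 1 + h / (2 * r[i])
    A[i, i] <- -2 - h^2 / lD^2
  }
  if (side == "exterior") {
    # flux BC at OHP (one-sided 2nd order), Dirichlet 0 far away
    A[1, 1:3] <- c(-3, 4, -1) / 2
    b[1] <- -h * sigma / (eps_r * constants$eps0) * R / (R + d)
    A[n, n] <- 1
  } else {
    A[1, 1:3] <- c(-3, 4, -1) / 2   # symmetry at the axis
    b[1] <- 0
    A[n, (n - 2):n] <- c(1, -4, 3) / 2
    b[n] <- h * sigma / (eps_r * constants$eps0) * R / (R - d)
  }
  list(r = r, V = solve(A, b))
}

# small solver options used throughout the tests: accurate enough for the
# stated tolerances, fast enough for the full suite
test_opts <- function(n_grid = 800, ...) solver_options(n_grid = n_grid, ...)
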