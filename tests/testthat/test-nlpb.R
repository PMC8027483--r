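mt <- microtubule_spec()

test_that("uncharged cylinder gives identically zero potential", {
  buf <- kcl_buffer(160)
  for (cyl in list(cylinder_spec(12.5e-9, 0, "exterior"),
                   cylinder_spec(8.4e-9, 0, "interior"))) {
    p <- solve_nlpb(cyl, buf, opts = test_opts(400))
    expect_true(p$converged)
    expect_equal(max(abs(p$data$V)), 0)
    expect_equal(p$data$c_cation, rep(buf$c_s, 400))
    expect_equal(p$data$c_anion, rep(buf$c_s, 400))
  }
})

test_that("nonlinear solver agrees with the analytic solution in the linear regime", {
  buf <- kcl_buffer(160)
  # exterior
  cyl <- cylinder_spec(12.5e-9, -1e-4, "exterior")
  p <- solve_nlpb(cyl, buf, permittivity_model("constant"), test_opts())
  expect_lt(max(abs(p$data$V)), 0.1 * thermal_voltage())
  Va <- lpb_exterior_potential(cyl, buf, 78.5, p$data$r)
  expect_lt(max(abs(p$data$V - Va)) / max(abs(Va)), 5e-3)
  # interior
  cyli <- cylinder_spec(8.4e-9, -1e-4, "interior")
  pi_ <- solve_nlpb(cyli, buf, permittivity_model("constant"), test_opts())
  Vai <- lpb_interior_potential(cyli, buf, 78.5, pi_$data$r)
  expect_lt(max(abs(pi_$data$V - Vai)) / max(abs(Vai)), 5e-3)
})

test_that("nonlinear-to-linear deviation vanishes cubically in sigma", {
  buf <- kcl_buffer(160)
  dev <- sapply(c(1, 0.5, 0.25), function(f) {
    cyl <- cylinder_spec(12.5e-9, -5e-3 * f, "exterior")
    p <- solve_nlpb(cyl, buf, permittivity_model("constant"),
                    test_opts(1500))
    Va <- lpb_exterior_potential(cyl, buf, 78.5, p$data$r)
    max(abs(p$data$V - Va))
  })
  # Richardson: sinh is odd, so the leading nonlinear correction is
  # O(sigma^3) and halving sigma cuts the deviation by ~8
  expect_gt(dev[1] / dev[2], 5)
  expect_lt(dev[1] / dev[2], 11)
  expect_gt(dev[2] / dev[3], 5)
  expect_lt(dev[2] / dev[3], 11)
})

test_that("planar limit reproduces the Grahame surface potential", {
  oc <- make_gouy_chapman_case(c_s_mM = 100, sigma = -0.083)
  p <- solve_nlpb(oc$cyl, oc$buffer, oc$perm, test_opts(1200))
  expect_equal(oc$expected$V0, ORACLE$grahame_V0_100mM, tolerance = 1e-12)
  expect_lt(abs(p$data$V[1] - oc$expected$V0) / abs(oc$expected$V0), 5e-3)
  # and the full Gouy-Chapman tanh profile within a few Debye lengths
  sel <- p$data$dist < 5 * oc$expected$lambda_D
  Vexp <- oc$expected$profile(p$data$dist[sel])
  expect_lt(max(abs(p$data$V[sel] - Vexp)) / abs(oc$expected$V0), 5e-3)
})

test_that("Boltzmann identity holds at machine precision on the converged grid", {
  p <- solve_nlpb(mt$outer, kcl_buffer(160), opts = test_opts())
  expect_equal(p$data$c_cation * p$data$c_anion,
               rep(p$buffer$c_s^2, nrow(p$data)), tolerance = 1e-12)
})

test_that("exterior screening is complete (Gauss's law)", {
  cst <- pb_constants()
  for (case in list(list(cyl = mt$outer, c = 160),
                    list(cyl = mt$ct, c = 10))) {
    p <- solve_nlpb(case$cyl, kcl_buffer(case$c), opts = test_opts(1200))
    q_ion <- cst$N_A * cst$e *
      cylpb:::.radial_integral(p$data$r, p$data$c_cation - p$data$c_anion,
                               p$r_ohp, p$r_max)
    q_surf <- 2 * pi * p$R * p$sigma
    expect_lt(abs(q_ion + q_surf) / abs(q_surf), 1e-3)
  }
})

test_that("lumen solve is Gauss-consistent and electroneutral", {
  p <- solve_nlpb(mt$inner, kcl_buffer(160), opts = test_opts(1200))
  expect_lt(lumen_electroneutrality_residual(p), 1e-3)
  # |V| maximal at the wall, decaying toward the axis
  expect_true(all(diff(abs(p$data$V)) >= -1e-18))
  expect_equal(which.max(abs(p$data$V)), nrow(p$data))
  # and the very-low-concentration lumen (strongly nonlinear) also closes
  p2 <- solve_nlpb(mt$inner, kcl_buffer(0.01), opts = test_opts(1200))
  expect_lt(lumen_electroneutrality_residual(p2), 1e-3)
})

test_that("potential magnitude decays monotonically away from the surface", {
  for (c_mM in c(0.1, 160)) {
    p <- solve_nlpb(mt$outer, kcl_buffer(c_mM), opts = test_opts())
    expect_true(all(diff(abs(p$data$V)) <= 1e-18))
    expect_true(p$far_field_ok)
  }
})

test_that("solution is grid-converged at second order and truncation-independent", {
  V_ohp <- sapply(c(400, 800, 1600), function(n) {
    solve_nlpb(mt$outer, kcl_buffer(160), opts = test_opts(n))$data$V[1]
  })
  order <- log2(abs(V_ohp[2] - V_ohp[1]) / abs(V_ohp[3] - V_ohp[2]))
  expect_gt(order, 1.7)
  expect_lt(order, 2.3)
  # doubling the grid changes V(OHP) by < 1e-4 relative at production size
  v1 <- solve_nlpb(mt$outer, kcl_buffer(160), opts = test_opts(2000))$data$V[1]
  v2 <- solve_nlpb(mt$outer, kcl_buffer(160), opts = test_opts(4000))$data$V[1]
  expect_lt(abs(v2 - v1) / abs(v1), 1e-4)
  # doubling the truncation radius leaves bound-layer observables unchanged
  b1 <- bound_layer(solve_nlpb(mt$outer, kcl_buffer(160),
                               opts = test_opts(1500, r_max_factor = 40)))
  b2 <- bound_layer(solve_nlpb(mt$outer, kcl_buffer(160),
                               opts = test_opts(1500, r_max_factor = 80)))
  expect_lt(abs(b1$extent_m - b2$extent_m) / b1$extent_m, 1e-4)
  expect_lt(abs(b1$q_net_C_per_m - b2$q_net_C_per_m) / abs(b1$q_net_C_per_m),
            1e-4)
})

test_that("self-consistent permittivity drops at the surface and recovers in the bulk", {
  p <- solve_nlpb(mt$outer, kcl_buffer(160), permittivity_model("full"),
                  test_opts(1200))
  lD <- debye_length(p$buffer)
  expect_lt(p$data$eps[1], 70)            # well below bulk at the OHP
  # recovers the bulk-electrolyte value (water minus the 160 mM ion
  # decrement) within a few Debye lengths
  eps_bulk <- permittivity_field(0, p$buffer$c_s, p$perm, p$buffer$c_max)
  tail <- p$data$eps[p$data$dist > 5 * lD]
  expect_true(all(abs(tail - eps_bulk) < 0.2))
  expect_true(all(p$data$eps > 1.8 & p$data$eps <= 78.5 + 1e-9))
})

test_that("model variants: constant permittivity is mild, linearization is not", {
  v160 <- compare_model_variants(mt$outer, kcl_buffer(160),
                                 opts = test_opts())
  d160 <- v160$deviations
  ref160 <- d160$max_abs_V_alpha[1]
  # constant-permittivity NLPB stays close to the full model
  expect_lt(d160$max_abs_dV[d160$pair == "beta_vs_alpha"] / ref160, 0.12)
  v10 <- compare_model_variants(mt$outer, kcl_buffer(10), opts = test_opts())
  d10 <- v10$deviations
  # the linear solution degrades much faster as screening weakens
  rel_gamma_10 <- d10$max_abs_dV[d10$pair == "gamma_vs_alpha"] /
    d10$max_abs_V_alpha[1]
  rel_gamma_160 <- d160$max_abs_dV[d160$pair == "gamma_vs_alpha"] / ref160
  expect_gt(rel_gamma_10, 2 * rel_gamma_160)
  expect_gt(rel_gamma_10, 1)   # completely inaccurate at 10 mM
  # with no charge all variants coincide at zero
  v0 <- compare_model_variants(cylinder_spec(12.5e-9, 0, "exterior"),
                               kcl_buffer(160), opts = test_opts(400))
  expect_equal(max(v0$deviations$max_abs_dV), 0)
})

test_that("solver reports convergence metadata and is deterministic", {
  p1 <- solve_nlpb(mt$outer, kcl_buffer(160), opts = test_opts())
  p2 <- solve_nlpb(mt$outer, kcl_buffer(160), opts = test_opts())
  expect_identical(p1$data, p2$data)
  expect_true(p1$converged)
  expect_gt(p1$iterations[["newton"]], 0)
  gl <- glance(p1)
  expect_s3_class(gl, "tbl_df")
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
})
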