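mt <- microtubule_spec()

test_that("Boltzmann concentrations: trivial values and invariant product", {
  buf <- kcl_buffer(160)
  cc <- concentrations_from_potential(0, buf)
  expect_equal(cc$c_cation, 160)
  expect_equal(cc$c_anion, 160)
  cc <- concentrations_from_potential(-thermal_voltage(), buf)
  expect_equal(cc$c_cation, exp(1) * 160, tolerance = 1e-12)
  V <- seq(-0.3, 0.3, length.out = 31)
  cc <- concentrations_from_potential(V, buf)
  expect_equal(cc$c_cation * cc$c_anion, rep(160^2, 31), tolerance = 1e-12)
})

test_that("bound layer: extent, charges, degenerate thresholds", {
  p <- solve_nlpb(mt$outer, kcl_buffer(160), opts = test_opts(1200))
  bl <- bound_layer(p)
  expect_gt(bl$extent_m, 0)
  expect_equal(bl$r_cross_m - p$r_ohp, bl$extent_m)
  expect_gt(bl$q_cation_C_per_m, 0)
  expect_lt(bl$q_anion_C_per_m, 0)
  expect_equal(bl$q_net_C_per_m, bl$q_cation_C_per_m + bl$q_anion_C_per_m)
  # V at the interpolated crossing equals the threshold
  Vc <- approx(p$data$r, p$data$V, xout = bl$r_cross_m)$y
  expect_equal(Vc, bl$threshold_V, tolerance = 1e-6)
  # an absurdly deep threshold empties the bound set
  bl0 <- bound_layer(p, threshold = -10)
  expect_true(bl0$empty)
  expect_equal(bl0$extent_m, 0)
  expect_equal(bl0$q_net_C_per_m, 0)
})

test_that("lumen bound layer saturates at the lumen radius at low concentration", {
  p <- solve_nlpb(mt$inner, kcl_buffer(0.01), opts = test_opts(1200))
  bl <- bound_layer(p)
  expect_equal(bl$extent_m, mt$r_inner)    # whole lumen bound
  expect_equal(bl$r_cross_m, 0)
  # essentially all neutralizing charge is inside
  q_wall <- 2 * pi * mt$r_inner * abs(mt$inner$sigma)
  expect_equal(bl$q_net_C_per_m, q_wall, tolerance = 2e-3)
  # at 500 mM the wall potential is too shallow to bind anything
  p5 <- solve_nlpb(mt$inner, kcl_buffer(500), opts = test_opts(1200))
  bl5 <- bound_layer(p5)
  expect_true(bl5$empty)
  expect_equal(bl5$q_net_C_per_m, 0)
})

test_that("electroneutrality residual is zero for an uncharged wall", {
  p <- solve_nlpb(cylinder_spec(8.4e-9, 0, "interior"), kcl_buffer(160),
                  opts = test_opts(400))
  expect_equal(lumen_electroneutrality_residual(p), 0)
})

test_that("local conductivity reduces to the buffer value without charge", {
  buf <- kcl_buffer(160)
  p <- solve_nlpb(cylinder_spec(12.5e-9, 0, "exterior"), buf,
                  opts = test_opts(400))
  lc <- local_conductivity(p)
  expect_equal(lc$sigma_local, rep(buffer_conductivity(buf), 400),
               tolerance = 1e-12)
  # charged surface: conductivity enhanced at the wall, bulk-like far away
  p2 <- solve_nlpb(mt$outer, buf, opts = test_opts())
  lc2 <- local_conductivity(p2)
  expect_gt(lc2$sigma_local[1], 5 * buffer_conductivity(buf))
  expect_equal(lc2$sigma_local[nrow(lc2)], buffer_conductivity(buf),
               tolerance = 1e-3)
})

test_that("mean conductivity bookkeeping: components, normalization, flags", {
  buf <- kcl_buffer(160)
  lumen <- solve_nlpb(mt$inner, buf, opts = test_opts())
  outer <- solve_nlpb(mt$outer, buf, opts = test_opts())
  ct <- solve_nlpb(mt$ct, buf, opts = test_opts())
  res <- mean_axial_conductivity(lumen, outer, ct, mt)
  expect_true(all(c(res$G_lumen, res$G_outer, res$G_ct_each) >= 0))
  expect_equal(res$n_ct_parallel, 13)
  bl_o <- bound_layer(outer)
  expect_equal(res$A_norm_m2, pi * bl_o$r_cross_m^2)
  expect_gte(res$A_norm_m2, pi * mt$r_outer^2)
  expect_equal(res$sigma_mean_S_per_m,
               (res$G_lumen + res$G_outer + 13 * res$G_ct_each) /
                 res$A_norm_m2)
  # removing the CT cannot increase the mean (same normalization)
  mt_smt <- microtubule_spec(include_ct = FALSE)
  res_smt <- mean_axial_conductivity(lumen, outer, NULL, mt_smt)
  expect_lt(res_smt$sigma_mean_S_per_m, res$sigma_mean_S_per_m)
  # lumen region flag: fluid >= bound, identical when the lumen is fully bound
  res_bound <- mean_axial_conductivity(lumen, outer, ct, mt,
                                       lumen_region = "bound")
  expect_gte(res$G_lumen, res_bound$G_lumen)
  lumen_lo <- solve_nlpb(mt$inner, kcl_buffer(0.1), opts = test_opts())
  outer_lo <- solve_nlpb(mt$outer, kcl_buffer(0.1), opts = test_opts())
  ct_lo <- solve_nlpb(mt$ct, kcl_buffer(0.1), opts = test_opts())
  rf <- mean_axial_conductivity(lumen_lo, outer_lo, ct_lo, mt)
  rb <- mean_axial_conductivity(lumen_lo, outer_lo, ct_lo, mt,
                                lumen_region = "bound")
  expect_equal(rf$G_lumen, rb$G_lumen, tolerance = 1e-10)
  # mismatched buffers are refused
  expect_error(mean_axial_conductivity(lumen_lo, outer, ct, mt),
               "different buffer")
})

test_that("uncharged complex has zero bound conductance", {
  buf <- kcl_buffer(160)
  mt0 <- microtubule_spec(q_inner_e = 0, q_outer_e = 0, q_ct_e = 0)
  lumen <- solve_nlpb(mt0$inner, buf, opts = test_opts(400))
  outer <- solve_nlpb(mt0$outer, buf, opts = test_opts(400))
  ct <- solve_nlpb(mt0$ct, buf, opts = test_opts(400))
  res <- mean_axial_conductivity(lumen, outer, ct, mt0,
                                 lumen_region = "bound")
  expect_equal(res$sigma_mean_S_per_m, 0)
  expect_equal(res$A_norm_m2, pi * mt0$r_outer^2)
})

test_that("net complex charge: conversions conserve totals", {
  buf <- kcl_buffer(1)
  bl_l <- bound_layer(solve_nlpb(mt$inner, buf, opts = test_opts()))
  bl_o <- bound_layer(solve_nlpb(mt$outer, buf, opts = test_opts()))
  bl_c <- bound_layer(solve_nlpb(mt$ct, buf, opts = test_opts()))
  qn <- net_complex_charge_per_dimer(bl_l, bl_o, bl_c, mt)
  e <- pb_constants()$e
  conv <- mt$dimer_repeat / mt$protofilaments / e
  expect_equal(qn$q_bound_lumen_e, bl_l$q_net_C_per_m * conv)
  expect_equal(qn$q_bound_outer_e, bl_o$q_net_C_per_m * conv)
  expect_equal(qn$q_bound_ct_e,
               bl_c$q_net_C_per_m * mt$ct_bound_length_per_dimer / e)
  expect_equal(qn$q_net_e, qn$q_protein_e + qn$q_bound_total_e)
  expect_equal(qn$q_protein_e, -52)
  # with nothing bound the net charge is the protein charge exactly
  empty <- bl_l
  empty$q_net_C_per_m <- 0
  empty_o <- bl_o; empty_o$q_net_C_per_m <- 0
  empty_c <- bl_c; empty_c$q_net_C_per_m <- 0
  qn0 <- net_complex_charge_per_dimer(empty, empty_o, empty_c, mt)
  expect_equal(qn0$q_net_e, -52)
})

test_that("CT potential wells overlap at low salt and separate under screening", {
  bl10 <- bound_layer(solve_nlpb(mt$ct, kcl_buffer(10), opts = test_opts()))
  ov10 <- ct_overlap(bl10, mt)
  expect_true(ov10$overlap)
  expect_gt(ov10$margin_m, 0)
  expect_equal(ov10$well_radius_m, bl10$r_cross_m)
  bl160 <- bound_layer(solve_nlpb(mt$ct, kcl_buffer(160),
                                  opts = test_opts()))
  ov160 <- ct_overlap(bl160, mt)
  expect_lt(ov160$well_radius_m, ov10$well_radius_m)
  # empty bound layer cannot overlap
  bl_none <- bl160
  bl_none$extent_m <- 0
  bl_none$r_cross_m <- mt$r_ct + kcl_buffer(160)$d_stern
  expect_false(ct_overlap(bl_none, mt)$overlap)
})
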