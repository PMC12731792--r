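# Tissue model: packaged constants, hemoglobin blending, stack assembly.

test_that("packaged layer properties round-trip through stack construction", {
  # spot values from the reference table
  mu <- tracheal_properties("mucosa")
  expect_equal(mu$thickness_mm, 0.35)
  wl <- tracheal_properties()$wavelengths_nm
  expect_identical(wl, c(500, 542, 556, 576, 586))
  expect_equal(mu$mu_a[wl == 542], 3.6)
  expect_equal(mu$mu_s[wl == 542], 142)
  expect_equal(mu$g[wl == 542], 0.73)
  adv <- tracheal_properties("adventitia")
  expect_equal(adv$mu_a[wl == 500], 2.1)
  expect_equal(adv$mu_s[wl == 500], 80)
  expect_equal(adv$g[wl == 500], 0.85)
  expect_equal(tracheal_properties("perichondrium")$mu_a_oxy[wl == 576], 6.84)
  expect_error(tracheal_properties("cartilago"), "unknown layer")

  # bit-exact round trip through build_stack
  st <- build_stack("six", probe_side = "mucosal", perichondrium = "oxy")
  expect_identical(st$layers$mucosa$mu_a, tracheal_properties("mucosa")$mu_a)
  expect_identical(st$layers$perichondrium_upper$mu_a,
                   tracheal_properties("perichondrium")$mu_a_oxy)
  expect_identical(st$layers$adventitia$mu_s,
                   tracheal_properties("adventitia")$mu_s)
  expect_equal(st$n, 1.37)
})

test_that("chromophore rows have the canonical spectral shapes", {
  tab <- chromophore_table()
  wl <- tab$wavelengths_nm
  expect_true(all(tab$mu_a_HbO2 > 0) && all(tab$mu_a_Hb > 0))
  # HbO2: local maxima at 542 and 576 relative to 500/556/586
  o <- tab$mu_a_HbO2
  expect_gt(o[wl == 542], o[wl == 500])
  expect_gt(o[wl == 542], o[wl == 556])
  expect_gt(o[wl == 576], o[wl == 556])
  expect_gt(o[wl == 576], o[wl == 586])
  # Hb: single maximum at 556
  h <- tab$mu_a_Hb
  expect_true(all(h[wl == 556] > h[wl != 556]))
  # verbatim (uncorrected) rows are the swap
  raw <- chromophore_table(corrected = FALSE)
  expect_identical(raw$mu_a_Hb, tab$mu_a_HbO2)
  expect_identical(raw$mu_a_HbO2, tab$mu_a_Hb)
})

test_that("blend_absorption is an affine blend reproducing the printed perichondrium rows", {
  # identity at zero blood fraction
  expect_equal(blend_absorption(3.3, 0.7, 0, 542), 3.3)
  # worked arithmetic on the corrected rows
  expect_equal(blend_absorption(4.0, 1, 0.01, 542), 4.0 + 0.01 * 285)
  expect_equal(blend_absorption(3.0, 0, 0.01, 556), 3.0 + 0.01 * 292)

  # affine in blood_fraction and in sto2: three-point collinearity
  for (s in c(0, 0.3, 1)) {
    f <- c(0.002, 0.011, 0.02)
    v <- blend_absorption(2.5, s, f, 576)
    expect_equal(v[2], (v[1] + v[3]) / 2, tolerance = 1e-12)
  }
  for (f in c(0.005, 0.02)) {
    s <- c(0.1, 0.5, 0.9)
    v <- vapply(s, function(si) blend_absorption(2.5, si, f, 586),
                numeric(1))
    expect_equal(v[2], (v[1] + v[3]) / 2, tolerance = 1e-12)
  }

  # printed perichondrium rows equal cartilage base + 1% blend within
  # 0.05 cm^-1 at 542-586 nm (500 nm is a known anomaly of the source
  # table and is excluded)
  peri <- tracheal_properties("perichondrium")
  cart <- tracheal_properties("cartilage")
  wl <- tracheal_properties()$wavelengths_nm
  sel <- wl >= 542
  oxy_pred <- blend_absorption(cart$mu_a[sel], 1, 0.01, wl[sel])
  deoxy_pred <- blend_absorption(cart$mu_a[sel], 0, 0.01, wl[sel])
  expect_true(all(abs(oxy_pred - peri$mu_a_oxy[sel]) <= 0.05))
  expect_true(all(abs(deoxy_pred - peri$mu_a_deoxy[sel]) <= 0.05))

  expect_error(blend_absorption(1, 0.5, -0.01, 542), "nonnegative")
  expect_error(blend_absorption(1, 0.5, 0.01, 550), "grid")
})

test_that("stack variants have the documented thicknesses and ordering", {
  st6 <- build_stack("six")
  expect_equal(vapply(st6$layers, `[[`, numeric(1), "thickness_mm"),
               c(mucosa = 0.35, submucosa = 0.55,
                 perichondrium_upper = 0.1, cartilage = 0.8,
                 perichondrium_lower = 0.1, adventitia = 0.1))
  expect_equal(stack_thickness(st6), 2.0)

  st4 <- build_stack("four")
  expect_equal(unname(vapply(st4$layers, `[[`, numeric(1), "thickness_mm")),
               c(0.35, 0.55, 1.0, 0.1))

  # additivity of an override
  sto <- build_stack("four", thickness = list(mucosa = 0.15))
  expect_equal(stack_thickness(sto), 1.8)
  expect_identical(sto$layers$submucosa, st4$layers$submucosa)

  # adventitial access reverses traversal order
  sta <- build_stack("six", probe_side = "adventitial")
  expect_identical(names(sta$layers), rev(names(st6$layers)))
  expect_identical(sta$layers$adventitia$mu_a, st6$layers$adventitia$mu_a)

  expect_error(build_stack("four", thickness = list(mucosa = 0)),
               "positive")
  expect_error(build_stack("four", thickness = list(muscle = 0.3)),
               "unknown layer")
})

test_that("whole-stack perfusion blends every layer's bloodless baseline", {
  ps <- perfusion_state(0.5, 0.01)
  st <- build_stack("four", perfusion = ps)
  st0 <- build_stack("four")
  tab <- chromophore_table()
  wl <- st$wavelengths_nm
  add <- 0.01 * (0.5 * tab$mu_a_HbO2 + 0.5 * tab$mu_a_Hb)
  for (nm in names(st$layers)) {
    expect_equal(st$layers[[nm]]$mu_a, st0$layers[[nm]]$mu_a + add,
                 tolerance = 1e-12)
  }
  # six-layer perichondrium-only blending uses the cartilage baseline
  st6 <- build_stack("six", perfusion = list(perichondrium = ps))
  cart <- tracheal_properties("cartilage")$mu_a
  expect_equal(st6$layers$perichondrium_upper$mu_a, cart + add,
               tolerance = 1e-12)
  expect_identical(st6$layers$mucosa$mu_a, st0$layers$mucosa$mu_a)

  expect_error(perfusion_state(1.2, 0.01), "sto2")
  expect_error(perfusion_state(0.5, -1), "nonnegative")
})

test_that("stack_config is a faithful plain-list export", {
  st <- build_stack("six", probe_side = "adventitial")
  cfg <- stack_config(st)
  expect_identical(cfg$variant, "six")
  expect_identical(cfg$probe_side, "adventitial")
  expect_equal(length(cfg$layers), 6)
  expect_identical(cfg$layers[[1]]$name, "adventitia")
  expect_identical(cfg$layers[[1]]$mu_a, st$layers$adventitia$mu_a)
})
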