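# Monte Carlo transport: sampling primitives, conservation, detector
# behaviour and agreement with the independent reference walker.

test_that("Henyey-Greenstein sampling matches the closed form", {
  expect_equal(sample_hg_deflection(0, 0.5), 0)
  expect_equal(sample_hg_deflection(0, 1), 1)
  expect_equal(sample_hg_deflection(0, 0), -1)
  # closed-form arithmetic at g = 0.5, u = 0.5
  expect_equal(sample_hg_deflection(0.5, 0.5), 0.6875, tolerance = 1e-12)
  # range and endpoint behaviour over a parameter sweep
  for (g in c(-0.9, -0.3, 0.2, 0.73, 0.95)) {
    u <- seq(0, 1, length.out = 101)
    ct <- sample_hg_deflection(g, u)
    expect_true(all(ct >= -1 & ct <= 1))
    expect_true(all(diff(ct) >= 0))  # inverse CDF is monotone in u
    expect_equal(ct[101], 1, tolerance = 1e-9)
  }
  # mean cosine approximates g
  set.seed(42)
  expect_equal(mean(sample_hg_deflection(0.8, runif(2e5))), 0.8,
               tolerance = 0.005)
  expect_error(sample_hg_deflection(1, 0.5), "< 1")
})

test_that("Fresnel reflectance matches the boundary physics", {
  expect_equal(fresnel_reflectance(1.37, 1.37, 0.5), 0)
  expect_equal(fresnel_reflectance(1.37, 1.0, 1), (0.37 / 2.37)^2,
               tolerance = 1e-6)
  # total internal reflection beyond the critical angle
  crit_cos <- sqrt(1 - (1 / 1.37)^2)
  expect_equal(fresnel_reflectance(1.37, 1.0, crit_cos * 0.9), 1)
  # probabilities throughout
  r <- fresnel_reflectance(1.37, 1.0, seq(0, 1, by = 0.05))
  expect_true(all(r >= 0 & r <= 1))
  # grazing incidence reflects fully
  expect_equal(fresnel_reflectance(1.0, 1.37, 0), 1, tolerance = 1e-9)
})

test_that("launch states respect the fiber face and NA cone", {
  set.seed(7)
  probe <- probe_geometry()
  L <- launch_photon(probe, 5e4)
  r <- sqrt(L$x_cm^2 + L$y_cm^2)
  expect_true(all(r <= 0.0125 + 1e-12))  # core radius 0.125 mm
  expect_true(all(L$z_cm == 0) && all(L$weight == 1))
  # directions inside the in-tissue NA cone
  cos_max <- sqrt(1 - (0.37 / 1.37)^2)
  expect_true(all(L$uz >= cos_max - 1e-12 & L$uz <= 1))
  expect_true(all(abs(sqrt(L$ux^2 + L$uy^2 + L$uz^2) - 1) < 1e-9))
  # transverse symmetry: mean transverse direction ~ 0 within 3 sigma
  se <- sd(L$ux) / sqrt(nrow(L))
  expect_lt(abs(mean(L$ux)), 3 * se)
  expect_lt(abs(mean(L$uy)), 3 * se)
  # collimated limit
  Lc <- launch_photon(probe_geometry(na = 1e-6), 100)
  expect_true(all(Lc$uz > 1 - 1e-9))
})

test_that("energy is conserved and tallies are consistent", {
  cfgN <- 2e4
  cases <- list(
    list(mu_a = 1.5, mu_s = 120, g = 0.8, d = 2),
    list(mu_a = 0.2, mu_s = 30, g = 0.0, d = 1),
    list(mu_a = 5.0, mu_s = 80, g = -0.4, d = 0.5)
  )
  for (cs in cases) {
    st <- make_slab_stack(cs$mu_a, cs$mu_s, cs$g, cs$d)
    tal <- propagate(st, 542, config = sim_config(n_photons = cfgN, seed = 9))
    total <- tal$Rd_total + tal$Td_total + tal$absorbed + tal$specular
    expect_lt(abs(total - 1), 4 / sqrt(cfgN))
    expect_lte(tal$Rd, tal$Rd_total)
    expect_lte(tal$Td, tal$Td_total)
    expect_true(all(c(tal$Rd, tal$Td, tal$Rd_total, tal$Td_total) >= 0))
    expect_true(all(c(tal$Rd_total, tal$Td_total) <= 1))
  }
  # non-absorbing medium: conservation is exact (no roulette fires)
  st0 <- make_slab_stack(0, 50, 0.9, 1)
  tal0 <- propagate(st0, 542, config = sim_config(n_photons = 5e3, seed = 2))
  expect_equal(tal0$Rd_total + tal0$Td_total + tal0$absorbed + tal0$specular,
               1, tolerance = 1e-9)
})

test_that("opaque and transparent limits behave physically", {
  # mu_a >> mu_s, thick slab: everything absorbed
  st <- make_slab_stack(200, 5, 0.5, 5)
  tal <- propagate(st, 542, config = sim_config(n_photons = 5e3, seed = 4))
  expect_lt(tal$Td_total, 1e-6)
  expect_gt(tal$absorbed, 0.95)
})

test_that("runs are deterministic under a fixed seed", {
  st <- build_stack("six")
  cfg <- sim_config(n_photons = 1e4, seed = 123)
  t1 <- simulate_spectrum(st, config = cfg)
  t2 <- simulate_spectrum(st, config = cfg)
  expect_identical(t1$Rd, t2$Rd)
  expect_identical(t1$Td, t2$Td)
  expect_identical(t1$absorbed, t2$absorbed)
  t3 <- simulate_spectrum(st, config = sim_config(n_photons = 1e4, seed = 124))
  expect_false(identical(t1$Rd, t3$Rd))
})

test_that("tally standard error shrinks as 1/sqrt(N)", {
  st <- make_slab_stack(1, 100, 0.8, 1)
  reps <- function(n, seeds) {
    vapply(seeds, function(s) {
      propagate(st, 542, config = sim_config(n_photons = n, seed = s))$Rd
    }, numeric(1))
  }
  sd_small <- sd(reps(500, 1:14))
  sd_big <- sd(reps(5e4, 1:14))
  ratio <- sd_small / sd_big  # expect ~ sqrt(100) = 10
  expect_gt(ratio, 4)
  expect_lt(ratio, 25)
  # the analytic photon-count uncertainty follows the same law
  expect_equal(photon_count_uncertainty(1e4) / photon_count_uncertainty(1e6),
               10)
})

test_that("raising absorption cannot raise the escaping fractions", {
  base <- make_slab_stack(0.5, 100, 0.85, 1.5)
  high <- make_slab_stack(2.5, 100, 0.85, 1.5)
  cfg <- sim_config(n_photons = 5e4, seed = 31)
  tb <- propagate(base, 542, config = cfg)
  th <- propagate(high, 542, config = cfg)
  expect_gt(tb$Rd_total + tb$Td_total, th$Rd_total + th$Td_total)
})

test_that("a zero-thickness layer is a no-op", {
  st3 <- make_slab_stack(c(1, 2, 1), c(100, 90, 100), c(0.8, 0.7, 0.8),
                         c(0.5, 0, 0.5))
  st2 <- make_slab_stack(c(1, 1), c(100, 100), c(0.8, 0.8), c(0.5, 0.5))
  cfg <- sim_config(n_photons = 3e4, seed = 17)
  t3 <- propagate(st3, 542, config = cfg)
  t2 <- propagate(st2, 542, config = cfg)
  # identical stream once the zero layer is dropped: bit-equal tallies
  expect_identical(t3$Rd_total, t2$Rd_total)
  expect_identical(t3$absorbed, t2$absorbed)
})

test_that("probe-side reversal is exactly a traversal-order reversal", {
  # an adventitial-side stack must simulate identically to the mucosal
  # stack with its layer list reversed by hand (same kernel input, same
  # stream)
  st_a <- build_stack("six", probe_side = "adventitial")
  st_m <- build_stack("six", probe_side = "mucosal")
  st_m$layers <- rev(st_m$layers)
  cfg <- sim_config(n_photons = 2e4, seed = 19)
  ta <- propagate(st_a, 576, config = cfg)
  tm <- propagate(st_m, 576, config = cfg)
  expect_identical(ta$Rd, tm$Rd)
  expect_identical(ta$Td_total, tm$Td_total)
  expect_identical(ta$absorbed, tm$absorbed)
})

test_that("kernel totals agree with the independent reference walker", {
  # one-layer slab oracle comparison (smaller budget than the acceptance
  # run; the acceptance suite repeats this at 1e5 photons)
  n <- 3e4
  st <- make_slab_stack(0.1, 100, 0.9, 2)  # d = 0.2 cm
  tal <- propagate(st, 542, config = sim_config(n_photons = n, seed = 13))
  ref <- reference_walker(n, 0.1, 100, 0.9, 0.2, seed = 14)
  for (q in c("rd", "td")) {
    kv <- if (q == "rd") tal$Rd_total else tal$Td_total
    rv <- ref[[paste0(q, "_total")]]
    sigma <- sqrt(binom_se(kv, n)^2 + ref[[paste0(q, "_se")]]^2)
    expect_lt(abs(kv - rv), 3 * sigma)
  }
})

test_that("detected reflectance responds to the detector model", {
  st <- build_stack("six", probe_side = "adventitial")
  cfg <- sim_config(n_photons = 3e4, seed = 8)
  ann <- propagate(st, 542, probe_geometry(detector = "annulus"), cfg)
  dsc <- propagate(st, 542, probe_geometry(detector = "disc"), cfg)
  # the annulus covers ~6x the single-fiber area
  expect_gt(ann$Rd, dsc$Rd)
  # dropping the NA test can only increase the detected fraction
  all_ang <- propagate(st, 542, probe_geometry(na_test = FALSE), cfg)
  expect_gte(all_ang$Rd, ann$Rd)
  # sanity on input validation
  expect_error(propagate(st, 999), "grid")
  expect_error(sim_config(n_photons = 0), "at least 1")
})
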