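test_that("tissue generation is deterministic under a fixed seed", {
  a <- generate_tissue_maps(small_phantom_spec(seed = 11))
  b <- generate_tissue_maps(small_phantom_spec(seed = 11))
  expect_identical(a$tissue$eps_bl0, b$tissue$eps_bl0)
  expect_identical(a$tissue$eps_ics, b$tissue$eps_ics)
  expect_identical(a$maps$ktrans_s, b$maps$ktrans_s)
  c <- generate_tissue_maps(small_phantom_spec(seed = 12))
  expect_false(identical(a$tissue$eps_bl0, c$tissue$eps_bl0))
})

test_that("degenerate ranges give constant fields", {
  ph <- generate_tissue_maps(small_phantom_spec(epsBL_range = c(0.05, 0.05)))
  tumor <- ph$tissue$grid$region == 1L
  expect_true(all(ph$tissue$eps_bl0[tumor] == 0.05))
})

test_that("generated plasma fractions span the requested range", {
  ph <- generate_tissue_maps(small_phantom_spec())
  tumor <- ph$tissue$grid$region == 1L
  ebl <- ph$tissue$eps_bl0[tumor]
  lo <- 2.22e-14; hi <- 9.66e-2
  expect_gte(min(ebl), lo)
  expect_lte(max(ebl), hi)
  # the affine rescaling attains both endpoints
  expect_equal(min(ebl), lo)
  expect_equal(max(ebl), hi)
})

test_that("volume fractions close to one at every interior voxel", {
  ph <- generate_tissue_maps(small_phantom_spec())
  tis <- ph$tissue
  interior <- tis$grid$region != 0L
  total <- tis$eps_bl0 + tis$eps_ecs0 + tis$eps_cm + tis$eps_ics
  expect_lt(max(abs(total[interior] - 1)), 1e-12)
  # intracellular fraction honours its lower bound and the closure cap
  tumor <- tis$grid$region == 1L
  expect_gte(min(tis$eps_ics[tumor]), 0.5808 - 1e-12)
  expect_lte(max(tis$eps_ics[tumor]), 1 / (1 + 0.154))
})

test_that("phantom geometry is validated", {
  expect_error(phantom_spec(grid_dims_mm = c(30, 30, 30),
                            tumor_center_mm = c(15, 15, 15),
                            tumor_radii_mm = c(20, 10, 10)),
               "inside the domain")
  expect_error(phantom_spec(epsBL_range = c(0.5, 0.2)), "low <= high")
  expect_error(phantom_spec(epsBL_range = c(-0.1, 0.2)), "\\[0, 1\\]")
})

test_that("synthetic AIF is zero pre-bolus, nonnegative, single-peaked", {
  t <- seq(0, 300, by = 0.5)
  aif <- synth_aif(t, aif_params())
  expect_true(all(aif$cb_mM[t < 10] == 0))
  expect_true(all(aif$cb_mM >= 0))
  # single interior maximum: rising to the peak, falling after it
  pk <- which.max(aif$cb_mM)
  expect_true(all(diff(aif$cb_mM[t >= 10 & t <= t[pk]]) >= 0))
  expect_true(all(diff(aif$cb_mM[pk:length(t)]) <= 0))

  z <- synth_aif(t, aif_params(A1_mM = 0, A2_mM = 0))
  expect_true(all(z$cb_mM == 0))
  expect_error(aif_params(A1_mM = -1), "nonnegative")
  expect_error(synth_aif(c(0, 0, 1)), "increasing")
})

test_that("AIF argmax matches the closed-form mode", {
  p <- aif_params()  # defaults: single component, closed form applies
  # independent closed form of the difference-of-exponentials mode
  mode_expected <- p$t0_s +
    log(p$m_fast_s / p$m_slow_s) / (p$m_fast_s - p$m_slow_s)
  expect_equal(aif_mode(p), mode_expected)
  t <- seq(0, 300, by = 0.01)
  aif <- synth_aif(t, p)
  expect_equal(t[which.max(aif$cb_mM)], mode_expected, tolerance = 0.01)
})

test_that("DCE series of zero parameter maps is flat at baseline", {
  dm <- c(4, 4, 4)
  zero <- array(0, dim = dm)
  maps <- perfusion_maps(zero, zero, zero, zero)
  aif <- synth_aif(dce_times())
  s <- generate_dce_series(maps, aif, dce_times(),
                           t10_map = array(1, dim = dm), baseline = 500)
  expect_true(all(abs(s - 500) < 1e-9))
})

test_that("noisy DCE series is reproducible under a fixed seed", {
  dm <- c(4, 4, 4)
  maps <- perfusion_maps(array(0.03, dm), array(2e-3, dm),
                         array(0.4, dm), array(0, dm))
  aif <- synth_aif(dce_times())
  t10 <- array(1.2, dim = dm)
  s1 <- generate_dce_series(maps, aif, dce_times(), t10,
                            noise_sd_frac = 0.02, seed = 5)
  s2 <- generate_dce_series(maps, aif, dce_times(), t10,
                            noise_sd_frac = 0.02, seed = 5)
  expect_identical(s1, s2)
  s3 <- generate_dce_series(maps, aif, dce_times(), t10,
                            noise_sd_frac = 0.02, seed = 6)
  expect_false(identical(s1, s3))
})
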