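acq <- acquisition_params()

test_that("SPGR enhancement is exactly 1 without contrast and matches a
           direct arithmetic evaluation at 1 mM", {
  expect_equal(spgr_signal_ratio(0, 1.0, acq), 1, tolerance = 1e-14)
  expect_equal(spgr_signal_ratio(0, 0.6, acq), 1, tolerance = 1e-14)

  # independent arithmetic transcription of the signal equation
  TR <- 6.27e-3; TE <- 3.0e-3; th <- 10 * pi / 180
  R1 <- 3.5; R2 <- 4.9; T10 <- 1; C <- 1
  E0 <- exp(-TR / T10)
  k0 <- (1 - cos(th) * E0) / (1 - E0)
  E <- exp(-TR * (1 / T10 + R1 * C))
  expected <- k0 * exp(-TE * R2 * C) * (1 - E) / (1 - cos(th) * E)
  expect_equal(spgr_signal_ratio(1, 1, acq), expected, tolerance = 1e-12)
  expect_equal(expected, 2.20, tolerance = 0.005)

  expect_error(spgr_signal_ratio(1, -0.5, acq), "positive")
  expect_error(spgr_signal_ratio(-1, 1, acq), "nonnegative")
})

test_that("SPGR enhancement increases with concentration on [0, C*]", {
  cstar <- spgr_cstar(1, acq)
  expect_gt(cstar, 1)
  cs <- seq(0, cstar, length.out = 400)
  rs <- spgr_signal_ratio(cs, 1, acq)
  expect_true(all(diff(rs) > 0))
  # just beyond the stationary point the curve turns over
  expect_lt(spgr_signal_ratio(cstar * 1.2, 1, acq),
            spgr_signal_ratio(cstar, 1, acq))
})

test_that("signal inversion recovers concentrations on the monotone branch", {
  expect_identical(concentration_from_signal(1, 1, acq), 0)
  for (C in c(0.1, 0.5, 2.0)) {
    r <- spgr_signal_ratio(C, 1, acq)
    expect_equal(concentration_from_signal(r, 1, acq), C,
                 tolerance = 1e-8)
  }
  # inverse of the worked example above
  expect_equal(concentration_from_signal(2.1985, 1, acq), 1.0,
               tolerance = 5e-3)
  expect_error(concentration_from_signal(10, 1, acq), "achievable maximum")
  expect_warning(c0 <- concentration_from_signal(0.98, 1, acq), "clamped")
  expect_identical(c0, 0)
})

test_that("T10 estimation inverts its own spin-echo forward model", {
  fse <- fse_params()
  t1 <- 1.2; t2 <- 0.09
  s1 <- fse_signal(t1, t2, fse$TR1_s, fse$TE1_s)
  s2 <- fse_signal(t1, t2, fse$TR2_s, fse$TE2_s)
  s3 <- fse_signal(t1, t2, fse$TR3_s, fse$TE3_s)
  est <- estimate_t10(s1, s2, s3, fse)
  expect_true(est$valid)
  expect_equal(est$t10_s, 1.2, tolerance = 1e-6)

  # degenerate pair: no T2 information
  bad <- estimate_t10(s1, s3, s3, fse)
  expect_false(bad$valid)
  expect_true(is.na(bad$t10_s))
})

test_that("T10 estimation degrades gracefully under 1% noise", {
  fse <- fse_params()
  set.seed(42)
  nv <- 1000
  t1 <- runif(nv, 0.7, 1.8)
  t2 <- runif(nv, 0.06, 0.12)
  noisy <- function(tr, te) {
    s <- fse_signal(t1, t2, tr, te)
    s * (1 + rnorm(nv, sd = 0.01))
  }
  est <- estimate_t10(noisy(fse$TR1_s, fse$TE1_s),
                      noisy(fse$TR2_s, fse$TE2_s),
                      noisy(fse$TR3_s, fse$TE3_s), fse)
  relerr <- abs(est$t10_s - t1) / t1
  expect_lt(median(relerr, na.rm = TRUE), 0.05)
})

test_that("tracer model reduces to its limiting forms", {
  aif <- synth_aif(dce_times())
  t <- dce_times()
  # no exchange: pure plasma term
  expect_equal(ltkm_forward(0.05, 0, 0.4, 0, aif, t), 0.05 * aif$cb_mM)
  # leakage only: plasma term plus cumulative integral of the AIF
  skip_if_not_installed("pracma")
  cum <- pracma::cumtrapz(t, aif$cb_mM)[, 1]
  expect_equal(ltkm_forward(0.05, 0, 0.4, 2e-4, aif, t),
               0.05 * aif$cb_mM + 2e-4 * cum, tolerance = 1e-12)
})

test_that("tracer convolution matches an oversampled quadrature oracle", {
  t <- dce_times()
  p <- c(epsBL = 0.05, ktrans = 5e-3, epsECS = 0.4, lambda = 1e-4)
  # the integrals run on the AIF's own sampling, so a finely sampled AIF
  # resolves the bolus-arrival kink that 3.8 s frames cannot
  tfine <- seq(0, max(t), by = 0.38)
  aif <- synth_aif(tfine)
  got <- ltkm_forward(p[1], p[2], p[3], p[4], aif, t)

  # fine-grid quadrature oracle (1000x oversampled, trapezoid)
  tf <- seq(0, max(t), length.out = length(t) * 1000)
  aif_f <- synth_aif(tf)
  kep <- p[2] / p[3]
  oracle <- vapply(t, function(ti) {
    sel <- tf <= ti
    ts <- tf[sel]; cb <- aif_f$cb_mM[sel]
    if (length(ts) < 2) return(p[1] * cb[length(cb)])
    w1 <- cb * exp(kep * (ts - ti))
    trap <- function(y) sum(diff(ts) * (y[-1] + y[-length(y)]) / 2)
    p[1] * cb[length(cb)] + p[2] * trap(w1) + p[4] * trap(cb)
  }, numeric(1))
  rel <- abs(got - oracle)[-1] / pmax(abs(oracle[-1]), 1e-12)
  expect_lt(max(rel), 5e-3)
})

test_that("noiseless voxel fits recover the generating parameters", {
  t <- dce_times()
  aif <- synth_aif(t)
  truth <- c(0.05, 0.005, 0.4, 1e-4)
  curve <- ltkm_forward(truth[1], truth[2], truth[3], truth[4], aif, t)
  fit <- fit_ltkm(curve, aif, t)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params - truth) / truth), 0.01)

  z <- fit_ltkm(rep(0, length(t)), aif, t)
  expect_identical(unname(z$params), c(0, 0, 0, 0))
  expect_identical(z$rss, 0)

  g <- fit_ltkm(curve, aif, t, gtkm = TRUE)
  expect_identical(unname(g$params["lambda_tr_s"]), 0)
  expect_gt(g$rss, fit$rss)

  expect_error(fit_ltkm(curve[1:4], aif, t[1:4]), ">= 8")
  expect_error(fit_ltkm(c(curve[-1], NA), aif, t), "finite")
})

test_that("volume-fraction closure and microvascular scaling are exact", {
  # closure arithmetic at a single voxel
  dm <- c(4, 4, 4)
  g <- build_grid(rep(8, 3), rep(2, 3), region = array(1L, dm))
  maps <- perfusion_maps(array(0.02, dm), array(3e-3, dm),
                         array(0.40, dm), array(0, dm))
  tis <- derive_property_maps(maps, g)
  expect_equal(tis$eps_ics[1], (1 - 0.02 - 0.40) / 1.154)
  expect_equal(tis$eps_ics[1], 0.50260, tolerance = 1e-5)
  expect_equal(tis$eps_cm[1], 0.07740, tolerance = 1e-5)
  total <- tis$eps_bl0 + tis$eps_ecs0 + tis$eps_cm + tis$eps_ics
  expect_lt(max(abs(total - 1)), 1e-12)

  # Ktrans-proportional surface density: twice the average -> twice SVb
  kt <- array(3e-3, dm); kt[1, 1, 1] <- 6e-3; kt[2, 1, 1] <- 0
  kt_avg <- mean(kt)
  maps2 <- perfusion_maps(array(0.02, dm), kt, array(0.40, dm),
                          array(0, dm))
  tis2 <- derive_property_maps(maps2, g)
  expect_equal(tis2$sv0[1, 1, 1], 6e-3 / kt_avg * 2.0e4)
  expect_equal(tis2$sv0[2, 1, 1], 0)

  # normal-region ratio 0.188 and normal surface-density baseline
  r <- array(1L, dm); r[, , 3:4] <- 2L; r[, , 1] <- 0L
  g2 <- set_region(g, r)
  tis3 <- derive_property_maps(maps, g2)
  expect_equal(tis3$eps_ics[1, 1, 3], (1 - 0.42) / 1.188)
  expect_equal(tis3$sv0[1, 1, 3], 7.0e3)  # ktrans == tumor average here
  # exterior voxels carry all-zero properties
  expect_true(all(tis3$eps_ecs0[, , 1] == 0) && all(tis3$sv0[, , 1] == 0))

  # infeasible fractions are clipped with a warning
  maps3 <- perfusion_maps(array(0.6, dm), array(3e-3, dm),
                          array(0.6, dm), array(0, dm))
  expect_warning(tis4 <- derive_property_maps(maps3, g), "clipped")
  expect_lte(max(tis4$eps_bl0 + tis4$eps_ecs0), 1)
})

test_that("a noiseless synthesize-and-fit round trip recovers the maps", {
  dm <- c(3, 3, 3)
  set.seed(3)
  maps <- perfusion_maps(array(runif(27, 0.01, 0.08), dm),
                         array(runif(27, 1e-3, 8e-3), dm),
                         array(runif(27, 0.25, 0.55), dm),
                         array(runif(27, 0, 2e-4), dm))
  t <- dce_times()
  aif <- synth_aif(t)
  t10 <- array(1.4, dim = dm)
  series <- generate_dce_series(maps, aif, t, t10, noise_sd_frac = 0)
  # frames before bolus arrival (10 s) serve as baseline
  fit <- fit_perfusion_maps(series, t, aif, t10, n_baseline = 2)
  for (f in c("epsBL", "ktrans_s", "epsECS", "lambda_tr_s")) {
    rel <- abs(fit[[f]] - maps[[f]]) / pmax(abs(maps[[f]]), 1e-4)
    expect_lt(max(rel), 0.01)
  }
})
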