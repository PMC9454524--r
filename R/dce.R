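#' DCE acquisition parameters
#'
#' Spoiled gradient-recalled echo (SPGR/FFE) acquisition settings of the
#' dynamic series.  Defaults follow a 3T T1-perfusion brain protocol:
#' TR 6.27 ms, TE 3.0 ms, flip angle 10 degrees, 3.8 s temporal resolution,
#' and gadoterate relaxivities R1 = 3.5, R2 = 4.9 mM^-1 s^-1.
#'
#' @param TR_s repetition time (s).
#' @param TE_s echo time (s).
#' @param flip_deg flip angle (degrees, in (0, 90)).
#' @param R1_permMs longitudinal relaxivity (mM^-1 s^-1).
#' @param R2_permMs transverse relaxivity (mM^-1 s^-1).
#' @param dt_s temporal resolution of the dynamic series (s).
#' @return a `ced_acq` parameter list (flip stored in radians as `flip_rad`).
#' @export
acquisition_params <- function(TR_s = 6.27e-3, TE_s = 3.0e-3, flip_deg = 10,
                               R1_permMs = 3.5, R2_permMs = 4.9, dt_s = 3.8) {
  stopifnot(TR_s > 0, TE_s > 0, R1_permMs > 0, R2_permMs > 0, dt_s > 0)
  if (flip_deg <= 0 || flip_deg >= 90) stop("flip angle must be in (0, 90)")
  structure(
    list(TR_s = TR_s, TE_s = TE_s, flip_rad = flip_deg * pi / 180,
         R1_permMs = R1_permMs, R2_permMs = R2_permMs, dt_s = dt_s),
    class = "ced_acq"
  )
}

#' SPGR signal enhancement ratio for a contrast concentration
#'
#' Computes I(t)/I(0) of the spoiled gradient echo sequence for contrast
#' concentration `c_mM`, including the T2* attenuation term:
#' `k0 exp(-TE R2 C) (1 - E) / (1 - cos(theta) E)` with
#' `E = exp(-TR (1/T10 + R1 C))` and `k0` the pre-contrast normalization so
#' that the ratio is exactly 1 at C = 0.
#'
#' @param c_mM contrast agent concentration (mM), vectorized.
#' @param t10_s pre-contrast T1 (s), scalar or vector.
#' @param acq a `ced_acq`.
#' @return signal ratio, dimensionless.
#' @export
spgr_signal_ratio <- function(c_mM, t10_s, acq = acquisition_params()) {
  if (any(t10_s <= 0)) stop("T10 must be positive")
  if (any(c_mM < 0)) stop("concentration must be nonnegative")
  cth <- cos(acq$flip_rad)
  e0 <- exp(-acq$TR_s / t10_s)
  k0 <- (1 - cth * e0) / (1 - e0)
  e <- exp(-acq$TR_s * (1 / t10_s + acq$R1_permMs * c_mM))
  k0 * exp(-acq$TE_s * acq$R2_permMs * c_mM) * (1 - e) / (1 - cth * e)
}

#' First stationary point of the SPGR enhancement curve
#'
#' The enhancement ratio increases with concentration at low C (T1
#' shortening) and eventually decreases (T2* losses); inversion is restricted
#' to the monotone branch `[0, C*]`.
#'
#' @param t10_s pre-contrast T1 (s).
#' @param acq a `ced_acq`.
#' @param c_max_mM upper search bound (mM).
#' @return `C*` (mM), the first stationary point of the ratio.
#' @export
spgr_cstar <- function(t10_s, acq = acquisition_params(), c_max_mM = 50) {
  f <- function(c) spgr_signal_ratio(c, t10_s, acq)
  cs <- seq(0, c_max_mM, length.out = 2001)
  rs <- f(cs)
  i <- which(diff(rs) <= 0)
  hi <- if (length(i)) cs[min(i) + 1] else c_max_mM
  lo <- max(0, hi - 2 * (cs[2] - cs[1]))
  optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

#' Invert the SPGR signal ratio to a contrast concentration
#'
#' Bracketed root finding of `spgr_signal_ratio(C) = ratio` on the monotone
#' branch `[0, C*]`; the smallest nonnegative root is returned.  Ratios below
#' 1 (noise undershoot of the pre-contrast level) are clamped to C = 0 with a
#' warning; ratios above the achievable maximum raise an error.
#'
#' @param ratio observed I(t)/I(0), vectorized (must be positive).
#' @param t10_s pre-contrast T1 (s), scalar.
#' @param acq a `ced_acq`.
#' @param tol_mM absolute root tolerance (mM).
#' @return concentration (mM).
#' @export
concentration_from_signal <- function(ratio, t10_s, acq = acquisition_params(),
                                      tol_mM = 1e-12) {
  if (any(ratio <= 0)) stop("signal ratio must be positive")
  cstar <- spgr_cstar(t10_s, acq)
  rmax <- spgr_signal_ratio(cstar, t10_s, acq)
  if (any(ratio > rmax * (1 + 1e-12))) {
    stop(sprintf(
      "signal ratio %.6g exceeds the achievable maximum %.6g on [0, C*=%.4g mM]",
      max(ratio), rmax, cstar
    ))
  }
  if (any(ratio < 1)) {
    warning("signal ratio below 1 clamped to zero concentration")
  }
  vapply(ratio, function(r) {
    if (r <= 1) return(0)
    if (r >= rmax) return(cstar)
    uniroot(function(c) spgr_signal_ratio(c, t10_s, acq) - r,
            interval = c(0, cstar), tol = tol_mM)$root
  }, numeric(1))
}

#' Fast spin-echo acquisition parameters for T10 estimation
#'
#' TR/TE pairs (s) of the three structural images used for pre-contrast T1
#' mapping: T1-weighted 360/10 ms, T2-weighted 3500/90 ms, and
#' proton-density-weighted 3500/7.2 ms.
#'
#' @param TR1_s,TE1_s T1-weighted repetition/echo time (s).
#' @param TR2_s,TE2_s T2-weighted repetition/echo time (s).
#' @param TR3_s,TE3_s PD-weighted repetition/echo time (s).
#' @return named list of the six times.
#' @export
fse_params <- function(TR1_s = 0.360, TE1_s = 0.010,
                       TR2_s = 3.500, TE2_s = 0.090,
                       TR3_s = 3.500, TE3_s = 0.0072) {
  stopifnot(TR2_s == TR3_s, TE2_s > TE3_s)
  list(TR1_s = TR1_s, TE1_s = TE1_s, TR2_s = TR2_s, TE2_s = TE2_s,
       TR3_s = TR3_s, TE3_s = TE3_s)
}

#' Forward fast spin-echo signal model
#'
#' `S = M0 (1 - exp(-TR/T1)) exp(-TE/T2)`, used to synthesize structural
#' signals and as the model inverted by [estimate_t10()].
#'
#' @param t1_s,t2_s relaxation times (s).
#' @param TR_s,TE_s sequence times (s).
#' @param m0 proton density scale.
#' @return signal (arbitrary units).
#' @export
fse_signal <- function(t1_s, t2_s, TR_s, TE_s, m0 = 1) {
  m0 * (1 - exp(-TR_s / t1_s)) * exp(-TE_s / t2_s)
}

#' Estimate pre-contrast T1 from three fast spin-echo images
#'
#' Two-ratio estimation under the FSE signal model: T2 follows from the
#' equal-TR T2-weighted/PD pair as `T2 = (TE2 - TE3) / ln(S_PD / S_T2w)`;
#' T1 is then the root of the T1-weighted/PD ratio equation with that T2.
#' Voxels with nonpositive signals, `S_PD <= S_T2w`, or a ratio outside the
#' attainable range are flagged invalid (`NA`).
#'
#' @param s_t1w,s_t2w,s_pd signal vectors/arrays (same shape).
#' @param fse a [fse_params()] list.
#' @return list with `t10_s` (same shape as input, `NA` where invalid) and
#'   logical `valid`.
#' @export
estimate_t10 <- function(s_t1w, s_t2w, s_pd, fse = fse_params()) {
  stopifnot(length(s_t1w) == length(s_t2w), length(s_t2w) == length(s_pd))
  valid <- is.finite(s_t1w) & is.finite(s_t2w) & is.finite(s_pd) &
    s_t1w > 0 & s_t2w > 0 & s_pd > s_t2w
  t2 <- rep(NA_real_, length(s_pd))
  t2[valid] <- (fse$TE2_s - fse$TE3_s) / log(s_pd[valid] / s_t2w[valid])

  # target for g(T1) = (1 - e^{-TR1/T1}) / (1 - e^{-TR3/T1}),
  # strictly decreasing from 1 (T1 -> 0) to TR1/TR3 (T1 -> infinity)
  q <- rep(NA_real_, length(s_pd))
  q[valid] <- s_t1w[valid] / s_pd[valid] *
    exp((fse$TE1_s - fse$TE3_s) / t2[valid])
  lo_q <- fse$TR1_s / fse$TR3_s
  valid <- valid & is.finite(q) & q > lo_q & q < 1

  t1 <- rep(NA_real_, length(s_pd))
  g <- function(T1) (1 - exp(-fse$TR1_s / T1)) / (1 - exp(-fse$TR3_s / T1))
  idx <- which(valid)
  for (v in idx) {
    t1[v] <- uniroot(function(T1) g(T1) - q[v],
                     interval = c(1e-4, 50), tol = 1e-10)$root
  }
  if (!is.null(dim(s_t1w))) {
    dim(t1) <- dim(s_t1w)
    dim(valid) <- dim(s_t1w)
  }
  list(t10_s = t1, valid = valid)
}

#' Leaky tracer kinetic model forward curve
#'
#' Tissue contrast concentration predicted by the leaky tracer kinetic model
#' (LTKM) for a blood input `cb(t)`:
#' `C(t) = epsBL cb(t) + Ktrans int_0^t cb(tau) exp(Ktrans/epsECS (tau - t)) dtau
#'  + lambda_tr int_0^t cb(tau) dtau`,
#' with both integrals evaluated by the trapezoid rule on the requested
#' sampling.  Setting `lambda_tr = 0` gives the general tracer kinetic model.
#'
#' @param epsBL plasma volume fraction (0..1).
#' @param ktrans_s transvascular rate Ktrans (s^-1).
#' @param epsECS extracellular volume fraction (0..1; must be positive when
#'   `ktrans_s > 0`).
#' @param lambda_tr_s leakage constant (s^-1).
#' @param aif a `ced_aif` (see [synth_aif()]).
#' @param times_s evaluation times (s); must lie within the AIF support.
#' @return concentration curve (mM) at `times_s`.
#' @export
ltkm_forward <- function(epsBL, ktrans_s, epsECS, lambda_tr_s, aif,
                         times_s = aif$times_s) {
  stopifnot(epsBL >= 0, epsBL <= 1, ktrans_s >= 0, lambda_tr_s >= 0,
            epsECS >= 0, epsECS <= 1)
  if (ktrans_s > 0 && epsECS <= 0) {
    stop("epsECS must be positive when ktrans > 0")
  }
  rng <- range(aif$times_s)
  if (any(times_s < rng[1] - 1e-9) || any(times_s > rng[2] + 1e-9)) {
    stop("requested times outside the AIF support")
  }
  # integrate on the AIF's own sampling (which may be finer than the
  # requested output times), then read off at the requested instants
  ts <- sort(unique(c(aif$times_s, times_s)))
  cb <- approx(aif$times_s, aif$cb_mM, xout = ts, rule = 2)$y
  nt <- length(ts)
  kep <- if (ktrans_s > 0) ktrans_s / epsECS else 0

  dt <- diff(ts)
  cum <- c(0, cumsum(0.5 * dt * (cb[-nt] + cb[-1])))

  conv <- numeric(nt)
  if (ktrans_s > 0) {
    # recursive exponentially-weighted trapezoid accumulation
    for (i in 2:nt) {
      e <- exp(-kep * dt[i - 1])
      conv[i] <- conv[i - 1] * e +
        0.5 * dt[i - 1] * (cb[i - 1] * e + cb[i])
    }
  }
  out <- epsBL * cb + ktrans_s * conv + lambda_tr_s * cum
  out[match(times_s, ts)]
}

#' Fit the leaky tracer kinetic model to one voxel curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the four LTKM parameters to a tissue concentration
#' curve, with fractions bounded to `[0, 1]` and rates to `[0, 1]` s^-1.
#' Three deterministic starts are tried and the lowest residual sum of
#' squares wins; ties break toward the smaller leakage constant.  With
#' `gtkm = TRUE` the leakage constant is fixed at zero (general model).
#'
#' @param curve tissue concentration samples (mM).
#' @param aif a `ced_aif`.
#' @param times_s sample times (s), same length as `curve` (>= 8 samples).
#' @param gtkm logical, fit the general (non-leaky) model.
#' @return a `ced_voxel_fit`: `params` (epsBL, ktrans_s, epsECS,
#'   lambda_tr_s), `rss`, `converged`.
#' @export
fit_ltkm <- function(curve, aif, times_s, gtkm = FALSE) {
  if (length(curve) != length(times_s) || length(curve) < 8) {
    stop("curve and times must have equal length >= 8")
  }
  if (!all(is.finite(curve)) || !all(is.finite(times_s))) {
    stop("non-finite values in curve or times")
  }
  if (all(curve == 0)) {
    return(structure(
      list(params = c(epsBL = 0, ktrans_s = 0, epsECS = 0, lambda_tr_s = 0),
           rss = 0, converged = TRUE),
      class = "ced_voxel_fit"
    ))
  }
  lower <- c(0, 0, 1e-3, 0)
  upper <- c(1, 1, 1, 1)
  resid_fn <- function(p) {
    lam <- if (gtkm) 0 else p[4]
    ltkm_forward(p[1], p[2], p[3], lam, aif, times_s) - curve
  }
  starts <- list(
    c(0.02, 0.002, 0.3, 1e-5),
    c(0.10, 0.010, 0.6, 1e-4),
    c(0.005, 0.0005, 0.15, 1e-6)
  )
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    cand <- list(par = fit$par, rss = rss,
                 converged = fit$info %in% 1:4)
    if (is.null(best) || rss < best$rss - 1e-300 ||
        (abs(rss - best$rss) <= 1e-12 * max(rss, 1e-30) &&
         cand$par[4] < best$par[4])) {
      best <- cand
    }
  }
  if (is.null(best)) stop("all LTKM fit starts failed")
  par <- best$par
  if (gtkm) par[4] <- 0
  structure(
    list(params = setNames(par, c("epsBL", "ktrans_s", "epsECS",
                                  "lambda_tr_s")),
         rss = best$rss, converged = best$converged),
    class = "ced_voxel_fit"
  )
}

#' Fit perfusion maps from a 4D DCE signal series
#'
#' Voxelwise pipeline over a masked region: normalize by the pre-bolus
#' baseline frames to get I(t)/I(0), invert the SPGR model to contrast
#' concentration, and fit the LTKM.  Voxels outside the mask get all-zero
#' parameters.
#'
#' @param series 4D array (x, y, z, t) of signal intensities.
#' @param times_s frame times (s).
#' @param aif a `ced_aif`.
#' @param t10_map 3D array of pre-contrast T1 (s), positive inside the mask.
#' @param acq a `ced_acq`.
#' @param mask logical 3D array of voxels to fit.
#' @param n_baseline number of pre-bolus frames averaged for I(0).
#' @return a `ced_perfusion`: arrays `epsBL`, `ktrans_s`, `epsECS`,
#'   `lambda_tr_s`, plus `rss` and logical `converged` diagnostics.
#' @export
fit_perfusion_maps <- function(series, times_s, aif, t10_map,
                               acq = acquisition_params(), mask = NULL,
                               n_baseline = 2) {
  dm <- dim(series)
  stopifnot(length(dm) == 4, dm[4] == length(times_s))
  if (is.null(mask)) mask <- array(TRUE, dim = dm[1:3])
  zero <- array(0, dim = dm[1:3])
  out <- list(epsBL = zero, ktrans_s = zero, epsECS = zero,
              lambda_tr_s = zero, rss = zero,
              converged = array(TRUE, dim = dm[1:3]))
  idx <- which(mask)
  nvox <- prod(dm[1:3])
  smat <- matrix(series, nrow = nvox)
  for (v in idx) {
    s <- smat[v, ]
    i0 <- mean(s[seq_len(n_baseline)])
    if (!is.finite(i0) || i0 <= 0) next
    ratio <- pmax(s / i0, 1e-6)
    conc <- suppressWarnings(
      concentration_from_signal(ratio, t10_map[v], acq)
    )
    fit <- fit_ltkm(conc, aif, times_s)
    out$epsBL[v] <- fit$params["epsBL"]
    out$ktrans_s[v] <- fit$params["ktrans_s"]
    out$epsECS[v] <- fit$params["epsECS"]
    out$lambda_tr_s[v] <- fit$params["lambda_tr_s"]
    out$rss[v] <- fit$rss
    out$converged[v] <- fit$converged
  }
  structure(out, class = "ced_perfusion")
}

#' Construct perfusion maps from arrays
#'
#' @param epsBL,ktrans_s,epsECS,lambda_tr_s 3D arrays of the four voxelwise
#'   tracer-kinetic parameters (shared shape; fractions in `[0, 1]`, rates
#'   nonnegative).
#' @return a `ced_perfusion`.
#' @export
perfusion_maps <- function(epsBL, ktrans_s, epsECS, lambda_tr_s) {
  dm <- dim(epsBL)
  stopifnot(identical(dim(ktrans_s), dm), identical(dim(epsECS), dm),
            identical(dim(lambda_tr_s), dm))
  if (any(epsBL < 0 | epsBL > 1) || any(epsECS < 0 | epsECS > 1)) {
    stop("volume fractions must lie in [0, 1]")
  }
  if (any(ktrans_s < 0) || any(lambda_tr_s < 0)) {
    stop("rates must be nonnegative")
  }
  structure(
    list(epsBL = epsBL, ktrans_s = ktrans_s, epsECS = epsECS,
         lambda_tr_s = lambda_tr_s),
    class = "ced_perfusion"
  )
}

#' Derive simulation tissue properties from perfusion maps
#'
#' Completes the per-voxel volume-fraction closure
#' `epsBL + epsECS + epsCM + epsICS = 1` using the fixed cell-membrane to
#' intracellular ratio (0.154 in tumor, 0.188 in normal tissue):
#' `epsICS = (1 - epsBL - epsECS) / (1 + ratio)`, `epsCM = ratio * epsICS`.
#' The baseline microvascular surface density is scaled voxelwise from the
#' Ktrans map, `SV0 = (Ktrans / Ktrans_avg) * SVb`, where the average is
#' taken over the tumor mask only and `SVb` is the per-region literature
#' baseline.  Exterior voxels keep all-zero properties.  Voxels with
#' `epsBL + epsECS > 1` are clipped with a warning.
#'
#' @param maps a `ced_perfusion`.
#' @param grid a `ced_grid` with region labels (shape must match the maps).
#' @param t10_map optional pre-contrast T1 array carried through.
#' @param tables tissue property tables ([tissue_tables()]).
#' @return a `ced_tissue`: the grid plus arrays `eps_bl0`, `eps_ecs0`,
#'   `eps_cm`, `eps_ics`, `sv0`, `ktrans_s`, `lambda_tr_s`, `t10_s`, and
#'   `ktrans_avg_s` (tumor-average Ktrans).
#' @export
derive_property_maps <- function(maps, grid, t10_map = NULL,
                                 tables = tissue_tables()) {
  stopifnot(inherits(maps, "ced_perfusion"), inherits(grid, "ced_grid"))
  if (!identical(dim(maps$epsBL), as.integer(grid$n))) {
    stop("perfusion maps do not match the grid shape")
  }
  interior <- grid$region != REGION_EXTERIOR
  epsBL <- ifelse(interior, maps$epsBL, 0)
  epsECS <- ifelse(interior, maps$epsECS, 0)

  over <- interior & (epsBL + epsECS > 1)
  if (any(over)) {
    warning(sprintf(
      "%d voxel(s) with epsBL + epsECS > 1 clipped to the closure bound",
      sum(over)
    ))
    scale <- (1 - 1e-6) / (epsBL[over] + epsECS[over])
    epsBL[over] <- epsBL[over] * scale
    epsECS[over] <- epsECS[over] * scale
  }

  ratio <- region_field(grid, tables$tumor$cm_ics_ratio,
                        tables$normal$cm_ics_ratio)
  eps_ics <- ifelse(interior, (1 - epsBL - epsECS) / (1 + ratio), 0)
  eps_cm <- ratio * eps_ics

  tumor <- grid$region == REGION_TUMOR
  if (!any(tumor)) stop("grid has no tumor voxels")
  ktrans_avg <- mean(maps$ktrans_s[tumor])
  if (ktrans_avg <= 0) stop("tumor-average Ktrans must be positive")
  svb <- region_field(grid, tables$tumor$SVb, tables$normal$SVb)
  sv0 <- ifelse(interior, maps$ktrans_s / ktrans_avg * svb, 0)

  structure(
    list(
      grid = grid,
      eps_bl0 = epsBL, eps_ecs0 = epsECS, eps_cm = eps_cm, eps_ics = eps_ics,
      sv0 = sv0,
      ktrans_s = ifelse(interior, maps$ktrans_s, 0),
      lambda_tr_s = ifelse(interior, maps$lambda_tr_s, 0),
      t10_s = if (is.null(t10_map)) NULL else ifelse(interior, t10_map, 0),
      ktrans_avg_s = ktrans_avg
    ),
    class = "ced_tissue"
  )
}

#' @export
print.ced_tissue <- function(x, ...) {
  tumor <- x$grid$region == REGION_TUMOR
  cat("<ced_tissue>\n")
  print(x$grid)
  cat(sprintf("  tumor epsBL  range: %.3g .. %.3g\n",
              min(x$eps_bl0[tumor]), max(x$eps_bl0[tumor])))
  cat(sprintf("  tumor epsICS range: %.3g .. %.3g\n",
              min(x$eps_ics[tumor]), max(x$eps_ics[tumor])))
  cat(sprintf("  tumor-average Ktrans: %.3g 1/s\n", x$ktrans_avg_s))
  invisible(x)
}
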