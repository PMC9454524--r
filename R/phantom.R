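#' Synthetic tissue phantom specification
#'
#' Defines the geometry and statistical structure of the synthetic
#' heterogeneous brain-tissue phantom: a box of normal tissue enclosing an
#' ellipsoidal tumor whose plasma volume fraction, intracellular fraction,
#' transvascular rate and leakage constant are smoothly correlated random
#' fields.  The default plasma-fraction range spans 2.22e-14 to 9.66e-2 and
#' the intracellular fraction starts at 0.5808, matching the spread observed
#' in patient-derived property maps; the upper intracellular bound is capped
#' at generation time by the volume-fraction closure (see vignette).
#'
#' @param grid_dims_mm physical extents of the box (mm).
#' @param voxel_mm voxel spacing (mm).
#' @param tumor_center_mm,tumor_radii_mm ellipsoid centre and semi-axes (mm);
#'   the ellipsoid must lie fully inside the domain.
#' @param epsBL_range range of the tumor plasma volume fraction.
#' @param epsICS_range target range of the tumor intracellular fraction
#'   (upper end clipped where the closure would drive epsECS below
#'   `eps_ecs_floor`).
#' @param ktrans_mean_s tumor-mean transvascular rate (s^-1).
#' @param lambda_tr_range range of the leakage constant (s^-1).
#' @param heterogeneity_corr_len_mm correlation length of the random fields.
#' @param ics_bl_anticorr weight in `[0, 1]` coupling the intracellular
#'   fraction to the (inverted) plasma fraction field: densely vascularized
#'   regions are less cell-dense, reproducing the joint structure seen in
#'   patient maps (well-perfused tumor is more porous, high cell density
#'   coincides with low microvascular density); 0 draws the fields
#'   independently.
#' @param noise_sd_frac relative Gaussian noise on synthesized DCE signals.
#' @param eps_ecs_floor minimum extracellular fraction kept free by clipping.
#' @param normal list of homogeneous normal-tissue values (`epsBL`, `epsECS`,
#'   `ktrans_s`, `lambda_tr_s`, `t10_s`).
#' @param t10_tumor_s pre-contrast T1 assigned to tumor voxels (s).
#' @param seed integer RNG seed; a fixed seed makes every generated volume
#'   bit-identical.
#' @return a `ced_phantom_spec`.
#' @export
phantom_spec <- function(grid_dims_mm = c(58, 97, 72),
                         voxel_mm = c(0.9, 0.9, 6.0),
                         tumor_center_mm = grid_dims_mm / 2,
                         tumor_radii_mm = c(12, 16, 14),
                         epsBL_range = c(2.22e-14, 9.66e-2),
                         epsICS_range = c(0.5808, 0.999),
                         ktrans_mean_s = 3e-3,
                         lambda_tr_range = c(0, 1e-4),
                         heterogeneity_corr_len_mm = 6,
                         ics_bl_anticorr = 0.6,
                         noise_sd_frac = 0.01,
                         eps_ecs_floor = 5e-3,
                         normal = list(epsBL = 0.008, epsECS = 0.20,
                                       ktrans_s = 2e-5, lambda_tr_s = 0,
                                       t10_s = 1.0),
                         t10_tumor_s = 1.4,
                         seed = 1L) {
  stopifnot(length(grid_dims_mm) == 3, length(voxel_mm) == 3,
            length(tumor_center_mm) == 3, length(tumor_radii_mm) == 3)
  if (any(voxel_mm <= 0) || any(tumor_radii_mm <= 0)) {
    stop("spacings and radii must be positive")
  }
  check_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 1) {
      stop(sprintf("%s must be a pair in [0, 1] with low <= high", nm))
    }
  }
  check_range(epsBL_range, "epsBL_range")
  check_range(epsICS_range, "epsICS_range")
  stopifnot(ics_bl_anticorr >= 0, ics_bl_anticorr <= 1)
  if (any(tumor_center_mm - tumor_radii_mm < 0) ||
      any(tumor_center_mm + tumor_radii_mm > grid_dims_mm)) {
    stop("tumor ellipsoid must lie fully inside the domain")
  }
  structure(
    list(grid_dims_mm = grid_dims_mm, voxel_mm = voxel_mm,
         tumor_center_mm = tumor_center_mm, tumor_radii_mm = tumor_radii_mm,
         epsBL_range = epsBL_range, epsICS_range = epsICS_range,
         ktrans_mean_s = ktrans_mean_s, lambda_tr_range = lambda_tr_range,
         heterogeneity_corr_len_mm = heterogeneity_corr_len_mm,
         ics_bl_anticorr = ics_bl_anticorr,
         noise_sd_frac = noise_sd_frac, eps_ecs_floor = eps_ecs_floor,
         normal = normal, t10_tumor_s = t10_tumor_s, seed = as.integer(seed)),
    class = "ced_phantom_spec"
  )
}

# Separable Gaussian smoothing of a 3D array (truncated at 4 sigma),
# normalized kernels with edge renormalization.
smooth3d <- function(a, sigma_cells) {
  dm <- dim(a)
  for (ax in 1:3) {
    s <- sigma_cells[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    ker <- exp(-0.5 * ((-half:half) / s)^2)
    n <- dm[ax]
    band <- outer(seq_len(n), seq_len(n), function(i, j) {
      d <- j - i
      (abs(d) <= half) * ker[pmin(pmax(d + half + 1, 1), length(ker))]
    })
    band <- band / rowSums(band)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    m <- band %*% matrix(ap, nrow = n)
    a <- aperm(array(m, dim = dm[perm]), order(perm))
  }
  a
}

# Smoothly correlated random field rescaled to [0, 1] over `mask`.
grf01 <- function(grid, corr_len_mm, mask) {
  z <- array(rnorm(n_cells(grid)), dim = grid$n)
  z <- smooth3d(z, corr_len_mm / grid$h_mm)
  zm <- z[mask]
  if (max(zm) == min(zm)) return(array(0.5, dim = grid$n))
  (z - min(zm)) / (max(zm) - min(zm))
}

#' Generate synthetic heterogeneous tissue and perfusion maps
#'
#' Builds the phantom grid (ellipsoidal tumor in a box of normal tissue),
#' draws smoothly correlated random fields inside the tumor for the plasma
#' volume fraction, intracellular fraction, transvascular rate (proportional
#' to the plasma fraction, i.e. correlated with vascularity) and leakage
#' constant, assigns homogeneous defaults to normal tissue and zeros to
#' exterior voxels, and completes the volume-fraction closure via
#' [derive_property_maps()].
#'
#' @param spec a [phantom_spec()].
#' @return list with `tissue` (a `ced_tissue`), `maps` (a `ced_perfusion`),
#'   and `t10_s` (pre-contrast T1 array).
#' @export
generate_tissue_maps <- function(spec) {
  stopifnot(inherits(spec, "ced_phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  grid <- build_grid(spec$grid_dims_mm, spec$voxel_mm)
  cc <- cell_centers(grid)
  r2 <- ((cc$x - spec$tumor_center_mm[1]) / spec$tumor_radii_mm[1])^2 +
    ((cc$y - spec$tumor_center_mm[2]) / spec$tumor_radii_mm[2])^2 +
    ((cc$z - spec$tumor_center_mm[3]) / spec$tumor_radii_mm[3])^2
  region <- array(REGION_NORMAL, dim = grid$n)
  region[r2 <= 1] <- REGION_TUMOR
  grid <- set_region(grid, region)
  tumor <- region == REGION_TUMOR

  cl <- spec$heterogeneity_corr_len_mm
  z_bl <- grf01(grid, cl, tumor)
  z_ind <- grf01(grid, cl, tumor)
  z_lam <- grf01(grid, cl, tumor)
  # cell density anticorrelated with vascularity (well-perfused regions are
  # more porous); rescale the mixture back onto [0, 1] over the tumor
  w <- spec$ics_bl_anticorr
  z_ics <- w * (1 - z_bl) + (1 - w) * z_ind
  zt <- z_ics[tumor]
  if (max(zt) > min(zt)) {
    z_ics <- (z_ics - min(zt)) / (max(zt) - min(zt))
  }

  epsBL <- array(spec$normal$epsBL, dim = grid$n)
  epsBL[tumor] <- spec$epsBL_range[1] +
    diff(spec$epsBL_range) * z_bl[tumor]

  # target intracellular fraction, capped so the closure keeps
  # epsECS >= eps_ecs_floor with epsCM = ratio * epsICS
  ratio_t <- tissue_tables()$tumor$cm_ics_ratio
  ics <- spec$epsICS_range[1] + diff(spec$epsICS_range) * z_ics[tumor]
  ics_cap <- (1 - epsBL[tumor] - spec$eps_ecs_floor) / (1 + ratio_t)
  ics <- pmin(ics, ics_cap)
  epsECS <- array(spec$normal$epsECS, dim = grid$n)
  epsECS[tumor] <- 1 - epsBL[tumor] - (1 + ratio_t) * ics

  ktrans <- array(spec$normal$ktrans_s, dim = grid$n)
  ktrans[tumor] <- spec$ktrans_mean_s * epsBL[tumor] / mean(epsBL[tumor])

  lam <- array(spec$normal$lambda_tr_s, dim = grid$n)
  lam[tumor] <- spec$lambda_tr_range[1] +
    diff(spec$lambda_tr_range) * z_lam[tumor]

  t10 <- array(spec$normal$t10_s, dim = grid$n)
  t10[tumor] <- spec$t10_tumor_s

  maps <- perfusion_maps(epsBL, ktrans, epsECS, lam)
  tissue <- derive_property_maps(maps, grid, t10_map = t10)
  list(tissue = tissue, maps = maps, t10_s = t10)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Parameters of the synthetic arterial input function
#'
#' Delayed double-exponential bolus-plus-washout model
#' `cb(t) = A1 (exp(-m_slow tau) - exp(-m_fast tau))
#'        + A2 (exp(-m_slow2 tau) - exp(-m_fast tau))`, `tau = t - t0`,
#' zero before the bolus arrival `t0`.  `m_fast` controls the shared rise,
#' `m_slow` the first-pass washout; the optional second component (`A2`,
#' default 0) adds a slower washout compartment.  With `A2 = 0` the curve's
#' mode is `t0 + log(m_fast / m_slow) / (m_fast - m_slow)` in closed form.
#'
#' @param t0_s bolus arrival time (s).
#' @param A1_mM,A2_mM component amplitudes (mM, nonnegative).
#' @param m_slow_s,m_fast_s,m_slow2_s rate constants (s^-1),
#'   `m_fast_s > m_slow_s`.
#' @return named parameter list.
#' @export
aif_params <- function(t0_s = 10, A1_mM = 8, A2_mM = 0,
                       m_slow_s = 0.01, m_fast_s = 0.1, m_slow2_s = 1e-3) {
  if (A1_mM < 0 || A2_mM < 0) stop("AIF amplitudes must be nonnegative")
  stopifnot(m_fast_s > m_slow_s, m_slow_s > 0, m_slow2_s > 0)
  list(t0_s = t0_s, A1_mM = A1_mM, A2_mM = A2_mM, m_slow_s = m_slow_s,
       m_fast_s = m_fast_s, m_slow2_s = m_slow2_s)
}

#' Synthesize an arterial input function
#'
#' @param times_s strictly increasing sample instants (s).
#' @param params an [aif_params()] list.
#' @return a `ced_aif`: `times_s` and blood contrast concentration `cb_mM`.
#' @export
synth_aif <- function(times_s, params = aif_params()) {
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (params$A1_mM < 0 || params$A2_mM < 0) {
    stop("AIF amplitudes must be nonnegative")
  }
  tau <- pmax(times_s - params$t0_s, 0)
  rise <- exp(-params$m_fast_s * tau)
  cb <- params$A1_mM * (exp(-params$m_slow_s * tau) - rise) +
    params$A2_mM * (exp(-params$m_slow2_s * tau) - rise)
  cb[times_s < params$t0_s] <- 0
  structure(list(times_s = times_s, cb_mM = cb), class = "ced_aif")
}

#' Mode of the synthetic AIF
#'
#' Closed form for the single-component curve (`A2 = 0`); numeric
#' maximization otherwise.
#'
#' @param params an [aif_params()] list.
#' @return time (s) at which the AIF attains its maximum.
#' @export
aif_mode <- function(params = aif_params()) {
  if (params$A2_mM == 0) {
    params$t0_s + log(params$m_fast_s / params$m_slow_s) /
      (params$m_fast_s - params$m_slow_s)
  } else {
    f <- function(t) -synth_aif(c(0, t), params)$cb_mM[2]
    optimize(f, c(params$t0_s, params$t0_s + 20 / params$m_slow_s))$minimum
  }
}

#' Synthesize a 4D DCE signal series from perfusion maps
#'
#' Forward composition of the tracer-kinetic and signal models: per voxel,
#' the LTKM predicts the contrast concentration from the AIF, the SPGR model
#' converts it to a signal enhancement ratio, and the ratio is scaled by a
#' baseline intensity; optional Gaussian noise of standard deviation
#' `noise_sd_frac * baseline` is added.
#'
#' @param maps a `ced_perfusion`.
#' @param aif a `ced_aif`.
#' @param times_s frame times (s).
#' @param t10_map pre-contrast T1 array (s), positive where tissue.
#' @param acq a `ced_acq`.
#' @param baseline baseline intensity I(0) (arbitrary units).
#' @param noise_sd_frac relative noise level; 0 for a noiseless series.
#' @param seed RNG seed for the noise (fixed seed gives identical series).
#' @param mask logical array of voxels to synthesize (default: all).
#' @return 4D array (x, y, z, t) of signal intensities.
#' @export
generate_dce_series <- function(maps, aif, times_s, t10_map,
                                acq = acquisition_params(), baseline = 1000,
                                noise_sd_frac = 0, seed = 1L, mask = NULL) {
  dm <- dim(maps$epsBL)
  if (!identical(dim(t10_map), dm)) stop("t10 map shape mismatch")
  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  if (!identical(dim(mask), dm)) stop("mask shape mismatch")
  nt <- length(times_s)
  series <- array(baseline, dim = c(dm, nt))
  smat <- matrix(series, nrow = prod(dm))
  for (v in which(mask)) {
    if (t10_map[v] <= 0) next
    conc <- ltkm_forward(maps$epsBL[v], maps$ktrans_s[v], maps$epsECS[v],
                         maps$lambda_tr_s[v], aif, times_s)
    smat[v, ] <- baseline * spgr_signal_ratio(conc, t10_map[v], acq)
  }
  if (noise_sd_frac > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    smat <- smat + rnorm(length(smat), sd = noise_sd_frac * baseline)
  }
  array(smat, dim = c(dm, nt))
}
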