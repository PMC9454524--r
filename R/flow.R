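# Quasi-steady Darcy-Starling interstitial fluid flow on the structured grid.
#
# Continuity with distributed transvascular exchange, div v = F_BL + q_in,
# closed with Darcy's law v = -(kappa/mu) grad p, gives
#   -div( (kappa/mu) grad p ) = F_BL(p) + q_in,
# with the Starling exchange linear in p and folded into the matrix diagonal.
# Momentum inertia and Brinkman drag are negligible at tissue scales
# (v ~ um/s, kappa ~ 1e-14 m^2); see the methods vignette.

# Face conductance assembly (SI units).  lam is the per-cell mobility-like
# coefficient (kappa/mu for flow, D for diffusion); zero marks an excluded
# cell (exterior or catheter shaft) whose faces carry no flux.  boundary
# "dirichlet" adds half-cell conductances on the outer boundary, "neumann"
# leaves the outer boundary closed to diffusive flux.
assemble_faces <- function(grid, lam, boundary = c("dirichlet", "neumann")) {
  boundary <- match.arg(boundary)
  n <- grid$n
  h <- grid$h_mm * 1e-3
  area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])

  harm <- function(a, b) ifelse(a > 0 & b > 0, 2 * a * b / (a + b), 0)

  gx <- array(0, dim = c(n[1] + 1, n[2], n[3]))
  gx[2:n[1], , ] <- area[1] / h[1] *
    harm(lam[1:(n[1] - 1), , , drop = FALSE], lam[2:n[1], , , drop = FALSE])
  gy <- array(0, dim = c(n[1], n[2] + 1, n[3]))
  gy[, 2:n[2], ] <- area[2] / h[2] *
    harm(lam[, 1:(n[2] - 1), , drop = FALSE], lam[, 2:n[2], , drop = FALSE])
  gz <- array(0, dim = c(n[1], n[2], n[3] + 1))
  gz[, , 2:n[3]] <- area[3] / h[3] *
    harm(lam[, , 1:(n[3] - 1), drop = FALSE], lam[, , 2:n[3], drop = FALSE])

  bnd <- list(
    xlo = matrix(0, n[2], n[3]), xhi = matrix(0, n[2], n[3]),
    ylo = matrix(0, n[1], n[3]), yhi = matrix(0, n[1], n[3]),
    zlo = matrix(0, n[1], n[2]), zhi = matrix(0, n[1], n[2])
  )
  if (boundary == "dirichlet") {
    bnd$xlo <- area[1] / (h[1] / 2) * lam[1, , ]
    bnd$xhi <- area[1] / (h[1] / 2) * lam[n[1], , ]
    bnd$ylo <- area[2] / (h[2] / 2) * lam[, 1, ]
    bnd$yhi <- area[2] / (h[2] / 2) * lam[, n[2], ]
    bnd$zlo <- area[3] / (h[3] / 2) * lam[, , 1]
    bnd$zhi <- area[3] / (h[3] / 2) * lam[, , n[3]]
  }
  list(gx = gx, gy = gy, gz = gz, bnd = bnd, area = area)
}

# Sum of face conductances entering each cell's diagonal.
face_diag <- function(grid, fc) {
  n <- grid$n
  d <- array(0, dim = n)
  d <- d + fc$gx[1:n[1], , ] + fc$gx[2:(n[1] + 1), , ]
  d <- d + fc$gy[, 1:n[2], ] + fc$gy[, 2:(n[2] + 1), ]
  d <- d + fc$gz[, , 1:n[3]] + fc$gz[, , 2:(n[3] + 1)]
  d[1, , ] <- d[1, , ] + fc$bnd$xlo
  d[n[1], , ] <- d[n[1], , ] + fc$bnd$xhi
  d[, 1, ] <- d[, 1, ] + fc$bnd$ylo
  d[, n[2], ] <- d[, n[2], ] + fc$bnd$yhi
  d[, , 1] <- d[, , 1] + fc$bnd$zlo
  d[, , n[3]] <- d[, , n[3]] + fc$bnd$zhi
  d
}

# Zero all faces touching the given linear cell indices (no-flux walls).
block_faces <- function(grid, fc, cells) {
  if (!length(cells)) return(fc)
  n <- grid$n
  ijk <- linear_to_ijk(grid, cells)
  for (r in seq_len(nrow(ijk))) {
    i <- ijk[r, 1]; j <- ijk[r, 2]; k <- ijk[r, 3]
    fc$gx[i, j, k] <- 0; fc$gx[i + 1, j, k] <- 0
    fc$gy[i, j, k] <- 0; fc$gy[i, j + 1, k] <- 0
    fc$gz[i, j, k] <- 0; fc$gz[i, j, k + 1] <- 0
    if (i == 1) fc$bnd$xlo[j, k] <- 0
    if (i == n[1]) fc$bnd$xhi[j, k] <- 0
    if (j == 1) fc$bnd$ylo[i, k] <- 0
    if (j == n[2]) fc$bnd$yhi[i, k] <- 0
    if (k == 1) fc$bnd$zlo[i, j] <- 0
    if (k == n[3]) fc$bnd$zhi[i, j] <- 0
  }
  fc
}

#' Starling transvascular fluid source
#'
#' `F_BL = L_BL (phi SV0) [p_BL - p - sigma_BL (pi_BL - pi_ISF)]` per cell
#' (s^-1); negative values indicate net reabsorption into the blood.
#'
#' @param p interstitial fluid pressure array (Pa).
#' @param phi vascular scaling field (0..1), scalar or array.
#' @param sv0 baseline vessel surface density array (m^-1).
#' @param props per-cell property arrays (`L_BL`, `p_BL`, `sigma_BL`,
#'   `pi_BL`, `pi_ISF`), e.g. from the tissue tables.
#' @return array of volumetric transvascular flux (s^-1).
#' @export
starling_source <- function(p, phi, sv0, props) {
  props$L_BL * (phi * sv0) *
    (props$p_BL - p - props$sigma_BL * (props$pi_BL - props$pi_ISF))
}

#' Solve the quasi-steady interstitial fluid flow problem
#'
#' Finite-volume solve of `-div((kappa/mu) grad p) = F_BL(p) + q_in` with
#' harmonic-mean face permeabilities, the Starling exchange folded into the
#' diagonal (linear in p), a Dirichlet outer boundary, no-flux
#' exterior/catheter cells, and the infusion as a volumetric source in the
#' tip cell.  The SPD system is solved by Jacobi-preconditioned conjugate
#' gradients.
#'
#' @param tissue a `ced_tissue` (supplies the grid and baseline SV0).
#' @param phi vascular scaling field (scalar or array), default 1.
#' @param catheter optional `ced_catheter`; its shaft cells are blocked and
#'   `Q_in_m3s` enters at the tip cell.
#' @param Q_in_m3s infusion rate (m^3/s), nonnegative.
#' @param props optional per-cell property override (default:
#'   region-expanded [tissue_tables()]).
#' @param p_boundary Dirichlet boundary pressure (Pa): a scalar (default 0
#'   gauge) or a function `f(x_mm, y_mm, z_mm)` evaluated at boundary face
#'   centres (for imposing analytic solutions in verification runs).
#' @param tol relative residual tolerance of the linear solve.
#' @param maxit CG iteration cap.
#' @param p0 optional initial pressure guess (warm start).
#' @return a `ced_flow`: pressure `p` (Pa), oriented face volume fluxes
#'   `qx`, `qy`, `qz` (m^3/s), face velocities `vx`, `vy`, `vz` (m/s),
#'   transvascular source `F_BL` (s^-1), velocity magnitude `v_mag` at cell
#'   centres, and a `balance` report (boundary outflow, total transvascular
#'   gain, infusion, relative closure error, CG diagnostics).
#' @export
solve_flow <- function(tissue, phi = 1, catheter = NULL, Q_in_m3s = 0,
                       props = NULL, p_boundary = 0, tol = 1e-10,
                       maxit = 100000L, p0 = NULL) {
  grid <- tissue$grid
  n <- grid$n
  if (Q_in_m3s < 0) stop("infusion rate must be nonnegative")
  if (Q_in_m3s > 0 && is.null(catheter)) {
    stop("an infusion requires a catheter")
  }
  if (is.null(props)) props <- expand_tissue_properties(grid)
  if (length(phi) == 1) phi <- array(phi, dim = n)

  active <- grid$region != REGION_EXTERIOR
  if (!is.null(catheter)) active[catheter$blocked] <- FALSE
  if (!any(active)) stop("no active cells: cannot assemble the flow system")

  lam <- ifelse(active, props$kappa / props$mu, 0)
  fc <- assemble_faces(grid, lam, boundary = "dirichlet")
  if (!is.null(catheter)) fc <- block_faces(grid, fc, catheter$blocked)

  v_cell <- prod(grid$h_mm * 1e-3)
  b_star <- ifelse(active, props$L_BL * phi * tissue$sv0, 0)
  p_eff <- props$p_BL - props$sigma_BL * (props$pi_BL - props$pi_ISF)

  pb <- boundary_values(grid, p_boundary)
  d <- face_diag(grid, fc) + v_cell * b_star
  rhs <- v_cell * b_star * p_eff
  rhs[1, , ] <- rhs[1, , ] + fc$bnd$xlo * pb$xlo
  rhs[n[1], , ] <- rhs[n[1], , ] + fc$bnd$xhi * pb$xhi
  rhs[, 1, ] <- rhs[, 1, ] + fc$bnd$ylo * pb$ylo
  rhs[, n[2], ] <- rhs[, n[2], ] + fc$bnd$yhi * pb$yhi
  rhs[, , 1] <- rhs[, , 1] + fc$bnd$zlo * pb$zlo
  rhs[, , n[3]] <- rhs[, , n[3]] + fc$bnd$zhi * pb$zhi
  if (Q_in_m3s > 0) {
    rhs[catheter$tip_linear] <- rhs[catheter$tip_linear] + Q_in_m3s
  }
  # decouple inactive cells as identity rows
  d[!active] <- 1
  rhs[!active] <- 0
  if (all(d[active] <= 0)) {
    stop("singular flow system: no Dirichlet boundary or Starling exchange")
  }

  x0 <- if (is.null(p0)) numeric(prod(n)) else as.numeric(p0)
  sol <- cg_stencil_cpp(as.integer(n), fc$gx, fc$gy, fc$gz,
                        as.numeric(d), as.numeric(rhs),
                        x0, tol, as.integer(maxit))
  if (sol$relres > tol) {
    stop(sprintf("flow solve did not converge: relative residual %.3e after %d iterations",
                 sol$relres, sol$iter))
  }
  p <- array(sol$x, dim = n)

  fl <- face_fluxes(grid, fc, p, pb)
  F_BL <- starling_source(p, phi, tissue$sv0, props)
  F_BL[!active] <- 0

  outflow <- boundary_outflux(grid, fc, p, pb)
  src <- sum(F_BL) * v_cell + Q_in_m3s
  denom <- max(abs(src), abs(outflow), Q_in_m3s, 1e-30)
  structure(
    list(p = p, qx = fl$qx, qy = fl$qy, qz = fl$qz,
         vx = fl$qx / fc$area[1], vy = fl$qy / fc$area[2],
         vz = fl$qz / fc$area[3],
         v_mag = cell_speed(grid, fl),
         F_BL = F_BL, active = active,
         balance = list(boundary_outflow_m3s = outflow,
                        source_total_m3s = src,
                        Q_in_m3s = Q_in_m3s,
                        rel_error = abs(outflow - src) / denom,
                        cg_iter = sol$iter, cg_relres = sol$relres)),
    class = "ced_flow"
  )
}

# Dirichlet boundary pressures as six face-centre matrices.  p_boundary is a
# scalar or a function f(x_mm, y_mm, z_mm) evaluated at face centres (used
# to impose analytic solutions in verification runs).
boundary_values <- function(grid, p_boundary) {
  n <- grid$n
  if (is.numeric(p_boundary) && length(p_boundary) == 1) {
    return(list(
      xlo = matrix(p_boundary, n[2], n[3]), xhi = matrix(p_boundary, n[2], n[3]),
      ylo = matrix(p_boundary, n[1], n[3]), yhi = matrix(p_boundary, n[1], n[3]),
      zlo = matrix(p_boundary, n[1], n[2]), zhi = matrix(p_boundary, n[1], n[2])
    ))
  }
  stopifnot(is.function(p_boundary))
  o <- grid$origin_mm
  h <- grid$h_mm
  cx <- o[1] + (seq_len(n[1]) - 0.5) * h[1]
  cy <- o[2] + (seq_len(n[2]) - 0.5) * h[2]
  cz <- o[3] + (seq_len(n[3]) - 0.5) * h[3]
  lo <- o
  hi <- o + n * h
  list(
    xlo = outer(cy, cz, function(y, z) p_boundary(lo[1], y, z)),
    xhi = outer(cy, cz, function(y, z) p_boundary(hi[1], y, z)),
    ylo = outer(cx, cz, function(x, z) p_boundary(x, lo[2], z)),
    yhi = outer(cx, cz, function(x, z) p_boundary(x, hi[2], z)),
    zlo = outer(cx, cy, function(x, y) p_boundary(x, y, lo[3])),
    zhi = outer(cx, cy, function(x, y) p_boundary(x, y, hi[3]))
  )
}

# Oriented (+axis) face volume fluxes (m^3/s) from a pressure field.
face_fluxes <- function(grid, fc, p, pb) {
  n <- grid$n
  qx <- array(0, dim = dim(fc$gx))
  qx[2:n[1], , ] <- fc$gx[2:n[1], , ] *
    (p[1:(n[1] - 1), , , drop = FALSE] - p[2:n[1], , , drop = FALSE])
  qx[1, , ] <- fc$bnd$xlo * (pb$xlo - p[1, , ])
  qx[n[1] + 1, , ] <- fc$bnd$xhi * (p[n[1], , ] - pb$xhi)
  qy <- array(0, dim = dim(fc$gy))
  qy[, 2:n[2], ] <- fc$gy[, 2:n[2], ] *
    (p[, 1:(n[2] - 1), , drop = FALSE] - p[, 2:n[2], , drop = FALSE])
  qy[, 1, ] <- fc$bnd$ylo * (pb$ylo - p[, 1, ])
  qy[, n[2] + 1, ] <- fc$bnd$yhi * (p[, n[2], ] - pb$yhi)
  qz <- array(0, dim = dim(fc$gz))
  qz[, , 2:n[3]] <- fc$gz[, , 2:n[3]] *
    (p[, , 1:(n[3] - 1), drop = FALSE] - p[, , 2:n[3], drop = FALSE])
  qz[, , 1] <- fc$bnd$zlo * (pb$zlo - p[, , 1])
  qz[, , n[3] + 1] <- fc$bnd$zhi * (p[, , n[3]] - pb$zhi)
  list(qx = qx, qy = qy, qz = qz)
}

boundary_outflux <- function(grid, fc, p, pb) {
  n <- grid$n
  sum(fc$bnd$xlo * (p[1, , ] - pb$xlo)) +
    sum(fc$bnd$xhi * (p[n[1], , ] - pb$xhi)) +
    sum(fc$bnd$ylo * (p[, 1, ] - pb$ylo)) +
    sum(fc$bnd$yhi * (p[, n[2], ] - pb$yhi)) +
    sum(fc$bnd$zlo * (p[, , 1] - pb$zlo)) +
    sum(fc$bnd$zhi * (p[, , n[3]] - pb$zhi))
}

# Cell-centred superficial speed from face fluxes (average of face pairs).
cell_speed <- function(grid, fl) {
  n <- grid$n
  h <- grid$h_mm * 1e-3
  area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])
  vx <- (fl$qx[1:n[1], , ] + fl$qx[2:(n[1] + 1), , ]) / (2 * area[1])
  vy <- (fl$qy[, 1:n[2], ] + fl$qy[, 2:(n[2] + 1), ]) / (2 * area[2])
  vz <- (fl$qz[, , 1:n[3]] + fl$qz[, , 2:(n[3] + 1)]) / (2 * area[3])
  sqrt(vx^2 + vy^2 + vz^2)
}

#' @export
print.ced_flow <- function(x, ...) {
  cat(sprintf(
    "<ced_flow> p: %.4g .. %.4g Pa | balance error %.2e (CG %d it, res %.1e)\n",
    min(x$p[x$active]), max(x$p[x$active]),
    x$balance$rel_error, x$balance$cg_iter, x$balance$cg_relres
  ))
  invisible(x)
}
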