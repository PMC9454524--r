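# Coupled drug transport: liposome-encapsulated cytotoxic drug, released
# free drug (with protein binding and cell partitioning at equilibrium),
# antiangiogenic drug, and the vascular scaling field phi.
#
# Conserved variables per cell: u_lp = epsECS*C_LP, u_aa = epsECS*C_AA, and
# for the free drug w = omega*C_FD (total free+bound drug per tissue volume).
# Each time step is operator-split into (i) an exact per-cell linear reaction
# update, (ii) explicit first-order upwind convection on the face volume
# fluxes (CFL sub-cycled), and (iii) an implicit diffusion solve.  The
# convective terms -v.grad(eps C) - F_BL eps C of the governing equations
# are identically the conservative divergence -div(eps C v) because the face
# velocities satisfy the discrete continuity equation div v = F_BL + q_in.

#' Infusion regimen specification
#'
#' @param regimen one of `"plainTMZ"`, `"plainTMZ+BEV"`, `"liposomalTMZ"`,
#'   `"liposomalTMZ+BEV"`.  Plain regimens hold the free cytotoxic drug at
#'   `C_tmz_M` in the infusion cell; liposomal regimens hold the liposome
#'   carrier there instead; `+BEV` regimens co-infuse the antiangiogenic
#'   drug at `C_bev_M`.
#' @param R_in_ul_min infusion rate (uL/min, in (0, 10]).
#' @param T_in_days infusion duration (days).
#' @param C_tmz_M,C_bev_M infused concentrations (M).
#' @param site optional integer length-3 infusion-site cell index; default
#'   is the maximum-epsBL tumor cell (densest microvasculature).
#' @return a `ced_regimen`.
#' @export
regimen_spec <- function(regimen = c("liposomalTMZ+BEV", "plainTMZ",
                                     "plainTMZ+BEV", "liposomalTMZ"),
                         R_in_ul_min = 3.0, T_in_days = 3.0,
                         C_tmz_M = 5.15e-3, C_bev_M = 7.26e-5,
                         site = NULL) {
  regimen <- match.arg(regimen)
  if (R_in_ul_min <= 0 || R_in_ul_min > 10) {
    stop("infusion rate must lie in (0, 10] uL/min")
  }
  if (C_tmz_M < 0 || C_bev_M < 0) stop("concentrations must be nonnegative")
  has_bev <- grepl("BEV", regimen, fixed = TRUE)
  lipo <- grepl("liposomal", regimen, fixed = TRUE)
  structure(
    list(regimen = regimen,
         R_in_ul_min = R_in_ul_min,
         Q_in_m3s = R_in_ul_min * 1e-9 / 60,
         T_in_s = T_in_days * 86400,
         C_in = list(lp = if (lipo) C_tmz_M else 0,
                     fd = if (lipo) 0 else C_tmz_M,
                     aa = if (has_bev) C_bev_M else 0),
         site = site),
    class = "ced_regimen"
  )
}

#' Effective free-drug capacity factor omega
#'
#' `omega = epsECS (1 + K_BC) + epsICS H_IE (1 + K_BC) + epsCM H_CE`, the
#' per-cell factor relating the extracellular free-drug concentration to the
#' total free + protein-bound drug stored per unit tissue volume under
#' equilibrium binding and partitioning.
#'
#' @param eps list of volume-fraction arrays (`ecs`, `ics`, `cm`).
#' @param K_BC protein binding constant.
#' @param H_IE intracellular/extracellular partition coefficient.
#' @param H_CE membrane/extracellular partition coefficient.
#' @return array of omega values.
#' @export
omega_field <- function(eps, K_BC, H_IE, H_CE) {
  eps$ecs * (1 + K_BC) + eps$ics * H_IE * (1 + K_BC) + eps$cm * H_CE
}

#' Update tissue volume fractions for a vascular scaling field
#'
#' Antiangiogenesis shrinks vessel radii, so the plasma fraction scales as
#' `epsBL = phi^2 epsBL0`; the cell membrane and intracellular fractions are
#' constants and the extracellular fraction absorbs the released volume via
#' the closure `epsECS = 1 - epsBL - epsCM - epsICS`.
#'
#' @param phi vascular scaling field in `[0, 1]`.
#' @param tissue a `ced_tissue` carrying the baseline fractions.
#' @return list of arrays `bl`, `ecs`, `cm`, `ics`.
#' @export
update_fractions <- function(phi, tissue) {
  if (any(phi < -1e-12) || any(phi > 1 + 1e-12)) {
    stop("phi must lie in [0, 1]")
  }
  bl <- phi^2 * tissue$eps_bl0
  ecs_base <- 1 - tissue$eps_bl0 - tissue$eps_cm - tissue$eps_ics
  ecs <- ecs_base + (tissue$eps_bl0 - bl)
  interior <- tissue$grid$region != REGION_EXTERIOR
  if (any(ecs[interior] < -1e-12)) stop("update produced negative epsECS")
  ecs[!interior] <- 0
  list(bl = bl, ecs = ecs, cm = tissue$eps_cm, ics = tissue$eps_ics)
}

#' Advance the vascular scaling field over one time step
#'
#' Integrates the per-cell vascular kinetics
#' `dphi/dt = phi (alpha + beta phi + gamma phi^2) - k_a phi C_AA`
#' with a classical fourth-order Runge-Kutta step (the rates involved are
#' at most ~1e-4 s^-1, so a single RK4 step at the transport time step is
#' accurate to well below 1e-6 relative), then clamps to `[0, 1]`.  With the
#' baseline coefficients `alpha + beta + gamma = 0`, so `phi = 1` is exactly
#' stationary in the absence of antiangiogenic drug.
#'
#' @param phi current scaling field.
#' @param C_AA antiangiogenic drug concentration field (M), held constant
#'   over the step.
#' @param dt_s time step (s).
#' @param k_a antiangiogenic rate (M^-1 s^-1).
#' @param alpha,beta,gamma natural angiogenesis coefficients (s^-1),
#'   scalars or per-cell arrays.
#' @return updated phi field.
#' @export
step_phi <- function(phi, C_AA, dt_s, k_a = drug_library()$bev$k_a,
                     alpha = tissue_tables()$tumor$alpha,
                     beta = tissue_tables()$tumor$beta,
                     gamma = tissue_tables()$tumor$gamma) {
  if (dt_s <= 0) stop("dt must be positive")
  f <- function(x) x * (alpha + beta * x + gamma * x^2) - k_a * x * C_AA
  k1 <- f(phi)
  k2 <- f(phi + 0.5 * dt_s * k1)
  k3 <- f(phi + 0.5 * dt_s * k2)
  k4 <- f(phi + dt_s * k3)
  pmin(pmax(phi + dt_s / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0), 1)
}

#' Initialize a transport state
#'
#' @param tissue a `ced_tissue`.
#' @param C_LP,C_FD,C_AA initial extracellular concentrations (M), scalars
#'   or arrays; default zero everywhere.
#' @param phi initial vascular scaling (default 1).
#' @param drug drug parameter list ([drug_library()]).
#' @return a `ced_state` with conserved fields `u_lp`, `w_fd`, `u_aa`,
#'   the scaling field `phi`, current fractions `eps`, `omega`, and time.
#' @export
transport_state <- function(tissue, C_LP = 0, C_FD = 0, C_AA = 0, phi = 1,
                            drug = drug_library()) {
  n <- tissue$grid$n
  as_field <- function(x) if (length(x) == 1) array(x, dim = n) else x
  phi <- as_field(phi)
  eps <- update_fractions(phi, tissue)
  omega <- omega_field(eps, drug$tmz$K_BC, drug$tmz$H_IE, drug$tmz$H_CE)
  structure(
    list(u_lp = as_field(C_LP) * eps$ecs,
         w_fd = as_field(C_FD) * omega,
         u_aa = as_field(C_AA) * eps$ecs,
         phi = phi, eps = eps, omega = omega, t_s = 0),
    class = "ced_state"
  )
}

#' Extract concentration fields from a transport state
#'
#' @param state a `ced_state`.
#' @return list of extracellular concentration arrays `C_LP`, `C_FD`,
#'   `C_AA` (M); zero where the extracellular fraction vanishes.
#' @export
concentrations <- function(state) {
  safe_div <- function(a, b) (b > 0) * a / (b + (b <= 0))
  list(C_LP = safe_div(state$u_lp, state$eps$ecs),
       C_FD = safe_div(state$w_fd, state$omega),
       C_AA = safe_div(state$u_aa, state$eps$ecs))
}

#' Numerical options for the transport simulation
#'
#' @param dt_s transport time step (s).
#' @param couple_dphi flow re-solve threshold on `max |delta phi|` since the
#'   last solve.
#' @param snapshot_every_s cadence of stored field snapshots (s).
#' @param cfl Courant safety factor for the explicit convection sub-steps.
#' @param cg_tol relative tolerance of the implicit diffusion solves.
#' @param flow_tol relative tolerance of the flow solves.
#' @return named list of options.
#' @export
numerics_opts <- function(dt_s = 60, couple_dphi = 0.01,
                          snapshot_every_s = 21600, cfl = 0.5,
                          cg_tol = 1e-8, flow_tol = 1e-8) {
  list(dt_s = dt_s, couple_dphi = couple_dphi,
       snapshot_every_s = snapshot_every_s, cfl = cfl, cg_tol = cg_tol,
       flow_tol = flow_tol)
}

# Assembled, step-invariant transport machinery: diffusion face conductances
# per species (with saved Dirichlet-cell face copies for flux bookkeeping),
# per-cell region drug properties, Dirichlet cell set and target
# concentrations, active mask and cell volume.
transport_context <- function(tissue, drug = drug_library(),
                              catheter = NULL, dirichlet_cells = NULL,
                              C_in = list(lp = 0, fd = 0, aa = 0),
                              numerics = numerics_opts()) {
  grid <- tissue$grid
  active <- grid$region != REGION_EXTERIOR
  if (!is.null(catheter)) active[catheter$blocked] <- FALSE
  if (is.null(dirichlet_cells) && !is.null(catheter)) {
    dirichlet_cells <- catheter$tip_linear
  }
  dir_cells <- as.integer(dirichlet_cells)

  spec_D <- list(
    lp = region_field(grid, drug$lip$D_t, drug$lip$D_n),
    fd = region_field(grid, drug$tmz$D_t, drug$tmz$D_n),
    aa = region_field(grid, drug$bev$D_t, drug$bev$D_n)
  )
  faces <- lapply(spec_D, function(D) {
    D[!active] <- 0
    fc <- assemble_faces(grid, D, boundary = "neumann")
    if (!is.null(catheter)) fc <- block_faces(grid, fc, catheter$blocked)
    d0 <- face_diag(grid, fc)
    # save Dirichlet-cell faces for flux accounting, then decouple them
    tipfaces <- NULL
    if (length(dir_cells)) {
      tipfaces <- fc
      fc <- block_faces(grid, fc, dir_cells)
    }
    list(fc = fc, d0 = d0, full = tipfaces)
  })

  act <- array(0, dim = grid$n)
  act[active] <- 1
  p_tv <- list(
    lp = act * region_field(grid, drug$lip$P_TV_t, drug$lip$P_TV_n),
    fd = act * region_field(grid, drug$tmz$P_TV_t, drug$tmz$P_TV_n)
  )

  list(grid = grid, active = active, act = act,
       v_cell = prod(grid$h_mm * 1e-3),
       drug = drug, faces = faces, p_tv = p_tv,
       dirichlet = dir_cells, C_in = C_in, numerics = numerics)
}

# Neighbour linear offsets and face conductances of one cell (for Dirichlet
# elimination and tip-flux bookkeeping).
cell_faces <- function(grid, fc, lin) {
  n <- grid$n
  ijk <- linear_to_ijk(grid, lin)
  i <- ijk[1, 1]; j <- ijk[1, 2]; k <- ijk[1, 3]
  out <- list()
  add <- function(out, g, nb) {
    if (g > 0) out[[length(out) + 1]] <- c(g = g, nb = nb)
    out
  }
  if (i > 1) out <- add(out, fc$gx[i, j, k], lin - 1L)
  if (i < n[1]) out <- add(out, fc$gx[i + 1, j, k], lin + 1L)
  if (j > 1) out <- add(out, fc$gy[i, j, k], lin - n[1])
  if (j < n[2]) out <- add(out, fc$gy[i, j + 1, k], lin + n[1])
  if (k > 1) out <- add(out, fc$gz[i, j, k], lin - n[1] * n[2])
  if (k < n[3]) out <- add(out, fc$gz[i, j, k + 1], lin + n[1] * n[2])
  out
}

# Exact per-cell linear reaction update over dt, returning new fields and
# the time integrals needed for the mass budget (amount-seconds per volume).
react_exact <- function(u_lp, w_fd, u_aa, k_lp, a_fd, k_rel_u, k_aa, dt) {
  # f(k) = (1 - e^{-k dt}) / k, stable down to k = 0 via expm1 with a tiny
  # positive clamp (the limit dt is recovered exactly)
  fint <- function(k) -expm1(-k * dt) / pmax(k, 1e-300)
  e_lp <- exp(-k_lp * dt)
  e_a <- exp(-a_fd * dt)
  dk <- a_fd - k_lp
  near <- which(abs(dk) < 1e-13)
  dk_safe <- dk
  if (length(near)) dk_safe[near] <- 1
  gap <- (e_lp - e_a) / dk_safe
  gap2 <- (fint(k_lp) - fint(a_fd)) / dk_safe
  if (length(near)) {
    em <- exp(-0.5 * (a_fd[near] + k_lp[near]) * dt)
    gap[near] <- dt * em
    gap2[near] <- 0.5 * dt^2 * em
  }

  # released free drug enters the conserved variable w directly
  src <- k_rel_u * u_lp
  list(
    u_lp = u_lp * e_lp,
    w_fd = w_fd * e_a + src * gap,
    u_aa = u_aa * exp(-k_aa * dt),
    int_lp = u_lp * fint(k_lp),                      # \int u_lp dt
    int_w = w_fd * fint(a_fd) + src * gap2,          # \int w dt
    int_aa = u_aa * fint(k_aa)                       # \int u_aa dt
  )
}

#' Advance the coupled drug fields over one time step
#'
#' One operator-split step of the three transport equations at fixed phi and
#' fractions: exact per-cell reaction update (release, blood drainage,
#' elimination), CFL-sub-cycled explicit upwind convection on the face
#' volume fluxes of `flow`, and an implicit diffusion solve per species.
#' Infused species are held at their infusion concentration in the Dirichlet
#' (tip) cells throughout.
#'
#' @param state a `ced_state` (fractions must be current for `state$phi`).
#' @param flow a `ced_flow` consistent with `state$phi`.
#' @param tissue a `ced_tissue`.
#' @param dt_s time step (s).
#' @param ctx a transport context (created internally by
#'   [simulate_regimen()]); required.
#' @param infusing logical: hold Dirichlet values (TRUE during the infusion).
#' @return list with the updated `state` and a `budget` of per-group mass
#'   increments (mol): infused, eliminated, drained-to-blood, boundary
#'   outflow for the cytotoxic group (`tmz`: liposomal + free) and the
#'   antiangiogenic group (`aa`).
#' @export
advance_drugs <- function(state, flow, tissue, dt_s, ctx, infusing = TRUE,
                          outrate = NULL) {
  if (dt_s <= 0) stop("dt must be positive")
  grid <- ctx$grid
  n <- grid$n
  V <- ctx$v_cell
  drug <- ctx$drug
  eps <- state$eps
  omega <- state$omega
  active <- ctx$active
  act <- ctx$act
  # omega / epsECS where active (both zero on excluded cells)
  m_fd <- act * (omega / pmax(eps$ecs, 1e-12)) + (1 - act)

  dir <- if (infusing) ctx$dirichlet else integer(0)
  u_lp_t <- eps$ecs[dir] * ctx$C_in$lp
  w_fd_t <- omega[dir] * ctx$C_in$fd
  u_aa_t <- eps$ecs[dir] * ctx$C_in$aa

  budget <- list(tmz = c(infused = 0, eliminated = 0, drained = 0,
                         outflow = 0),
                 aa = c(infused = 0, eliminated = 0, drained = 0,
                        outflow = 0))

  u_lp <- state$u_lp; w_fd <- state$w_fd; u_aa <- state$u_aa
  if (length(dir)) {
    budget$tmz["infused"] <- budget$tmz["infused"] +
      sum(u_lp_t - u_lp[dir]) * V + sum(w_fd_t - w_fd[dir]) * V
    budget$aa["infused"] <- budget$aa["infused"] +
      sum(u_aa_t - u_aa[dir]) * V
    u_lp[dir] <- u_lp_t; w_fd[dir] <- w_fd_t; u_aa[dir] <- u_aa_t
  }

  # --- exact reaction update ------------------------------------------------
  sv <- state$phi * tissue$sv0
  k_lp <- act * drug$lip$k_rel + ctx$p_tv$lp * sv
  drain_fd <- eps$ecs * ctx$p_tv$fd * sv
  s_fd <- drain_fd + act * (eps$ecs + eps$ics * drug$tmz$H_IE) * drug$tmz$k_e
  a_fd <- s_fd / (omega + (omega <= 0))
  k_aa <- act * drug$bev$k_e

  rx <- react_exact(u_lp, w_fd, u_aa, k_lp, a_fd, drug$lip$k_rel, k_aa, dt_s)
  drained_lp <- sum(ctx$p_tv$lp * sv * rx$int_lp) * V
  frac_drain <- drain_fd / (s_fd + (s_fd <= 0))
  sink_fd <- a_fd * rx$int_w
  budget$tmz["drained"] <- drained_lp + sum(frac_drain * sink_fd) * V
  budget$tmz["eliminated"] <- sum((1 - frac_drain) * sink_fd) * V
  budget$aa["eliminated"] <- sum(k_aa * rx$int_aa) * V
  u_lp <- rx$u_lp; w_fd <- rx$w_fd; u_aa <- rx$u_aa
  if (length(dir)) {
    budget$tmz["infused"] <- budget$tmz["infused"] +
      sum(u_lp_t - u_lp[dir]) * V + sum(w_fd_t - w_fd[dir]) * V
    budget$aa["infused"] <- budget$aa["infused"] +
      sum(u_aa_t - u_aa[dir]) * V
    u_lp[dir] <- u_lp_t; w_fd[dir] <- w_fd_t; u_aa[dir] <- u_aa_t
  }

  # --- explicit upwind convection (sub-cycled) ------------------------------
  if (is.null(outrate)) outrate <- max_outflux_rate(grid, flow) / V
  nsub <- max(1L, ceiling(dt_s * outrate / ctx$numerics$cfl))
  dt_c <- dt_s / nsub
  dims <- as.integer(n)
  for (s in seq_len(nsub)) {
    dv_lp <- upwind_div_cpp(dims, as.numeric(u_lp), flow$qx, flow$qy, flow$qz)
    u_fd <- w_fd / m_fd
    dv_fd <- upwind_div_cpp(dims, as.numeric(u_fd), flow$qx, flow$qy, flow$qz)
    dv_aa <- upwind_div_cpp(dims, as.numeric(u_aa), flow$qx, flow$qy, flow$qz)
    if (length(dir)) {
      budget$tmz["infused"] <- budget$tmz["infused"] +
        sum(dv_lp$out[dir] + dv_fd$out[dir]) * dt_c
      budget$aa["infused"] <- budget$aa["infused"] + sum(dv_aa$out[dir]) * dt_c
    }
    u_lp <- u_lp - dt_c / V * array(dv_lp$out, dim = n)
    w_fd <- w_fd - dt_c / V * array(dv_fd$out, dim = n)
    u_aa <- u_aa - dt_c / V * array(dv_aa$out, dim = n)
    budget$tmz["outflow"] <- budget$tmz["outflow"] +
      (dv_lp$boundary_out + dv_fd$boundary_out) * dt_c
    budget$aa["outflow"] <- budget$aa["outflow"] + dv_aa$boundary_out * dt_c
    if (length(dir)) {
      u_lp[dir] <- u_lp_t; w_fd[dir] <- w_fd_t; u_aa[dir] <- u_aa_t
    }
  }

  # --- implicit diffusion ---------------------------------------------------
  diff_step <- function(u, species, mass) {
    f <- ctx$faces[[species]]
    dm <- V * mass / dt_s
    d <- dm + f$d0
    rhs <- dm * u
    target <- switch(species, lp = u_lp_t, fd = w_fd_t / m_fd[dir],
                     aa = u_aa_t)
    if (length(dir)) {
      for (ii in seq_along(dir)) {
        for (fcs in cell_faces(grid, f$full, dir[ii])) {
          rhs[fcs["nb"]] <- rhs[fcs["nb"]] + fcs["g"] * target[ii]
        }
      }
      # identity rows scaled to the physical storage diagonal so the CG
      # residual norm weighs all equations homogeneously
      d[dir] <- dm[dir]
      rhs[dir] <- dm[dir] * target
    }
    d[!active] <- dm[!active]
    rhs[!active] <- 0
    sol <- cg_stencil_cpp(dims, f$fc$gx, f$fc$gy, f$fc$gz,
                          as.numeric(d), as.numeric(rhs),
                          as.numeric(u), ctx$numerics$cg_tol, 10000L)
    u1 <- array(sol$x, dim = n)
    tipflux <- 0
    if (length(dir)) {
      for (ii in seq_along(dir)) {
        for (fcs in cell_faces(grid, f$full, dir[ii])) {
          tipflux <- tipflux + fcs["g"] * (target[ii] - u1[fcs["nb"]])
        }
      }
    }
    list(u = u1, tipflux = unname(tipflux))
  }
  ones <- array(1, dim = n)
  st_lp <- diff_step(u_lp, "lp", ones)
  st_fd <- diff_step(w_fd / m_fd, "fd", m_fd)
  st_aa <- diff_step(u_aa, "aa", ones)
  u_lp <- st_lp$u
  w_fd <- st_fd$u * m_fd
  u_aa <- st_aa$u
  budget$tmz["infused"] <- budget$tmz["infused"] +
    (st_lp$tipflux + st_fd$tipflux) * dt_s
  budget$aa["infused"] <- budget$aa["infused"] + st_aa$tipflux * dt_s

  # --- nonnegativity guard --------------------------------------------------
  clipneg <- function(u, label) {
    mn <- min(u)
    if (mn < -1e-12 * max(max(u), 1e-300)) {
      stop(sprintf("negative %s concentration beyond tolerance: %.3e",
                   label, mn))
    }
    pmax(u, 0)
  }
  state$u_lp <- clipneg(u_lp, "liposome")
  state$w_fd <- clipneg(w_fd, "free-drug")
  state$u_aa <- clipneg(u_aa, "antiangiogenic")
  state$t_s <- state$t_s + dt_s
  list(state = state, budget = budget)
}

# Largest per-cell outgoing volume flux (m^3/s) for the CFL estimate.
max_outflux_rate <- function(grid, flow) {
  n <- grid$n
  out <- array(0, dim = n)
  out <- out + pmax(flow$qx[2:(n[1] + 1), , ], 0) - pmin(flow$qx[1:n[1], , ], 0)
  out <- out + pmax(flow$qy[, 2:(n[2] + 1), ], 0) - pmin(flow$qy[, 1:n[2], ], 0)
  out <- out + pmax(flow$qz[, , 2:(n[3] + 1)], 0) - pmin(flow$qz[, , 1:n[3]], 0)
  max(out)
}

#' Total stored drug mass per group (mol)
#'
#' @param state a `ced_state`.
#' @param v_cell_m3 cell volume (m^3).
#' @return named vector: `tmz` (liposomal + free including bound/cellular
#'   compartments) and `aa`.
#' @export
stored_mass <- function(state, v_cell_m3) {
  c(tmz = (sum(state$u_lp) + sum(state$w_fd)) * v_cell_m3 * 1e3,
    aa = sum(state$u_aa) * v_cell_m3 * 1e3)
}

#' Simulate a full infusion regimen
#'
#' Runs the coupled model: (i) pre-infusion steady flow solve at `phi = 1`;
#' (ii) transient loop over the infusion duration in which the vascular
#' scaling field is advanced, tissue fractions updated, the flow re-solved
#' whenever `max |delta phi|` since the last solve exceeds the coupling
#' threshold, and the drug fields advanced.  Initial concentrations are zero
#' everywhere.
#'
#' @param tissue a `ced_tissue`.
#' @param regimen a `ced_regimen`.
#' @param numerics a [numerics_opts()] list.
#' @param drug drug parameter list.
#' @param catheter optional `ced_catheter`; by default one is placed along
#'   the z axis with its tip at the regimen site (or the maximum-epsBL tumor
#'   cell).
#' @return a `ced_trajectory`: per-step `series` data frame (time, tumor
#'   ECS-volume-averaged free-drug and antiangiogenic concentrations, mean
#'   tumor phi and epsBL, total transvascular fluid gain), snapshot list,
#'   final `state` and `flow`, the pre-infusion `flow0`, the accumulated
#'   mass `budget` with its closure check, and the inputs.
#' @export
simulate_regimen <- function(tissue, regimen, numerics = numerics_opts(),
                             drug = drug_library(), catheter = NULL) {
  grid <- tissue$grid
  tumor <- grid$region == REGION_TUMOR
  if (is.null(catheter)) {
    site <- regimen$site
    if (is.null(site)) {
      cand <- which(tumor)
      site <- linear_to_ijk(grid, cand[which.max(tissue$eps_bl0[cand])])[1, ]
    }
    catheter <- catheter_spec(grid, site, track_axis = "z")
  }
  ctx <- transport_context(tissue, drug, catheter, C_in = regimen$C_in,
                           numerics = numerics)
  props <- expand_tissue_properties(grid)

  flow0 <- solve_flow(tissue, phi = 1, catheter = catheter, Q_in_m3s = 0,
                      props = props, tol = numerics$flow_tol)
  if (regimen$T_in_s <= 0) {
    return(structure(list(series = NULL, snapshots = list(),
                          state = transport_state(tissue, drug = drug),
                          flow = flow0, flow0 = flow0, budget = NULL,
                          tissue = tissue, regimen = regimen,
                          catheter = catheter, numerics = numerics),
                     class = "ced_trajectory"))
  }

  state <- transport_state(tissue, drug = drug)
  flow <- solve_flow(tissue, phi = state$phi, catheter = catheter,
                     Q_in_m3s = regimen$Q_in_m3s, props = props,
                     tol = numerics$flow_tol)
  phi_ref <- state$phi
  outrate <- max_outflux_rate(grid, flow) / prod(grid$h_mm * 1e-3)

  nstep <- ceiling(regimen$T_in_s / numerics$dt_s)
  budget <- list(tmz = c(infused = 0, eliminated = 0, drained = 0,
                         outflow = 0),
                 aa = c(infused = 0, eliminated = 0, drained = 0,
                        outflow = 0))
  tumor_idx <- which(tumor)
  v_ecs_w <- function(C) {
    w <- state$eps$ecs[tumor_idx]
    sum(C[tumor_idx] * w) / sum(w)
  }
  series <- matrix(NA_real_, nrow = nstep, ncol = 7,
                   dimnames = list(NULL, c("t_s", "cfd_avg_M", "clp_avg_M",
                                           "caa_avg_M", "phi_mean",
                                           "eps_bl_mean", "fbl_total_s")))
  snapshots <- list()
  next_snap <- numerics$snapshot_every_s

  for (it in seq_len(nstep)) {
    dt <- min(numerics$dt_s, regimen$T_in_s - state$t_s)
    ecs_pos <- state$eps$ecs > 0
    c_aa <- ecs_pos * state$u_aa / (state$eps$ecs + !ecs_pos)
    state$phi <- step_phi(state$phi, c_aa, dt, k_a = drug$bev$k_a,
                          alpha = props$alpha, beta = props$beta,
                          gamma = props$gamma)
    state$eps <- update_fractions(state$phi, tissue)
    omega_new <- omega_field(state$eps, drug$tmz$K_BC, drug$tmz$H_IE,
                             drug$tmz$H_CE)
    state$omega <- omega_new

    if (max(abs(state$phi - phi_ref)) > numerics$couple_dphi) {
      flow <- solve_flow(tissue, phi = state$phi, catheter = catheter,
                         Q_in_m3s = regimen$Q_in_m3s, props = props,
                         tol = numerics$flow_tol, p0 = flow$p)
      phi_ref <- state$phi
      outrate <- max_outflux_rate(grid, flow) / ctx$v_cell
    }

    stepped <- advance_drugs(state, flow, tissue, dt, ctx, infusing = TRUE,
                             outrate = outrate)
    state <- stepped$state
    for (g in names(budget)) budget[[g]] <- budget[[g]] + stepped$budget[[g]]

    conc <- concentrations(state)
    series[it, ] <- c(state$t_s, v_ecs_w(conc$C_FD), v_ecs_w(conc$C_LP),
                      v_ecs_w(conc$C_AA), mean(state$phi[tumor_idx]),
                      mean(state$eps$bl[tumor_idx]),
                      sum(flow$F_BL[tumor_idx]) * ctx$v_cell)
    if (state$t_s >= next_snap - 1e-6 || it == nstep) {
      snapshots[[length(snapshots) + 1]] <-
        list(t_s = state$t_s, C = conc, phi = state$phi, eps = state$eps)
      next_snap <- next_snap + numerics$snapshot_every_s
    }
  }

  # budget increments and stored mass both carried in M * m^3; the closure
  # check is unit-invariant and the report converts to mol (x 1000 L/m^3)
  stored_raw <- c(tmz = (sum(state$u_lp) + sum(state$w_fd)) * ctx$v_cell,
                  aa = sum(state$u_aa) * ctx$v_cell)
  closure <- vapply(names(budget), function(g) {
    b <- budget[[g]]
    inf <- b[["infused"]]
    if (inf <= 0) return(0)
    abs(stored_raw[[g]] + b[["eliminated"]] + b[["drained"]] +
          b[["outflow"]] - inf) / inf
  }, numeric(1))
  budget <- lapply(budget, function(b) b * 1e3)
  stored <- stored_mass(state, ctx$v_cell)

  structure(
    list(series = as.data.frame(series), snapshots = snapshots,
         state = state, flow = flow, flow0 = flow0,
         budget = list(groups = budget, stored_mol = stored,
                       closure_rel = closure),
         tissue = tissue, regimen = regimen, catheter = catheter,
         numerics = numerics),
    class = "ced_trajectory"
  )
}

#' @export
print.ced_trajectory <- function(x, ...) {
  cat(sprintf("<ced_trajectory> regimen %s", x$regimen$regimen))
  if (!is.null(x$series)) {
    last <- x$series[nrow(x$series), ]
    cat(sprintf(
      ": t = %.3g d | tumor-avg C_FD = %.3g M | mean phi = %.3f",
      last$t_s / 86400, last$cfd_avg_M, last$phi_mean
    ))
  }
  cat("\n")
  invisible(x)
}
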