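# Delivery-outcome metrics evaluated on simulation snapshots.  All four are
# defined over a cell mask (the tumor by default): the ECS-volume-weighted
# spatial average, distance courses around the infusion site, the
# distribution non-uniformity index, and the effective distribution volume.

#' ECS-volume-weighted spatial average concentration
#'
#' `C_avg = sum_i C_i V_ECS,i / sum_i V_ECS,i` with
#' `V_ECS,i = epsECS,i V_T,i`; on a uniform grid the cell volume cancels.
#'
#' @param C concentration field.
#' @param eps_ecs extracellular volume fraction field.
#' @param mask logical array of cells to include (non-empty).
#' @return the weighted mean (same units as `C`).
#' @export
spatial_avg <- function(C, eps_ecs, mask) {
  if (!any(mask)) stop("empty mask")
  w <- eps_ecs[mask]
  if (sum(w) <= 0) stop("mask has zero ECS volume")
  sum(C[mask] * w) / sum(w)
}

#' Distance course of a field around the infusion site
#'
#' Volume-weighted mean of a field over spherical shells
#' `[d, d + bin_mm)` of distance from the infusion site.  On a uniform grid
#' the tissue volumes cancel, leaving the plain mean per shell.  Shells with
#' no cells are reported as `NA`, not zero.
#'
#' @param field field of interest.
#' @param distances distance field (mm), e.g. from [distance_map()].
#' @param mask logical array of cells to include.
#' @param bin_mm shell width (mm); defaults to the reference in-plane cell
#'   size 0.9 mm.
#' @return data frame with shell centre `distance_mm`, `value`, and cell
#'   count `n`.
#' @export
distance_course <- function(field, distances, mask, bin_mm = 0.9) {
  if (bin_mm <= 0) stop("bin width must be positive")
  if (!any(mask)) stop("empty mask")
  d <- distances[mask]
  v <- field[mask]
  shell <- floor(d / bin_mm)
  edges <- seq(0, max(shell))
  value <- vapply(edges, function(s) {
    sel <- shell == s
    if (!any(sel)) NA_real_ else mean(v[sel])
  }, numeric(1))
  n <- vapply(edges, function(s) sum(shell == s), integer(1))
  data.frame(distance_mm = (edges + 0.5) * bin_mm, value = value, n = n)
}

#' Distribution non-uniformity index
#'
#' `NUN = sum_i |C_i - C_avg| V_ECS,i / (C_avg sum_i V_ECS,i)`: the
#' ECS-volume-weighted mean absolute deviation divided by the mean.  Zero
#' iff the field is constant on the mask; invariant under uniform scaling.
#'
#' @inheritParams spatial_avg
#' @return dimensionless non-uniformity.
#' @export
nun <- function(C, eps_ecs, mask) {
  avg <- spatial_avg(C, eps_ecs, mask)
  if (avg <= 0) stop("NUN undefined for zero mean concentration")
  w <- eps_ecs[mask]
  sum(abs(C[mask] - avg) * w) / (avg * sum(w))
}

#' Effective distribution volume
#'
#' Total tissue volume of masked cells whose free-drug concentration reaches
#' the LD90 threshold (inclusive), `V_eff = sum V_T,i where C_i >= LD90`.
#'
#' @param C free-drug concentration field (M).
#' @param grid a `ced_grid` (supplies the cell volume).
#' @param mask logical array of cells to include.
#' @param ld90_M threshold concentration (M), positive; default the
#'   cytotoxic drug's LD90.
#' @return volume (mm^3).
#' @export
effective_volume <- function(C, grid, mask, ld90_M = drug_library()$tmz$LD90) {
  if (ld90_M <= 0) stop("LD90 must be positive")
  sum(C[mask] >= ld90_M) * grid$v_cell_mm3
}
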