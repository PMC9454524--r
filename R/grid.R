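#' Build a uniform structured voxel grid
#'
#' Discretizes a rectangular physical domain into uniform cells.  The per-axis
#' cell count is the nearest integer to `extent / cell` with halves rounding
#' up, which reproduces the reference 82,944-element mesh when a
#' 58 x 97 x 72 mm volume is meshed with 0.9 x 0.9 x 6.0 mm cells.
#'
#' @param extent_mm numeric length-3, physical extents of the box (mm).
#' @param cell_mm numeric length-3, cell sizes (mm).
#' @param region optional region labels: an integer array of the resulting
#'   dimensions with values 0 (exterior), 1 (tumor), 2 (normal), or a function
#'   `f(x, y, z)` of cell-centre coordinate arrays (mm) returning such labels.
#'   Default labels every cell as normal tissue.
#' @return A `ced_grid` object: cell counts `n`, cell sizes `h_mm`, origin
#'   (box corner, mm), region label array, and cell volume `v_cell_mm3`.
#' @export
build_grid <- function(extent_mm, cell_mm, region = NULL) {
  stopifnot(length(extent_mm) == 3, length(cell_mm) == 3)
  if (any(extent_mm <= 0) || any(cell_mm <= 0)) {
    stop("extents and cell sizes must be positive")
  }
  n <- as.integer(floor(extent_mm / cell_mm + 0.5)) # round half up
  if (any(n < 2L)) {
    stop("grid must have at least 2 cells along every axis (stencil width)")
  }
  g <- structure(
    list(
      n = n,
      h_mm = as.numeric(cell_mm),
      origin_mm = c(0, 0, 0),
      extent_mm = n * as.numeric(cell_mm),
      v_cell_mm3 = prod(cell_mm),
      region = array(REGION_NORMAL, dim = n)
    ),
    class = "ced_grid"
  )
  if (!is.null(region)) {
    if (is.function(region)) {
      cc <- cell_centers(g)
      region <- region(cc$x, cc$y, cc$z)
    }
    g <- set_region(g, region)
  }
  g
}

#' @export
print.ced_grid <- function(x, ...) {
  cat(sprintf(
    "<ced_grid> %d x %d x %d cells (%s mm each), %d total\n",
    x$n[1], x$n[2], x$n[3], paste(format(x$h_mm), collapse = " x "),
    prod(x$n)
  ))
  tab <- table(factor(x$region, levels = 0:2,
                      labels = c("exterior", "tumor", "normal")))
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells in a grid
#' @param grid a `ced_grid`.
#' @return integer cell count.
#' @export
n_cells <- function(grid) as.integer(prod(grid$n))

#' Attach region labels to a grid
#' @param grid a `ced_grid`.
#' @param region integer array (0 = exterior, 1 = tumor, 2 = normal) matching
#'   the grid dimensions.
#' @return the grid with labels attached.
#' @export
set_region <- function(grid, region) {
  region <- array(as.integer(region), dim = dim(as.array(region)))
  if (!identical(dim(region), as.integer(grid$n))) {
    stop("region array does not match grid dimensions")
  }
  if (!all(region %in% 0:2)) stop("region labels must be 0, 1 or 2")
  grid$region <- region
  grid
}

#' Cell-centre physical coordinates
#' @param grid a `ced_grid`.
#' @return list of three arrays `x`, `y`, `z` of coordinates (mm).
#' @export
cell_centers <- function(grid) {
  ax <- lapply(1:3, function(a) {
    grid$origin_mm[a] + (seq_len(grid$n[a]) - 0.5) * grid$h_mm[a]
  })
  n <- grid$n
  list(
    x = array(rep(ax[[1]], times = n[2] * n[3]), dim = n),
    y = array(rep(rep(ax[[2]], each = n[1]), times = n[3]), dim = n),
    z = array(rep(ax[[3]], each = n[1] * n[2]), dim = n)
  )
}

#' Define an infusion catheter
#'
#' The catheter is a straight shaft inserted along one axis whose tip cell is
#' the infusion site.  Shaft cells between the domain boundary and the tip are
#' blocked (rigid wall: no flow, no flux), per the zero-slip/zero-flux wall
#' condition.
#'
#' @param grid a `ced_grid`.
#' @param tip_index integer length-3 `(i, j, k)` cell index of the infusion
#'   site (1-based); must lie in the tumor.
#' @param track_axis axis of insertion, `"x"`, `"y"` or `"z"`.
#' @param from_high logical; `TRUE` inserts from the high-index boundary.
#' @param diameter_mm catheter bore (must not exceed the in-plane cell size).
#' @param block_shaft logical; `FALSE` leaves the shaft cells open (an
#'   idealized point source, used for analytic verification).
#' @return a `ced_catheter`: tip index (vector and linear), blocked-cell
#'   linear indices, axis, diameter.
#' @export
catheter_spec <- function(grid, tip_index, track_axis = "z",
                          from_high = TRUE, diameter_mm = 0.9,
                          block_shaft = TRUE) {
  stopifnot(length(tip_index) == 3)
  tip_index <- as.integer(tip_index)
  if (any(tip_index < 1L) || any(tip_index > grid$n)) {
    stop("catheter tip outside the grid")
  }
  if (grid$region[tip_index[1], tip_index[2], tip_index[3]] != REGION_TUMOR) {
    stop("catheter tip must lie inside the tumor")
  }
  ax <- match(match.arg(track_axis, c("x", "y", "z")), c("x", "y", "z"))
  inplane <- min(grid$h_mm[-ax])
  if (diameter_mm > inplane + 1e-9) {
    stop("catheter diameter exceeds the in-plane cell size")
  }
  ks <- if (from_high) {
    seq_len(grid$n[ax] - tip_index[ax]) + tip_index[ax]
  } else {
    seq_len(tip_index[ax] - 1L)
  }
  blocked <- integer(0)
  if (!block_shaft) ks <- integer(0)
  if (length(ks)) {
    ijk <- matrix(rep(tip_index, each = length(ks)), ncol = 3)
    ijk[, ax] <- ks
    blocked <- ijk_to_linear(grid, ijk)
  }
  structure(
    list(
      tip_index = tip_index,
      tip_linear = ijk_to_linear(grid, matrix(tip_index, ncol = 3)),
      blocked = blocked,
      track_axis = c("x", "y", "z")[ax],
      from_high = from_high,
      diameter_mm = diameter_mm
    ),
    class = "ced_catheter"
  )
}

#' Euclidean distance from every cell centre to the infusion site
#'
#' @param grid a `ced_grid`.
#' @param catheter a `ced_catheter` (or an integer length-3 tip index).
#' @return array of distances (mm); zero exactly at the tip cell.
#' @export
distance_map <- function(grid, catheter) {
  tip <- if (inherits(catheter, "ced_catheter")) catheter$tip_index
         else as.integer(catheter)
  cc <- cell_centers(grid)
  tc <- grid$origin_mm + (tip - 0.5) * grid$h_mm
  sqrt((cc$x - tc[1])^2 + (cc$y - tc[2])^2 + (cc$z - tc[3])^2)
}

ijk_to_linear <- function(grid, ijk) {
  n <- grid$n
  as.integer(ijk[, 1] + n[1] * (ijk[, 2] - 1L) + n[1] * n[2] * (ijk[, 3] - 1L))
}

linear_to_ijk <- function(grid, lin) {
  n <- grid$n
  lin0 <- lin - 1L
  cbind(
    i = lin0 %% n[1] + 1L,
    j = (lin0 %/% n[1]) %% n[2] + 1L,
    k = lin0 %/% (n[1] * n[2]) + 1L
  )
}
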