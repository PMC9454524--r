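# Shared fixtures: all built in code, no files.

# Homogeneous single-region tissue on a cubic grid.
uniform_tissue <- function(n = 16, h_mm = 2, region = "tumor",
                           epsBL = 0.02, epsECS = 0.40, ktrans = 3e-3,
                           lambda = 0) {
  code <- if (region == "tumor") 1L else 2L
  g <- build_grid(rep(n * h_mm, 3), rep(h_mm, 3),
                  region = array(code, dim = c(n, n, n)))
  if (region != "tumor") {
    # derive_property_maps needs at least one tumor voxel for Kavg
    r <- g$region
    r[1, 1, 1] <- 1L
    g <- set_region(g, r)
  }
  m <- perfusion_maps(array(epsBL, dim = g$n), array(ktrans, dim = g$n),
                      array(epsECS, dim = g$n), array(lambda, dim = g$n))
  derive_property_maps(m, g)
}

# Small heterogeneous phantom used across tests (32 mm box, 2 mm voxels).
small_phantom_spec <- function(seed = 7, ...) {
  phantom_spec(grid_dims_mm = c(32, 32, 32), voxel_mm = c(2, 2, 2),
               tumor_center_mm = c(16, 16, 16), tumor_radii_mm = c(9, 10, 8),
               seed = seed, ...)
}

# The scaled-down study phantom: 32^3 cells, tumor of ~11 cm^3.
study_phantom <- function(seed = 1) {
  generate_tissue_maps(phantom_spec(
    grid_dims_mm = c(48, 48, 48), voxel_mm = c(1.5, 1.5, 1.5),
    tumor_center_mm = c(24, 24, 24), tumor_radii_mm = c(13, 15, 14),
    seed = seed
  ))
}

# Short DCE sampling grid (2-minute acquisition at 3.8 s resolution).
dce_times <- function() seq(0, 129.2, by = 3.8)
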