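# NIfTI / CSV / JSON input-output.  Property maps and snapshots are written
# as NIfTI volumes sharing one affine built from the grid spacing; grid
# metadata goes in a small JSON sidecar; tabular outputs are plain CSV.

#' Write a 3D or 4D field as a NIfTI volume
#'
#' @param field numeric array (3D, or 4D for a dynamic series).
#' @param grid a `ced_grid` supplying the voxel spacing.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param dt_s temporal spacing for 4D series (s).
#' @return the path, invisibly.
#' @export
write_field_nifti <- function(field, grid, path, dt_s = 1) {
  img <- RNifti::asNifti(field)
  RNifti::pixdim(img) <- c(grid$h_mm, if (length(dim(field)) == 4) dt_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path file path.
#' @return numeric array with a `pixdim_mm` attribute.
#' @export
read_field_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "pixdim_mm") <- RNifti::pixdim(img)
  out
}

#' Write grid metadata as a JSON sidecar
#'
#' @param grid a `ced_grid`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_grid_json <- function(grid, path) {
  jsonlite::write_json(
    list(n = grid$n, h_mm = grid$h_mm, origin_mm = grid$origin_mm,
         extent_mm = grid$extent_mm,
         region_counts = as.list(table(factor(grid$region, levels = 0:2,
                                              labels = c("exterior", "tumor",
                                                         "normal"))))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write an arterial input function as CSV
#'
#' @param aif a `ced_aif`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_aif_csv <- function(aif, path) {
  write.csv(data.frame(time_s = aif$times_s, cb_mM = aif$cb_mM), path,
            row.names = FALSE)
  invisible(path)
}

#' Read an arterial input function from CSV
#'
#' @param path CSV with columns `time_s` and `cb_mM`.
#' @return a `ced_aif`.
#' @export
read_aif_csv <- function(path) {
  d <- read.csv(path)
  structure(list(times_s = d$time_s, cb_mM = d$cb_mM), class = "ced_aif")
}

#' Write all tissue property maps as NIfTI volumes
#'
#' One file per property (`eps_bl0`, `eps_ecs0`, `eps_cm`, `eps_ics`,
#' `sv0`, `ktrans_s`, `lambda_tr_s`, plus region labels), with a shared
#' grid sidecar.
#'
#' @param tissue a `ced_tissue`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_tissue_maps <- function(tissue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fields <- c("eps_bl0", "eps_ecs0", "eps_cm", "eps_ics", "sv0",
              "ktrans_s", "lambda_tr_s")
  paths <- vapply(fields, function(f) {
    p <- file.path(dir, paste0(f, ".nii.gz"))
    write_field_nifti(tissue[[f]], tissue$grid, p)
    p
  }, character(1))
  rp <- file.path(dir, "region.nii.gz")
  write_field_nifti(tissue$grid$region + 0, tissue$grid, rp)
  write_grid_json(tissue$grid, file.path(dir, "grid.json"))
  invisible(c(paths, region = rp))
}
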