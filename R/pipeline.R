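# End-to-end orchestration: phantom -> (optional) DCE fitting -> regimen
# simulations -> delivery metrics, with every intermediate artifact written
# to disk and a deterministic summary table.

#' Select an infusion site in the tumor
#'
#' Site-selection modes: the maximum-epsBL cell (densest microvasculature,
#' the default catheter position), an explicitly given index, or the tumor
#' cell whose epsBL / epsICS is closest to a given quantile of its tumor
#' distribution (used for infusion-site sensitivity sweeps).
#'
#' @param tissue a `ced_tissue`.
#' @param mode one of `"max_epsBL"`, `"index"`, `"epsBL_quantile"`,
#'   `"epsICS_quantile"`.
#' @param index integer length-3 cell index (for `mode = "index"`).
#' @param q quantile in `[0, 1]` (for the quantile modes).
#' @return integer length-3 cell index `(i, j, k)`.
#' @export
select_infusion_site <- function(tissue,
                                 mode = c("max_epsBL", "index",
                                          "epsBL_quantile", "epsICS_quantile"),
                                 index = NULL, q = 0.5) {
  mode <- match.arg(mode)
  grid <- tissue$grid
  tumor_lin <- which(grid$region == REGION_TUMOR)
  if (!length(tumor_lin)) stop("no tumor cells")
  pick <- switch(
    mode,
    max_epsBL = tumor_lin[which.max(tissue$eps_bl0[tumor_lin])],
    index = {
      if (is.null(index)) stop("mode 'index' requires an index")
      return(as.integer(index))
    },
    epsBL_quantile = {
      v <- tissue$eps_bl0[tumor_lin]
      tumor_lin[which.min(abs(v - stats::quantile(v, q)))]
    },
    epsICS_quantile = {
      v <- tissue$eps_ics[tumor_lin]
      tumor_lin[which.min(abs(v - stats::quantile(v, q)))]
    }
  )
  linear_to_ijk(grid, pick)[1, ]
}

#' Run configuration for a full experiment
#'
#' @param phantom a [phantom_spec()] (or `NULL` when `tissue` is given).
#' @param tissue optional pre-built `ced_tissue` (exactly one of `phantom`
#'   or `tissue` must be supplied).
#' @param regimens character vector of regimen names to simulate.
#' @param site_mode,site_q infusion-site selection (see
#'   [select_infusion_site()]); `site_q` may be a vector to sweep sites.
#' @param fit_dce logical: regenerate the property maps by synthesizing and
#'   fitting a DCE series instead of using the phantom ground truth.
#' @param T_in_days infusion duration applied to every regimen (days).
#' @param numerics a [numerics_opts()] list.
#' @param out_dir output directory.
#' @param seed integer seed controlling every random draw.
#' @return a `ced_run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), tissue = NULL,
                       regimens = c("plainTMZ", "plainTMZ+BEV",
                                    "liposomalTMZ", "liposomalTMZ+BEV"),
                       site_mode = "max_epsBL", site_q = 0.5,
                       fit_dce = FALSE, T_in_days = 3,
                       numerics = numerics_opts(),
                       out_dir = tempfile("cedsim_run_"), seed = 1L) {
  if (is.null(phantom) == is.null(tissue)) {
    stop("exactly one of 'phantom' or 'tissue' must be supplied")
  }
  structure(
    list(phantom = phantom, tissue = tissue, regimens = regimens,
         site_mode = site_mode, site_q = site_q, fit_dce = fit_dce,
         T_in_days = T_in_days, numerics = numerics, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "ced_run_config"
  )
}

#' Execute a configured experiment end-to-end
#'
#' Stages: (1) phantom generation (or ingestion of a supplied tissue);
#' (2) optional DCE synthesis + voxelwise LTKM fitting of the property maps;
#' (3) one simulation per regimen x site; (4) delivery metrics per run.
#' Every stage writes its artifacts under `out_dir` (NIfTI maps, CSV
#' series/metrics, JSON log) and the whole run is deterministic for a fixed
#' seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the `summary` data frame (regimen, site,
#'   Day-end spatial-averaged free drug, NUN, V_eff), per-run trajectories,
#'   the tissue, and the stage log.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "ced_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stamp <- function(stage, t0, extra = NULL) {
    c(list(stage = stage, wall_s = as.numeric(Sys.time()) - t0), extra)
  }

  t0 <- as.numeric(Sys.time())
  if (!is.null(config$phantom)) {
    spec <- config$phantom
    spec$seed <- config$seed
    ph <- generate_tissue_maps(spec)
    tissue <- ph$tissue
  } else {
    tissue <- config$tissue
    ph <- NULL
  }
  write_tissue_maps(tissue, file.path(config$out_dir, "tissue"))
  log$phantom <- stamp("phantom", t0)

  if (config$fit_dce) {
    if (is.null(ph)) stop("fit_dce requires a phantom input")
    t0 <- as.numeric(Sys.time())
    acq <- acquisition_params()
    times <- seq(0, 129, by = acq$dt_s)
    aif <- synth_aif(times)
    write_aif_csv(aif, file.path(config$out_dir, "aif.csv"))
    series <- generate_dce_series(ph$maps, aif, times, ph$t10_s, acq,
                                  noise_sd_frac = spec$noise_sd_frac,
                                  seed = config$seed,
                                  mask = tissue$grid$region == REGION_TUMOR)
    write_field_nifti(series, tissue$grid,
                      file.path(config$out_dir, "dce_series.nii.gz"),
                      dt_s = acq$dt_s)
    fitted <- fit_perfusion_maps(series, times, aif, ph$t10_s, acq,
                                 mask = tissue$grid$region == REGION_TUMOR)
    refit <- ph$maps
    tmask <- tissue$grid$region == REGION_TUMOR
    for (f in c("epsBL", "ktrans_s", "epsECS", "lambda_tr_s")) {
      refit[[f]][tmask] <- fitted[[f]][tmask]
    }
    tissue <- derive_property_maps(refit, tissue$grid, t10_map = ph$t10_s)
    diag <- data.frame(voxel = which(tmask), rss = fitted$rss[tmask],
                       converged = fitted$converged[tmask])
    write.csv(diag, file.path(config$out_dir, "fit_diagnostics.csv"),
              row.names = FALSE)
    log$fit_dce <- stamp("fit_dce", t0, list(n_voxels = sum(tmask)))
  }

  tumor <- tissue$grid$region == REGION_TUMOR
  runs <- list()
  rows <- list()
  for (qi in seq_along(config$site_q)) {
    site <- select_infusion_site(tissue, config$site_mode,
                                 q = config$site_q[qi])
    for (rg in config$regimens) {
      t0 <- as.numeric(Sys.time())
      reg <- regimen_spec(rg, T_in_days = config$T_in_days, site = site)
      traj <- simulate_regimen(tissue, reg, numerics = config$numerics)
      key <- sprintf("%s_site%d", rg, qi)
      runs[[key]] <- traj
      write.csv(traj$series,
                file.path(config$out_dir, paste0("series_", key, ".csv")),
                row.names = FALSE)
      conc <- concentrations(traj$state)
      write_field_nifti(conc$C_FD, tissue$grid,
                        file.path(config$out_dir,
                                  paste0("cfd_final_", key, ".nii.gz")))
      write_field_nifti(traj$flow$p, tissue$grid,
                        file.path(config$out_dir,
                                  paste0("ifp_final_", key, ".nii.gz")))
      write_field_nifti(traj$flow$v_mag, tissue$grid,
                        file.path(config$out_dir,
                                  paste0("ifv_final_", key, ".nii.gz")))
      write_field_nifti(traj$flow$F_BL, tissue$grid,
                        file.path(config$out_dir,
                                  paste0("fbl_final_", key, ".nii.gz")))
      jsonlite::write_json(
        c(traj$flow$balance,
          list(budget_mol = traj$budget$groups,
               budget_closure_rel = as.list(traj$budget$closure_rel))),
        file.path(config$out_dir, paste0("balance_", key, ".json")),
        auto_unbox = TRUE, digits = NA, force = TRUE
      )
      rows[[key]] <- data.frame(
        regimen = rg, site_i = site[1], site_j = site[2], site_k = site[3],
        site_epsBL = tissue$eps_bl0[site[1], site[2], site[3]],
        site_epsICS = tissue$eps_ics[site[1], site[2], site[3]],
        cfd_avg_M = spatial_avg(conc$C_FD, traj$state$eps$ecs, tumor),
        nun = nun(conc$C_FD, traj$state$eps$ecs, tumor),
        veff_mm3 = effective_volume(conc$C_FD, tissue$grid, tumor),
        budget_closure = max(traj$budget$closure_rel)
      )
      log[[key]] <- stamp(key, t0, list(
        flow_relres = traj$flow$balance$cg_relres,
        balance_rel = traj$flow$balance$rel_error
      ))
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  write.csv(summary, file.path(config$out_dir, "summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(summary = summary, runs = runs, tissue = tissue, log = log))
}
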