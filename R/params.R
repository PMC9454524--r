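#' Biological properties of tumor and normal brain tissue
#'
#' Literature baseline values for the porous-medium flow and vascular exchange
#' model: hydraulic conductivity of the microvasculature wall `L_BL`
#' (m Pa^-1 s^-1), baseline vessel surface area per tissue volume `SVb`
#' (m^-1), blood pressure `p_BL` (Pa), osmotic reflection coefficient
#' `sigma_BL`, blood/interstitial osmotic pressures `pi_BL`, `pi_ISF` (Pa),
#' interstitial fluid density `rho` (kg m^-3) and viscosity `mu` (Pa s),
#' tissue permeability `kappa` (m^2), and the natural angiogenesis rate
#' coefficients `alpha`, `beta`, `gamma` (s^-1) of the vascular scaling ODE.
#'
#' @return a list with elements `tumor` and `normal`, each a named list.
#' @export
tissue_tables <- function() {
  list(
    tumor = list(
      L_BL = 1.1e-12, SVb = 2.0e4, p_BL = 4610, sigma_BL = 0.82,
      pi_BL = 3440, pi_ISF = 1110, rho = 1000, mu = 7.8e-4,
      kappa = 6.4e-14, alpha = -1.85e-6, beta = 5.56e-6, gamma = -3.71e-6,
      cm_ics_ratio = 0.154
    ),
    normal = list(
      L_BL = 1.4e-13, SVb = 7.0e3, p_BL = 4610, sigma_BL = 0.91,
      pi_BL = 3440, pi_ISF = 740, rho = 1000, mu = 7.8e-4,
      kappa = 6.5e-15, alpha = -1.85e-6, beta = 5.56e-6, gamma = -3.71e-6,
      cm_ics_ratio = 0.188
    )
  )
}

#' Transport and pharmacological drug properties
#'
#' Baseline values for the three modelled species: the antiangiogenic
#' antibody (bevacizumab-like, `bev`), the liposome carrier (`lip`), and the
#' free cytotoxic drug (temozolomide-like, `tmz`).  Per-region values carry
#' `_t` (tumor) and `_n` (normal tissue) suffixes.  Units: diffusivities
#' `D` m^2 s^-1; transvascular permeabilities `P_TV` m s^-1; rates s^-1;
#' the antiangiogenic rate `k_a` M^-1 s^-1; `LD90` M.
#'
#' @return nested named list of drug parameters.
#' @export
drug_library <- function() {
  list(
    bev = list(
      MW = 1.49e5,
      D_t = 3.2e-13, D_n = 4.9e-14,
      k_a = 1.12, k_e = 1.2e-5
    ),
    lip = list(
      P_TV_t = 5.8e-8, P_TV_n = 0,
      D_t = 1.5e-13, D_n = 3.2e-14,
      k_rel = 6.4e-4
    ),
    tmz = list(
      MW = 1.94e2,
      P_TV_t = 8.0e-8, P_TV_n = 4.3e-8,
      D_t = 7.2e-10, D_n = 3.4e-10,
      K_BC = 0.18, H_CE = 1.5e-2, H_IE = 1.0,
      k_e = 1.1e-4, LD90 = 3.9e-5
    )
  )
}

# Expand a per-region scalar (tumor/normal, exterior -> 0) onto the grid.
region_field <- function(grid, tumor_value, normal_value) {
  out <- array(0, dim = grid$n)
  out[grid$region == REGION_TUMOR] <- tumor_value
  out[grid$region == REGION_NORMAL] <- normal_value
  out
}

# Per-cell tissue property arrays from the region tables.
expand_tissue_properties <- function(grid, tables = tissue_tables()) {
  fields <- c("L_BL", "p_BL", "sigma_BL", "pi_BL", "pi_ISF", "mu", "kappa",
              "alpha", "beta", "gamma", "cm_ics_ratio")
  out <- lapply(fields, function(f) {
    region_field(grid, tables$tumor[[f]], tables$normal[[f]])
  })
  names(out) <- fields
  out
}
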