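#' Calibrated soil hydraulic parameter sets for the drainfield mesocosms
#'
#' Mean calibrated van Genuchten parameters (n = 3 replicate mesocosms) for
#' the native materials of each drainfield type: Bridgehampton silt loam
#' (A horizon) and gravelly-coarse sand (B/C horizons). The conventional
#' pipe-and-stone system was calibrated with a single native material
#' (gravelly-coarse sand; its low Ks reflects the biomat that develops at
#' the infiltrative surface). The engineered layers (entangled plastic
#' filaments of the Geomat, crushed stone of pipe-and-stone) are fixed,
#' highly conductive coarse-gravel-like materials (Ks = 3000 cm/d,
#' bulk density 1.50 g/cm^3) and are never calibrated.
#'
#' @param system One of `"PSND"`, `"GEO"`, `"P&S"`.
#' @return Named list of [vg_params()] objects (`silt_loam`, `sand`, and
#'   `filament` or `stone` where present).
#' @export
drainfield_hydraulics <- function(system = c("PSND", "GEO", "P&S")) {
  system <- match.arg(system)
  gravel <- vg_params(0.005, 0.30, 0.10, 3.0, Ks = 3000)
  switch(system,
    "PSND" = list(
      silt_loam = vg_params(0.025, 0.203, 0.0847, 2.289, Ks = 220.02),
      sand      = vg_params(0.013, 0.063, 0.0205, 4.037, Ks = 908.88)),
    "GEO" = list(
      silt_loam = vg_params(0.024, 0.181, 0.0182, 2.282, Ks = 252.43),
      sand      = vg_params(0.014, 0.138, 0.0189, 4.282, Ks = 942.48),
      filament  = gravel),
    "P&S" = list(
      sand      = vg_params(0.012, 0.068, 0.0838, 3.731, Ks = 4.513),
      stone     = gravel))
}

#' Modeled water-filled pore space reference values
#'
#' Layer-mean WFPS (theta/theta_s, mean +/- SD over the three replicate
#' calibrated mesocosm models) reported for the native soil layers. Used as
#' reference states by the kinetic parameterization helper and as targets
#' by the acceptance checks.
#'
#' @return Data frame with columns `system`, `material`, `wfps`, `sd`.
#' @export
wfps_reference <- function() {
  data.frame(
    system   = c("PSND", "PSND", "GEO", "GEO", "P&S"),
    material = c("silt_loam", "sand", "silt_loam", "sand", "sand"),
    wfps     = c(0.64, 0.41, 0.74, 0.56, 0.27),
    sd       = c(0.06, 0.05, 0.15, 0.15, 0.02)
  )
}

#' Average effective zero-order transformation rates per material
#'
#' Mean simulated zero-order nitrification and denitrification rates
#' (mg N L^-1 d^-1, n = 3) per material and system, used as targets when
#' back-calculating `mu_max` with [mu_max_from_rate()].
#'
#' @return Data frame with columns `system`, `material`, `nitrification`,
#'   `denitrification`.
#' @export
zero_order_rates <- function() {
  data.frame(
    system   = c("PSND", "PSND", "GEO", "GEO", "GEO", "P&S", "P&S"),
    material = c("silt_loam", "sand",
                 "silt_loam", "sand", "filament",
                 "sand", "stone"),
    nitrification   = c(45.25, 49.19, 2.17, 24.46, 25.88, 3.83, 12.10),
    denitrification = c(0.17, 1.31, 0.04, 0.31, 0.01, 0.36, 0.44)
  )
}

#' Default kinetic parameter sets per material for a drainfield system
#'
#' Builds nitrification/denitrification parameter objects for every
#' material of a system, with `mu_max` back-calculated from the effective
#' zero-order layer rates at the layer's reference WFPS and 20 C
#' ([mu_max_from_rate()]). Engineered layers, for which no WFPS is
#' reported, use a nominal reference saturation of 0.30. Depth references
#' are the mid-depths of each layer below the infiltrative surface.
#'
#' @param system One of `"PSND"`, `"GEO"`, `"P&S"`.
#' @param Topt,beta,alpha_c,Km Shared kinetic constants (see
#'   [nitrification_params()] and [denitrification_params()]).
#' @return Named list (by material) of lists with elements `nit` and
#'   `denit`.
#' @export
drainfield_kinetics <- function(system = c("PSND", "GEO", "P&S"),
                                Topt = 22.5, beta = 0.177,
                                alpha_c = 0.02, Km = 5) {
  system <- match.arg(system)
  rates <- zero_order_rates()
  rates <- rates[rates$system == system, ]
  wref <- wfps_reference()
  wref <- wref[wref$system == system, ]
  # layer mid-depths below the infiltrative surface (cm); engineered layers
  # sit at/above the IS (z = 0)
  zmid <- switch(system,
    "PSND" = c(silt_loam = 12.5, sand = 58.5),
    "GEO"  = c(silt_loam = 10.5, sand = 53.5, filament = 0.5),
    "P&S"  = c(sand = 26.5, stone = 0))
  out <- list()
  for (i in seq_len(nrow(rates))) {
    mat <- rates$material[i]
    S_ref <- if (mat %in% wref$material) {
      wref$wfps[wref$material == mat]
    } else 0.30
    nit0 <- nitrification_params(1, Km = Km, Topt = Topt, beta = beta)
    den0 <- denitrification_params(1, Km = Km, alpha_c = alpha_c,
                                   Topt = Topt, beta = beta)
    mu_nit <- mu_max_from_rate(rates$nitrification[i], S_ref, 20,
                               p = nit0, min_factor = 1e-4)
    mu_den <- mu_max_from_rate(rates$denitrification[i], S_ref, 20,
                               z_ref = zmid[[mat]], p = den0,
                               min_factor = 1e-4)
    out[[mat]] <- list(
      nit = nitrification_params(mu_nit, Km = Km, Topt = Topt, beta = beta),
      denit = denitrification_params(mu_den, Km = Km, alpha_c = alpha_c,
                                     Topt = Topt, beta = beta))
  }
  out
}

#' Default influent statistics per effluent source
#'
#' Field-typical total-N statistics of septic tank effluent (STE) and
#' advanced-treated (sand filter) effluent (ATE) used by the synthetic
#' influent generator: weekly TN draws with the stated mean and SD.
#'
#' @param source `"STE"` or `"ATE"`.
#' @return List with `mean`, `sd` (mg N L^-1) and `source`.
#' @export
influent_defaults <- function(source = c("STE", "ATE")) {
  source <- match.arg(source)
  switch(source,
    STE = list(mean = 60, sd = 9, source = "STE"),
    ATE = list(mean = 26, sd = 5, source = "ATE"))
}
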