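#' Climate scenario definition
#'
#' The climate projections explored are a warmer soil (23 C against the
#' 20 C baseline), a water table raised by 30 cm (thinning the unsaturated
#' zone), and both combined.
#'
#' @param temperature Soil temperature (degrees C), > 0; baseline 20.
#' @param water_table_rise Rise of the water table (cm), `>= 0`; the
#'   climate scenario uses 30.
#' @param label Optional label.
#' @return An object of class `dfn_scenario`.
#' @export
scenario <- function(temperature = 20, water_table_rise = 0,
                     label = NULL) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (water_table_rise < 0) {
    stop("water_table_rise must be >= 0", call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (temperature != 20 && water_table_rise > 0) "IWT+warm"
    else if (water_table_rise > 0) "IWT"
    else if (temperature != 20) sprintf("%gC", temperature)
    else "baseline"
  }
  structure(list(temperature = temperature,
                 water_table_rise = water_table_rise, label = label),
            class = "dfn_scenario")
}

#' Apply a climate scenario to a run configuration
#'
#' Pure transformation: returns a modified copy of the configuration with
#' the scenario temperature and water-table rise set; the baseline object
#' is never mutated. The identity scenario (20 C, no rise) returns the
#' configuration unchanged. The rise must be smaller than the unsaturated
#' thickness of the system geometry.
#'
#' @param config A run configuration list (see [load_config()]); at
#'   minimum carries `system` and optional `geometry$height`,
#'   `geometry$is_depth`.
#' @param s A [scenario()].
#' @return The modified configuration.
#' @export
apply_scenario <- function(config, s) {
  stopifnot(inherits(s, "dfn_scenario"))
  height <- config$geometry$height %||% 137
  is_depth <- config$geometry$is_depth %||%
    switch(config$system %||% "PSND", "PSND" = 20, "GEO" = 25, "P&S" = 84)
  if (s$water_table_rise >= height - is_depth) {
    stop("water-table rise reaches the infiltrative surface", call. = FALSE)
  }
  out <- config
  out$transport$temperature <- s$temperature
  out$scenario <- list(temperature = s$temperature,
                       water_table_rise = s$water_table_rise,
                       label = s$label)
  if (s$temperature == 20 && s$water_table_rise == 0) {
    out$scenario <- config$scenario  # identity: leave untouched
    out$transport$temperature <- config$transport$temperature
  }
  out
}

#' Raise the water table of a domain
#'
#' Implements the raised-water-table scenario: the seepage outlet is
#' relocated from the domain bottom to the new water-table level and the
#' zone below it is initialized (and remains) saturated, thinning the
#' unsaturated zone by `rise` cm. The input domain is not modified.
#'
#' @param domain A `dfn_domain`.
#' @param rise Water-table rise (cm), `>= 0`.
#' @return A modified copy of the domain.
#' @export
raise_water_table <- function(domain, rise) {
  if (rise < 0) stop("rise must be >= 0", call. = FALSE)
  if (rise == 0) return(domain)
  wt <- domain$height - rise
  if (wt <= domain$is_depth) {
    stop("water-table rise reaches the infiltrative surface",
         call. = FALSE)
  }
  jb <- which(domain$zf[-1] <= wt + 1e-9)
  j_seep <- jb[length(jb)]
  domain$water_table_depth <- domain$zf[j_seep + 1]
  domain$seep_cells <- cell_id(domain, j_seep, 1L)
  # refresh the boundary table and keep the outlet observation node in step
  domain$boundaries$length[domain$boundaries$type == "seepage_face"] <-
    domain$dx[1]
  if (!is.null(domain$obs)) {
    io <- domain$obs$label == "outlet"
    domain$obs$cell[io] <- domain$seep_cells[1]
    domain$obs$z[io] <- domain$zc[j_seep]
    domain$obs$depth_bgs[io] <- domain$zc[j_seep]
    # add a node at the water-table level on the centreline
    icol <- which.min(abs(domain$xc - domain$width / 2))
    if (!"water_table" %in% domain$obs$label) {
      domain$obs <- rbind(domain$obs, data.frame(
        label = "water_table", depth_bgs = domain$zc[j_seep],
        cell = cell_id(domain, j_seep, icol), x = domain$xc[icol],
        z = domain$zc[j_seep],
        material = names(domain$materials)[domain$mat[j_seep, icol]]))
    }
  }
  domain
}

#' Unsaturated-zone thickness of a domain
#'
#' Distance from the infiltrative surface down to the seepage-controlled
#' water table (the domain bottom unless the water table has been raised).
#'
#' @param domain A `dfn_domain`.
#' @return Thickness (cm).
#' @export
unsaturated_thickness <- function(domain) {
  domain$water_table_depth - domain$is_depth
}

#' Compare a scenario run against its baseline
#'
#' Reports the change in the N2 loss fraction (absolute, in percentage
#' points of N input, and relative, in percent of the baseline loss) and
#' in mean effluent NH4/NO3 concentrations.
#'
#' @param baseline,scenario_run `transport_result` objects (or lists with
#'   elements `mass_balance` and `effluent`) from the same system and
#'   influent series.
#' @return List of class `scenario_delta`.
#' @export
compare_runs <- function(baseline, scenario_run) {
  getmb <- function(x) {
    if (inherits(x, "transport_result")) nitrogen_mass_balance(x)
    else x$mass_balance
  }
  geteff <- function(x) x$effluent
  sysb <- if (inherits(baseline, "transport_result"))
    baseline$domain$system else baseline$system
  syss <- if (inherits(scenario_run, "transport_result"))
    scenario_run$domain$system else scenario_run$system
  if (!is.null(sysb) && !is.null(syss) && !identical(sysb, syss)) {
    stop("compare_runs: runs come from different systems", call. = FALSE)
  }
  mb0 <- getmb(baseline); mb1 <- getmb(scenario_run)
  e0 <- geteff(baseline); e1 <- geteff(scenario_run)
  mean_eff <- function(e, col) mean(e[[col]][e$q_out > 0], na.rm = TRUE)
  out <- list(
    d_n2_points = mb1$frac_N2 - mb0$frac_N2,
    pct_change_n2 = if (mb0$frac_N2 > 0)
      100 * (mb1$frac_N2 - mb0$frac_N2) / mb0$frac_N2 else NA_real_,
    d_eff_NH4 = mean_eff(e1, "C_NH4") - mean_eff(e0, "C_NH4"),
    d_eff_NO3 = mean_eff(e1, "C_NO3") - mean_eff(e0, "C_NO3"),
    baseline_n2 = mb0$frac_N2, scenario_n2 = mb1$frac_N2,
    baseline_eff_NH4 = mean_eff(e0, "C_NH4"),
    scenario_eff_NH4 = mean_eff(e1, "C_NH4"),
    baseline_eff_NO3 = mean_eff(e0, "C_NO3"),
    scenario_eff_NO3 = mean_eff(e1, "C_NO3"))
  structure(out, class = "scenario_delta")
}

#' @export
print.scenario_delta <- function(x, ...) {
  cat(sprintf("scenario vs baseline: N2 %.2f%% -> %.2f%% (%+.2f points, %+.1f%%); effluent NH4 %+.3g mg/L, NO3 %+.3g mg/L\n",
              x$baseline_n2, x$scenario_n2, x$d_n2_points,
              x$pct_change_n2, x$d_eff_NH4, x$d_eff_NO3))
  invisible(x)
}
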