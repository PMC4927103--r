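#' Synthetic-experiment ground truth
#'
#' Defines a complete, known parameterization from which synthetic
#' observation sets are generated: true hydraulic and kinetic parameters,
#' influent statistics, and the noise model (additive Gaussian noise on
#' moisture, multiplicative lognormal noise on concentrations, preserving
#' non-negativity). Defaults reproduce the calibrated mesocosm regime, so
#' synthetic experiments exercise the model where the real systems
#' operate.
#'
#' @param system `"PSND"`, `"GEO"` or `"P&S"`.
#' @param hydraulics Named list of [vg_params()] per material; defaults to
#'   [drainfield_hydraulics()].
#' @param kinetics Per-material kinetics as in [drainfield_kinetics()], or
#'   `NULL` to generate flow/moisture data only.
#' @param influent_stats `list(mean, sd, source)`; defaults per the
#'   system's effluent type.
#' @param noise `list(moisture_sd, conc_cv)`; SDs must be `>= 0`.
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(system = c("PSND", "GEO", "P&S"),
                            hydraulics = NULL, kinetics = NULL,
                            influent_stats = NULL,
                            noise = list(moisture_sd = 0.005,
                                         conc_cv = 0.1),
                            seed = 1L) {
  system <- match.arg(system)
  if (is.null(hydraulics)) hydraulics <- drainfield_hydraulics(system)
  if (is.null(influent_stats)) {
    influent_stats <- influent_defaults(
      if (system == "P&S") "STE" else "ATE")
  }
  if (influent_stats$sd < 0 || noise$moisture_sd < 0 || noise$conc_cv < 0) {
    stop("noise/influent SDs must be >= 0", call. = FALSE)
  }
  structure(list(system = system, hydraulics = hydraulics,
                 kinetics = kinetics, influent_stats = influent_stats,
                 noise = noise, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a weekly influent series
#'
#' Weekly total-N draws (Gaussian, truncated at zero) speciated into
#' NH4-N and NO3-N pools according to the effluent type. The seed fixes
#' the draws; identical seeds give identical tables.
#'
#' @param stats `list(mean, sd, source)` (see [influent_defaults()]).
#' @param n_weeks Number of weeks, `>= 1`.
#' @param seed Integer seed.
#' @return Data frame `week`, `time_d`, `TN`, `C_NH4`, `C_NO3`.
#' @export
generate_influent_series <- function(stats, n_weeks, seed = 1L) {
  if (n_weeks < 1) stop("n_weeks must be >= 1", call. = FALSE)
  if (stats$sd < 0) stop("influent sd must be >= 0", call. = FALSE)
  set.seed(seed)
  TN <- pmax(stats::rnorm(n_weeks, stats$mean, stats$sd), 0)
  sp <- speciate_influent(TN, stats$source)
  data.frame(week = seq_len(n_weeks), time_d = (seq_len(n_weeks) - 1) * 7,
             TN = TN, C_NH4 = sp$C_NH4, C_NO3 = sp$C_NO3)
}

set_hydraulics <- function(domain, hydraulics) {
  for (nm in names(hydraulics)) {
    if (!nm %in% names(domain$materials)) next
    domain$materials[[nm]]$vg <- hydraulics[[nm]]
  }
  domain
}

#' Generate a synthetic mesocosm observation set
#'
#' Runs the forward model at the ground truth and samples it the way the
#' mesocosms were instrumented: soil moisture sub-daily at the probe
#' depths (15 and 30 cm below the infiltrative surface) and effluent
#' chemistry weekly, with noise added per the truth's noise model. With
#' zero noise the observations equal the forward output at the sample
#' times exactly.
#'
#' @param truth A [synthetic_truth()].
#' @param t_end Simulated/observed period (d).
#' @param sample_dt Moisture sampling interval (d); snapped to the solver
#'   output grid.
#' @param overrides Mesh/geometry overrides passed to [build_mesocosm()]
#'   (coarser meshes keep synthetic studies fast).
#' @param cfg Optional [flow_config()]; `t_end` and flux storage are set
#'   as needed.
#' @return List of class `synthetic_observations`: `obs` (an
#'   [observation_set()]), `influent`, `flow`, `transport` (or `NULL`),
#'   and `truth`.
#' @export
generate_mesocosm_observations <- function(truth, t_end = 10,
                                           sample_dt = 0.25,
                                           overrides = list(),
                                           cfg = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  domain <- build_mesocosm(truth$system, overrides)
  domain <- set_hydraulics(domain, truth$hydraulics)
  if (is.null(cfg)) cfg <- flow_config()
  cfg$t_end <- t_end
  cfg$avg_window <- min(cfg$avg_window, t_end / 2)
  cfg$store_fluxes <- !is.null(truth$kinetics)
  flow <- solve_flow(domain, default_schedule(truth$system), cfg)

  n_weeks <- max(1L, ceiling(t_end / 7))
  influent <- generate_influent_series(truth$influent_stats, n_weeks,
                                       seed = truth$seed + 1L)
  tr <- NULL
  if (!is.null(truth$kinetics)) {
    tr <- solve_transport(flow, domain, truth$kinetics, influent)
  }

  # moisture at the probe nodes, sub-daily, snapped to the output grid
  grid <- flow$times
  want <- seq(0, t_end, by = sample_dt)
  idx <- unique(vapply(want, function(t) which.min(abs(grid - t)),
                       integer(1)))
  probes <- grep("^is_", domain$obs$label, value = TRUE)
  obs_list <- list()
  for (pn in probes) {
    ser <- flow$obs_series[flow$obs_series$node == pn, ]
    v <- ser$theta[idx] + stats::rnorm(length(idx), 0,
                                       truth$noise$moisture_sd)
    obs_list[[pn]] <- data.frame(
      group = paste0("moisture_", sub("^is_", "", pn)),
      time_d = grid[idx], value = v,
      sigma = max(truth$noise$moisture_sd, 1e-4))
  }
  if (!is.null(tr)) {
    wk <- influent$time_d + 7
    wk <- wk[wk <= t_end + 1e-9]
    eff_at <- function(col) {
      vapply(wk, function(t) {
        sel <- tr$effluent$time_d <= t & tr$effluent$time_d > t - 7 &
          tr$effluent$q_out > 0
        if (!any(sel)) NA_real_ else mean(tr$effluent[[col]][sel])
      }, numeric(1))
    }
    sdlog <- sqrt(log(1 + truth$noise$conc_cv^2))
    for (sp in c("NH4", "NO3")) {
      v <- eff_at(paste0("C_", sp))
      keep <- is.finite(v)
      noisy <- v[keep] * exp(stats::rnorm(sum(keep), -sdlog^2 / 2, sdlog))
      obs_list[[paste0("eff_", sp)]] <- data.frame(
        group = paste0("effluent_", sp), time_d = wk[keep], value = noisy,
        sigma = pmax(truth$noise$conc_cv * pmax(v[keep], 1e-6), 1e-3))
    }
  }
  obs <- observation_set(do.call(rbind, obs_list))
  rownames(obs) <- NULL
  structure(list(obs = obs, influent = influent, flow = flow,
                 transport = tr, truth = truth, domain = domain),
            class = "synthetic_observations")
}
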