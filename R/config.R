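#' @keywords internal
#' @aliases drainfieldN-package
#' @useDynLib drainfieldN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

config_schema <- function() {
  list(
    system = NULL,
    seed = NULL,
    geometry = c("width", "height", "is_depth", "dose_width", "axisym",
                 "obs_depths"),
    materials = NA,  # free-form named list, validated per material
    schedule = c("volume_mL", "duration_min", "period_min", "source"),
    flow = c("t_end", "h_init", "h_crit_min", "dt_max", "store_dt",
             "avg_window", "tol_h", "tol_theta", "face_weight"),
    transport = c("temperature", "dispersion", "enabled"),
    influent = c("mean", "sd", "source", "TN"),
    scenario = c("temperature", "water_table_rise", "label"),
    kinetics = c("Topt", "beta", "alpha_c", "Km")
  )
}

material_keys <- c("vg", "rho_b", "lambda_L", "lambda_T", "Kd", "D_free")
vg_keys <- c("theta_r", "theta_s", "alpha", "n", "l", "Ks")

reject_unknown <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("config: unknown key '%s' in %s (expected one of: %s)",
                 bad[1], where, paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
}

#' Validate a run configuration and inject defaults
#'
#' Checks the configuration against the schema (unknown keys are
#' rejected, naming the offending key), validates every material block by
#' constructing its parameter objects (so e.g. `theta_r >= theta_s` is a
#' validation error), and injects the standard defaults: pore
#' connectivity `l = 0.5`, initial pressure head -50 cm, minimum
#' permissible pressure -1000 cm, 90-day simulation, 20 C soil
#' temperature.
#'
#' @param cfg A configuration list (typically from [load_config()]).
#' @return The validated configuration with defaults filled in.
#' @export
validate_config <- function(cfg) {
  schema <- config_schema()
  reject_unknown(cfg, names(schema), "top level")
  if (is.null(cfg$system)) cfg$system <- "PSND"
  if (!cfg$system %in% c("PSND", "GEO", "P&S")) {
    stop(sprintf("config: unknown system '%s'", cfg$system), call. = FALSE)
  }
  for (sec in c("geometry", "schedule", "flow", "transport", "influent",
                "scenario", "kinetics")) {
    if (!is.null(cfg[[sec]])) {
      reject_unknown(cfg[[sec]], schema[[sec]], sec)
    } else {
      cfg[[sec]] <- list()
    }
  }
  if (!is.null(cfg$materials)) {
    for (nm in names(cfg$materials)) {
      m <- cfg$materials[[nm]]
      reject_unknown(m, material_keys, sprintf("materials$%s", nm))
      if (is.null(m$vg)) {
        stop(sprintf("config: materials$%s needs a vg block", nm),
             call. = FALSE)
      }
      reject_unknown(m$vg, vg_keys, sprintf("materials$%s$vg", nm))
      v <- m$vg
      # constructing validates (theta_r < theta_s, n > 1, ...)
      vg_params(v$theta_r, v$theta_s, v$alpha, v$n, v$l %||% 0.5, v$Ks)
      cfg$materials[[nm]]$vg$l <- v$l %||% 0.5
    }
  }
  flow_def <- list(t_end = 90, h_init = -50, h_crit_min = -1000)
  for (k in names(flow_def)) {
    cfg$flow[[k]] <- cfg$flow[[k]] %||% flow_def[[k]]
  }
  cfg$transport$temperature <- cfg$transport$temperature %||% 20
  cfg$transport$enabled <- cfg$transport$enabled %||% TRUE
  cfg$scenario$temperature <- cfg$scenario$temperature %||% 20
  cfg$scenario$water_table_rise <- cfg$scenario$water_table_rise %||% 0
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

#' Load (and validate) a YAML run configuration
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list (see [validate_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  validate_config(yaml::read_yaml(path))
}

#' Write a configuration back to YAML
#'
#' Round-trips with [load_config()]: loading a dumped configuration
#' yields an identical object.
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Hash of the semantically meaningful configuration content
#'
#' FNV-1a hash over the canonical serialized configuration (stable across
#' sessions); changes iff a meaningful field changes.
#'
#' @param cfg Configuration list.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  s <- paste(deparse(canon(cfg)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor into the low 16 bits (codepoints stay within them after %% )
    lo16 <- h %% 65536
    h <- h - lo16 + bitwXor(as.integer(lo16), as.integer(b %% 65536))
    # 32-bit modular multiply by the FNV prime without double overflow
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_domain <- function(cfg) {
  ov <- cfg$geometry
  if (!is.null(cfg$materials)) {
    mats <- lapply(names(cfg$materials), function(nm) {
      m <- cfg$materials[[nm]]
      v <- m$vg
      material_zone(nm,
                    vg_params(v$theta_r, v$theta_s, v$alpha, v$n,
                              v$l %||% 0.5, v$Ks),
                    rho_b = m$rho_b %||% 1.5,
                    lambda_L = m$lambda_L %||% 10,
                    lambda_T = m$lambda_T %||% 1,
                    Kd = m$Kd %||% 0)
    })
    names(mats) <- names(cfg$materials)
    dom <- build_mesocosm(cfg$system, overrides = c(ov,
                                                    list(materials = mats)))
  } else {
    dom <- build_mesocosm(cfg$system, overrides = ov)
  }
  if (cfg$scenario$water_table_rise > 0) {
    dom <- raise_water_table(dom, cfg$scenario$water_table_rise)
  }
  dom
}

#' Run the modeling pipeline from a configuration
#'
#' Executes the requested stages (`flow`, then optionally `transport`,
#' then optionally `scenario` deltas against the configured baseline),
#' writes CSV/JSON/VTK outputs and a run manifest (configuration hash,
#' package version, seed, timestamps, file inventory) into `out_dir`.
#' Stage dependencies are enforced: transport requires flow, scenario
#' requires transport. All randomness derives from the single manifest
#' seed; reruns with the same seed reproduce the outputs.
#'
#' @param cfg Validated configuration (see [load_config()]).
#' @param stages Subset of `c("flow", "transport", "scenario")`.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `cfg$seed`.
#' @return List with the stage results and the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("flow", "transport"),
                         out_dir, seed = NULL) {
  cfg <- validate_config(cfg)
  stages <- match.arg(stages, c("flow", "transport", "scenario"),
                      several.ok = TRUE)
  if ("transport" %in% stages && !"flow" %in% stages) {
    stop("stage dependency: transport requires flow", call. = FALSE)
  }
  if ("scenario" %in% stages && !"transport" %in% stages) {
    stop("stage dependency: scenario requires transport", call. = FALSE)
  }
  seed <- as.integer(seed %||% cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }

  domain <- config_domain(cfg)
  fcfg <- do.call(flow_config, cfg$flow)
  fcfg$store_fluxes <- "transport" %in% stages
  sched <- if (length(cfg$schedule)) {
    dosing_schedule(cfg$schedule$volume_mL, cfg$schedule$duration_min,
                    cfg$schedule$period_min,
                    cfg$schedule$source %||% "ATE")
  } else default_schedule(cfg$system)

  flow <- solve_flow(domain, sched, fcfg)
  emit(flow$obs_series, "flow_obs.csv")
  emit(data.frame(time_d = flow$times[-1], seep_q = flow$seep_series),
       "seepage.csv")
  export_vtk(domain, list(theta_avg = flow$theta_avg,
                          h_avg = flow$h_avg),
             file.path(out_dir, "fields.vtk"))
  files <- c(files, "fields.vtk")
  results <- list(flow = flow)
  message(sprintf("flow: closure %.4g%% of inflow",
                  100 * flow$water_balance_raw$closure_rel))

  if ("transport" %in% stages) {
    kin <- do.call(drainfield_kinetics, c(list(cfg$system), cfg$kinetics))
    n_weeks <- max(1L, ceiling(fcfg$t_end / 7))
    infl <- if (!is.null(cfg$influent$TN)) {
      list(TN = cfg$influent$TN,
           source = cfg$influent$source %||% sched$source)
    } else {
      stats <- influent_defaults(cfg$influent$source %||% sched$source)
      if (!is.null(cfg$influent$mean)) stats$mean <- cfg$influent$mean
      if (!is.null(cfg$influent$sd)) stats$sd <- cfg$influent$sd
      generate_influent_series(stats, n_weeks, seed)
    }
    tr <- solve_transport(flow, domain, kin, infl,
                          T_C = cfg$transport$temperature)
    emit(tr$effluent, "effluent.csv")
    mb <- nitrogen_mass_balance(tr)
    jsonlite::write_json(unclass(mb), file.path(out_dir,
                                                "mass_balance.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "mass_balance.json")
    results$transport <- tr
    results$mass_balance <- mb
    message(sprintf("N balance closure: %+.4g%% of input", mb$closure))

    if ("scenario" %in% stages) {
      s <- scenario(cfg$scenario$temperature,
                    cfg$scenario$water_table_rise,
                    cfg$scenario$label)
      dom_s <- raise_water_table(domain, s$water_table_rise)
      flow_s <- if (s$water_table_rise > 0) {
        solve_flow(dom_s, sched, fcfg)
      } else flow
      tr_s <- solve_transport(flow_s, dom_s, kin, infl,
                              T_C = s$temperature)
      delta <- compare_runs(tr, tr_s)
      jsonlite::write_json(unclass(delta),
                           file.path(out_dir, "scenario_delta.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, "scenario_delta.json")
      emit(tr_s$effluent, "effluent_scenario.csv")
      results$scenario <- tr_s
      results$delta <- delta
    }
  }

  manifest <- list(package = "drainfieldN",
                   version = as.character(utils::packageVersion("drainfieldN")),
                   config_hash = config_hash(cfg), seed = seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = stages, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  results$manifest <- manifest
  invisible(results)
}
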