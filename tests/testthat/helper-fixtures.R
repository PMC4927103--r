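# shared fixtures: calibrated parameter sets and small verification domains

psnd_loam <- function() vg_params(0.025, 0.203, 0.0847, 2.289, Ks = 220.02)
psnd_sand <- function() vg_params(0.013, 0.063, 0.0205, 4.037, Ks = 908.88)
ps_sand <- function() vg_params(0.012, 0.068, 0.0838, 3.731, Ks = 4.513)

# hydraulic loading: 2 L/d over a 15-cm-ID column cross-section
q_hlr <- function() 2000 / (pi * 7.5^2)

fitted_nit <- function(mu_max = 1) nitrification_params(mu_max)
fitted_denit <- function(mu_max = 1) denitrification_params(mu_max)

# small homogeneous sand column with bottom seepage, cheap to solve
sand_column <- function(height = 100, dz = 2, nx = 1,
                        material = psnd_sand()) {
  column_domain(material, height = height, dz = dz, nx = nx)
}

# cache expensive runs across test files within one suite run
run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(run_cache[[key]])) run_cache[[key]] <- force(expr)
  run_cache[[key]]
}

# unit-gradient moisture surrogate of a PSND-like two-layer profile:
# steady probe readings at 15 cm (silt loam) and 30 cm (sand) below the IS
# under a set of hydraulic loading rates (a multi-rate drainage experiment;
# a single rate leaves the retention parameters unidentifiable)
ug_surrogate <- function(n_rep = 4, rates = c(2, 11.32, 40, 90)) {
  fwd <- function(p) {
    loam <- vg_params(p[["th_rs"]], p[["th_ss"]], p[["alpha_s"]],
                      p[["n_s"]], Ks = p[["Ks_s"]])
    sand <- vg_params(p[["th_rg"]], p[["th_sg"]], p[["alpha_g"]],
                      p[["n_g"]], Ks = p[["Ks_g"]])
    th <- function(mat) vapply(rates, function(q)
      unit_gradient_state(q, mat)$theta, numeric(1))
    c(rep(th(loam), n_rep), rep(th(sand), n_rep))
  }
  truth <- c(th_rs = 0.025, th_ss = 0.203, alpha_s = 0.0847, n_s = 2.289,
             Ks_s = 220.02, th_rg = 0.013, th_sg = 0.063,
             alpha_g = 0.0205, n_g = 4.037, Ks_g = 908.88)
  nr <- n_rep * length(rates)
  obs <- observation_set(data.frame(
    group = rep(c("moisture_15cm", "moisture_30cm"), each = nr),
    time_d = rep(seq_len(nr), 2), value = fwd(truth), sigma = 0.005))
  list(fwd = fwd, truth = truth, obs = obs)
}

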