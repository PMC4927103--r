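coarse_mesh <- function() {
  list(dz = rep(137 / 46, 46), dx = rep(7.5, 2))
}

test_that("influent generator is deterministic and honours its statistics", {
  s0 <- generate_influent_series(list(mean = 60, sd = 0, source = "STE"),
                                 n_weeks = 8, seed = 5)
  expect_true(all(s0$TN == 60))
  expect_true(all(s0$C_NH4 == 60))  # STE: fully mineralized to NH4
  a <- generate_influent_series(influent_defaults("ATE"), 12, seed = 9)
  b <- generate_influent_series(influent_defaults("ATE"), 12, seed = 9)
  expect_identical(a, b)
  c2 <- generate_influent_series(influent_defaults("ATE"), 12, seed = 10)
  expect_false(identical(a, c2))
  # sample mean within two standard errors of the target
  big <- generate_influent_series(list(mean = 60, sd = 6, source = "STE"),
                                  n_weeks = 200, seed = 1)
  expect_lt(abs(mean(big$TN) - 60), 2 * 6 / sqrt(200))
  expect_true(all(big$TN >= 0))
  expect_error(generate_influent_series(list(mean = 60, sd = -1,
                                             source = "STE"), 5),
               ">= 0")
  expect_error(generate_influent_series(influent_defaults("STE"), 0),
               "n_weeks")
})

test_that("zero-noise observations equal the forward model at the sample times", {
  truth <- synthetic_truth("PSND", noise = list(moisture_sd = 0,
                                                conc_cv = 0), seed = 3)
  syn <- generate_mesocosm_observations(truth, t_end = 3, sample_dt = 0.25,
                                        overrides = coarse_mesh())
  m15 <- syn$obs[syn$obs$group == "moisture_15cm", ]
  fser <- syn$flow$obs_series
  fser <- fser[fser$node == "is_15cm", ]
  ref <- fser$theta[match(m15$time_d, fser$time_d)]
  expect_equal(m15$value, ref, tolerance = 1e-12)
})

test_that("moisture noise is recovered in the observation residuals", {
  sd_true <- 0.005
  truth0 <- synthetic_truth("PSND", noise = list(moisture_sd = 0,
                                                 conc_cv = 0), seed = 8)
  truth1 <- synthetic_truth("PSND", noise = list(moisture_sd = sd_true,
                                                 conc_cv = 0), seed = 8)
  cfg <- flow_config(store_dt = 0.02)
  clean <- generate_mesocosm_observations(truth0, t_end = 6,
                                          sample_dt = 0.02,
                                          overrides = coarse_mesh(),
                                          cfg = cfg)
  noisy <- generate_mesocosm_observations(truth1, t_end = 6,
                                          sample_dt = 0.02,
                                          overrides = coarse_mesh(),
                                          cfg = cfg)
  res <- noisy$obs$value - clean$obs$value
  expect_gte(length(res), 500)
  expect_equal(sd(res), sd_true, tolerance = 0.15)
})

test_that("replicate seeds give distinct observation sets from one truth", {
  obs <- lapply(1:3, function(s) {
    truth <- synthetic_truth("PSND", seed = s)
    generate_mesocosm_observations(truth, t_end = 2, sample_dt = 0.5,
                                   overrides = coarse_mesh())$obs
  })
  expect_false(identical(obs[[1]]$value, obs[[2]]$value))
  expect_false(identical(obs[[2]]$value, obs[[3]]$value))
  # identical structure: same groups and sample times
  expect_identical(obs[[1]]$time_d, obs[[2]]$time_d)
  expect_identical(obs[[1]]$group, obs[[3]]$group)
})

test_that("baseline synthetic effluent is nitrate-dominated (chain direction)", {
  truth <- synthetic_truth("PSND", kinetics = drainfield_kinetics("PSND"),
                           seed = 4)
  syn <- generate_mesocosm_observations(truth, t_end = 8, sample_dt = 0.5,
                                        overrides = coarse_mesh())
  eff <- syn$transport$effluent
  late <- eff[eff$time_d > 4 & eff$q_out > 0, ]
  expect_gt(mean(late$C_NO3, na.rm = TRUE), mean(late$C_NH4, na.rm = TRUE))
})

test_that("end-to-end fit on zero-noise synthetic data recovers the truth", {
  truth <- synthetic_truth("PSND", noise = list(moisture_sd = 0,
                                                conc_cv = 0), seed = 12)
  syn <- generate_mesocosm_observations(truth, t_end = 3, sample_dt = 0.5,
                                        overrides = coarse_mesh())
  obs <- syn$obs
  true_ths <- truth$hydraulics$silt_loam$theta_s
  model <- function(p) {
    hyd <- truth$hydraulics
    hyd$silt_loam <- vg_params(hyd$silt_loam$theta_r, p[["th_ss"]],
                               hyd$silt_loam$alpha, hyd$silt_loam$n,
                               Ks = hyd$silt_loam$Ks)
    t2 <- synthetic_truth("PSND", hydraulics = hyd,
                          noise = list(moisture_sd = 0, conc_cv = 0),
                          seed = 12)
    s2 <- generate_mesocosm_observations(t2, t_end = 3, sample_dt = 0.5,
                                         overrides = coarse_mesh())
    s2$obs$value
  }
  fit <- gauss_newton_fit(model, obs, init = c(th_ss = true_ths * 1.15),
                          lower = 0.1, upper = 0.35, tol = 1e-6)
  expect_lt(abs(fit$par[["th_ss"]] - true_ths) / true_ths, 1e-3)
})
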