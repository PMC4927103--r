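test_that("the weighted objective behaves as a weighted sum of squares", {
  obs <- observation_set(data.frame(group = "g", time_d = 1:3,
                                    value = c(1, 2, 3), sigma = 1))
  model_exact <- function(p) c(1, 2, 3)
  expect_equal(weighted_sse(c(a = 0), model_exact, obs), 0)
  model_off <- function(p) c(3, 2, 3)  # one residual of 2
  expect_equal(weighted_sse(c(a = 0), model_off, obs), 4)
  obs2 <- obs
  obs2$weight <- obs$weight * 2
  expect_equal(weighted_sse(c(a = 0), model_off, obs2), 8)  # linear in w
})

test_that("rmse satisfies its defining identities", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3) + 0.7, c(1, 2, 3)), 0.7)
  expect_equal(rmse(c(1, -1, 1, -1), c(0, 0, 0, 0)), 1)
  expect_error(rmse(1:3, 1:4), "lengths differ")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("undamped Gauss-Newton solves a linear model in one accepted step", {
  set.seed(3)
  X <- cbind(1, seq(0, 1, length.out = 12), runif(12))
  beta <- c(2, -1, 0.5)
  obs <- observation_set(data.frame(group = "y", time_d = 1:12,
                                    value = drop(X %*% beta), sigma = 0.1))
  model <- function(p) drop(X %*% p)
  fit <- gauss_newton_fit(model, obs, init = c(b0 = 0, b1 = 0, b2 = 0),
                          lambda0 = 0)
  # first accepted step is already the least-squares minimizer
  expect_lt(fit$trajectory[2] / fit$trajectory[1], 1e-12)
  expect_equal(unname(fit$par), beta, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("noiseless synthetic observations are recovered to within 0.1%", {
  sg <- ug_surrogate()
  free <- c("th_ss", "n_s", "th_sg", "n_g")
  model <- function(p) {
    full <- sg$truth
    full[free] <- p
    sg$fwd(full)
  }
  init <- sg$truth[free] * c(1.2, 0.9, 1.25, 1.1)
  fit <- gauss_newton_fit(model, sg$obs, init = init,
                          lower = sg$truth[free] * 0.5,
                          upper = sg$truth[free] * 2, tol = 1e-8)
  expect_lt(fit$objective / weighted_sse(init, model, sg$obs), 1e-8)
  expect_equal(unname(fit$par), unname(sg$truth[free]), tolerance = 1e-3)
  expect_lt(max(abs(fit$par - sg$truth[free]) / sg$truth[free]), 1e-3)
})

test_that("a ten-parameter two-layer fit converges after CSS screening", {
  sg <- ug_surrogate()
  # attempting all ten parameters is correctly refused: the air-entry
  # parameters carry no information in this experiment
  expect_error(gauss_newton_fit(sg$fwd, sg$obs, init = sg$truth * 1.05,
                                lambda0 = 0),
               "unidentifiable.*alpha")
  # screen by CSS ratio < 0.01, then fit the remaining eight simultaneously
  css <- composite_scaled_sensitivity(sg$fwd, sg$truth, sg$obs)
  free <- names(css$css)[!css$excluded]
  expect_setequal(setdiff(names(sg$truth), free), c("alpha_s", "alpha_g"))
  model <- function(p) {
    full <- sg$truth
    full[free] <- p
    sg$fwd(full)
  }
  set.seed(11)
  noisy <- sg$obs
  noisy$value <- noisy$value + rnorm(nrow(noisy), 0, 0.002)
  init <- sg$truth[free] * runif(length(free), 0.9, 1.1)
  fit <- gauss_newton_fit(model, noisy, init = init,
                          lower = sg$truth[free] * 0.5,
                          upper = sg$truth[free] * 2, max_iter = 40)
  expect_true(fit$converged)
  expect_lt(fit$objective, weighted_sse(init, model, noisy))
  # the information-rich parameters are recovered despite the noise
  expect_equal(fit$par[["th_ss"]], 0.203, tolerance = 0.05)
})

test_that("parameter recovery with replicate noisy data stays within its uncertainty", {
  sg <- ug_surrogate(n_rep = 3)
  model <- function(p) {
    full <- sg$truth
    full["th_ss"] <- p
    sg$fwd(full)
  }
  set.seed(21)
  ests <- vapply(1:3, function(rep) {
    noisy <- sg$obs
    noisy$value <- noisy$value * (1 + rnorm(nrow(noisy), 0, 0.05))
    fit <- gauss_newton_fit(model, noisy, init = c(th_ss = 0.25),
                            lower = 0.1, upper = 0.4, tol = 1e-6)
    fit$par[["th_ss"]]
  }, numeric(1))
  # 5% multiplicative noise on theta ~ 5% on theta_s at Se ~ 0.6
  expect_lt(abs(mean(ests) - 0.203), 2 * sd(ests) + 0.01)
})

test_that("composite scaled sensitivities flag inert parameters and rank theta_ss first", {
  sg <- ug_surrogate()
  # an inert parameter with no model influence gets CSS exactly 0
  fwd2 <- function(p) sg$fwd(p[names(sg$truth)])
  pars <- c(sg$truth, dead = 1)
  css <- composite_scaled_sensitivity(fwd2, pars, sg$obs)
  expect_equal(css$css[["dead"]], 0)
  expect_true(css$excluded[["dead"]])
  expect_equal(max(css$ratio), 1)
  # saturated water content of the upper soil carries the most information
  expect_equal(names(which.max(css$css)), "th_ss")
  expect_equal(css$ratio[["th_ss"]], 1)
  # alpha does not affect the steady unit-gradient moisture: screened out
  expect_true(css$excluded[["alpha_s"]])
  expect_true(css$excluded[["alpha_g"]])
})

test_that("CSS is invariant to observation rescaling when weights follow 1/sigma^2", {
  sg <- ug_surrogate()
  css1 <- composite_scaled_sensitivity(sg$fwd, sg$truth, sg$obs)
  # express moisture in percent: values x100, sigma x100, model x100
  obs2 <- sg$obs
  obs2$value <- obs2$value * 100
  obs2$weight <- obs2$weight / 100^2
  fwd2 <- function(p) sg$fwd(p) * 100
  css2 <- composite_scaled_sensitivity(fwd2, sg$truth, obs2)
  expect_equal(css1$css, css2$css, tolerance = 1e-8)
})

test_that("degenerate calibration inputs raise informative errors", {
  obs1 <- observation_set(data.frame(group = "g", time_d = 1,
                                     value = 1, sigma = 1))
  expect_error(gauss_newton_fit(function(p) p[1], obs1,
                                init = c(a = 1, b = 2)),
               "fewer observations")
  expect_error(observation_set(data.frame(group = "g", time_d = 1,
                                          value = 1)),
               "sigma or weight")
  expect_error(observation_set(data.frame(group = "g", time_d = 1,
                                          value = 1, sigma = 0)),
               "sigma must be")
})
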