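test_that("nitrification water-content response has the fitted three-branch shape", {
  p <- fitted_nit()
  # optimal plateau between the fitted breakpoints
  expect_equal(fsw_nitrification(0.74, p), 1)
  expect_equal(fsw_nitrification(0.665 + 1e-9, p), 1, tolerance = 1e-6)
  # saturated endpoint shuts nitrification off (fs = 0)
  expect_equal(fsw_nitrification(1, p), 0)
  # at and below the wilting point
  expect_equal(fsw_nitrification(0.154, p), 0)
  expect_equal(fsw_nitrification(0.05, p), 0)
  # dry branch: direct scalar evaluation
  expect_equal(fsw_nitrification(0.40, p),
               ((0.40 - 0.154) / (0.665 - 0.154))^1.104,
               tolerance = 1e-12)
  expect_equal(fsw_nitrification(0.40, p), 0.446165191, tolerance = 1e-8)
  expect_error(fsw_nitrification(1.2, p), "\\[0, 1\\]")
})

test_that("nitrification response is continuous at the breakpoints", {
  p <- fitted_nit()
  eps <- 1e-10
  expect_equal(fsw_nitrification(p$sl - eps, p),
               fsw_nitrification(p$sl + eps, p), tolerance = 1e-6)
  expect_equal(fsw_nitrification(p$sh - eps, p),
               fsw_nitrification(p$sh + eps, p), tolerance = 1e-6)
})

test_that("denitrification water-content response is the fitted threshold power law", {
  p <- fitted_denit()  # sdn = 0, f = 2.86
  expect_equal(fsw_denitrification(1, p), 1)
  expect_equal(fsw_denitrification(0.5, p), 0.5^2.86, tolerance = 1e-12)
  expect_equal(fsw_denitrification(0.5, p), 0.137738139, tolerance = 1e-8)
  p2 <- denitrification_params(1, sdn = 0.3)
  expect_equal(fsw_denitrification(0.2, p2), 0)
  expect_equal(fsw_denitrification(0.3, p2), 0)
  expect_equal(fsw_denitrification(1, p2), 1)
})

test_that("temperature response peaks at the optimum and is symmetric", {
  expect_equal(f_temperature(25, 25, 0.3), 1)
  expect_equal(f_temperature(12.3, 12.3, 1.7), 1)
  expect_equal(f_temperature(c(5, 18, 40), 20, 0), rep(1, 3))
  # frozen independent evaluation of the exponent
  expect_equal(f_temperature(20, 25, 0.05), 0.97530991, tolerance = 1e-8)
  # symmetry about the optimum: f(T) = f(2 Topt - T)
  expect_equal(f_temperature(20, 25, 0.05), f_temperature(30, 25, 0.05))
  # monotone up below Topt, down above
  Tlo <- seq(1, 25, by = 0.5)
  expect_true(all(diff(f_temperature(Tlo, 25, 0.1)) > 0))
  Thi <- seq(25, 60, by = 0.5)
  expect_true(all(diff(f_temperature(Thi, 25, 0.1)) < 0))
})

test_that("carbon availability decays exponentially with depth", {
  expect_equal(f_carbon_depth(0, 0.02), 1)
  expect_equal(f_carbon_depth(c(5, 50, 500), 0), rep(1, 3))
  expect_equal(f_carbon_depth(log(2) / 0.02, 0.02), 0.5)
  expect_error(f_carbon_depth(-1, 0.02), ">= 0")
})

test_that("rate laws follow Michaelis-Menten with the dependency factors", {
  nit <- nitrification_params(40, Km = 5, Topt = 25, beta = 0.1)
  # half-saturation: at C = Km with all factors 1 the rate is mu_max / 2
  expect_equal(nitrification_rate(5, 0.7, 25, nit), 20)
  expect_equal(nitrification_rate(0, 0.7, 25, nit), 0)
  # zero-order limit at high substrate
  expect_equal(nitrification_rate(5000, 0.7, 25, nit), 40,
               tolerance = 1e-3)
  expect_true(nitrification_rate(5000, 0.7, 25, nit) <= nit$mu_max)

  den <- denitrification_params(2, Km = 5, Topt = 25, beta = 0.1)
  expect_equal(denitrification_rate(5, 1, 25, 0, den), 1)
  expect_equal(denitrification_rate(5000, 1, 25, 0, den), 2,
               tolerance = 1e-3)
  den2 <- denitrification_params(2, sdn = 0.4, Topt = 25, beta = 0.1)
  expect_equal(denitrification_rate(100, 0.2, 25, 0, den2), 0)
})

test_that("dependency factors stay in [0,1] over the admissible parameter box", {
  set.seed(42)
  for (rep in 1:200) {
    br <- sort(runif(3))
    p <- nitrification_params(1, fs = runif(1), fwp = runif(1),
                              swp = br[1], sl = br[2], sh = br[3],
                              e1 = runif(1, 0.5, 4), e2 = runif(1, 0.5, 4),
                              Topt = runif(1, 15, 30),
                              beta = runif(1, 0, 1))
    d <- denitrification_params(1, sdn = runif(1), f_exp = runif(1, 0.5, 4),
                                alpha_c = runif(1, 0, 0.1))
    S <- runif(8)
    expect_true(all(fsw_nitrification(S, p) >= 0 &
                    fsw_nitrification(S, p) <= 1))
    expect_true(all(fsw_denitrification(S, d) >= 0 &
                    fsw_denitrification(S, d) <= 1))
    Tv <- runif(4, 0.1, 45)
    expect_true(all(f_temperature(Tv, p$Topt, p$beta) > 0 &
                    f_temperature(Tv, p$Topt, p$beta) <= 1 + 1e-12))
  }
})

test_that("rates are non-decreasing in substrate concentration", {
  nit <- nitrification_params(40)
  den <- denitrification_params(2)
  C <- seq(0, 200, by = 2)
  expect_true(all(diff(nitrification_rate(C, 0.7, 20, nit)) >= 0))
  expect_true(all(diff(denitrification_rate(C, 0.9, 20, 10, den)) >= 0))
})

test_that("warming towards the optimum raises both transformation rates", {
  nit <- nitrification_params(40, Topt = 25, beta = 0.2)
  den <- denitrification_params(2, Topt = 25, beta = 0.2)
  expect_gt(nitrification_rate(50, 0.7, 23, nit),
            nitrification_rate(50, 0.7, 20, nit))
  expect_gt(denitrification_rate(50, 0.9, 23, 5, den),
            denitrification_rate(50, 0.9, 20, 5, den))
})

test_that("influent speciation follows the effluent-type composition", {
  expect_equal(unlist(speciate_influent(0, "STE")), c(C_NH4 = 0, C_NO3 = 0,
                                                      C_inert = 0))
  ate <- speciate_influent(100, "ATE")
  expect_equal(ate$C_NH4, 44)  # 18% organic N mineralized + 26% NH4
  expect_equal(ate$C_NO3, 56)
  ste <- speciate_influent(60, "STE")
  expect_equal(ste$C_NH4, 60)  # full mineralization of organic N
  expect_equal(ste$C_NO3, 0)
  expect_error(speciate_influent(10, "XYZ"))
  # recalcitrant organic N passes through untransformed
  r <- speciate_influent(100, "STE", recalcitrant = 0.5)
  expect_equal(r$C_NH4 + r$C_NO3 + r$C_inert, 100)
  expect_equal(r$C_inert, 10)
})

test_that("mu_max back-calculation inverts the effective zero-order rate", {
  nit <- nitrification_params(1, Topt = 22.5, beta = 0.177)
  mu <- mu_max_from_rate(45.25, S_ref = 0.64, T_ref = 20, p = nit)
  got <- nitrification_params(mu, Topt = 22.5, beta = 0.177)
  expect_equal(nitrification_rate(1e6, 0.64, 20, got), 45.25,
               tolerance = 1e-5)
  den <- denitrification_params(1, alpha_c = 0.02)
  mu_d <- mu_max_from_rate(1.31, S_ref = 0.41, z_ref = 58.5, p = den)
  got_d <- denitrification_params(mu_d, alpha_c = 0.02)
  expect_equal(denitrification_rate(1e6, 0.41, 20, 58.5, got_d), 1.31,
               tolerance = 1e-5)
  # unbounded mu_max is refused rather than silently huge
  expect_error(mu_max_from_rate(1, S_ref = 1, p = nit), "unbounded")
})

test_that("the rate table spans the grid and peaks inside the optimal band", {
  nit <- nitrification_params(40, Topt = 25, beta = 0.1)
  den <- denitrification_params(2, Topt = 25, beta = 0.1)
  tab <- kinetics_table(nit, den, S = seq(0, 1, 0.25), T_C = c(20, 25))
  expect_equal(nrow(tab), 10)
  best <- tab[which.max(tab$nitrification), ]
  expect_equal(best$T_C, 25)
  expect_true(best$S > 0.665 - 0.01 && best$S <= 0.809 + 0.01)
  expect_equal(max(tab$denitrification), 2 * 1, tolerance = 1e-3)
})
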