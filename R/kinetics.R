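#' Nitrification kinetic parameters
#'
#' Michaelis-Menten nitrification with a piecewise water-content dependency
#' (DRAINMOD-N2 form) and a bell-shaped temperature response. The default
#' water-content breakpoints and exponents are the fitted median values of
#' the mesocosm calibration (`f_wp = 0`, `f_s = 0`, `s_wp = 0.154`,
#' `s_l = 0.665`, `s_h = 0.809`, `e1 = 2.267`, `e2 = 1.104`).
#'
#' @param mu_max Maximum nitrification rate (mg N L^-1 d^-1, pore water).
#' @param Km NH4-N half-saturation constant (mg N L^-1).
#' @param fs Value of the dependency function at full saturation.
#' @param fwp Value at the wilting point.
#' @param swp,sl,sh Saturation breakpoints: wilting point, lower and upper
#'   bound of the optimal range; `0 <= swp < sl < sh <= 1`.
#' @param e1,e2 Shape exponents of the wet and dry branches.
#' @param Topt Optimum temperature (degrees C).
#' @param beta Temperature-response shape parameter (dimensionless).
#' @return An object of class `nitrification_params`.
#' @export
nitrification_params <- function(mu_max, Km = 5, fs = 0, fwp = 0,
                                 swp = 0.154, sl = 0.665, sh = 0.809,
                                 e1 = 2.267, e2 = 1.104,
                                 Topt = 22.5, beta = 0.177) {
  if (mu_max < 0) stop("mu_max must be >= 0", call. = FALSE)
  if (Km <= 0) stop("Km must be > 0", call. = FALSE)
  if (fs < 0 || fs > 1 || fwp < 0 || fwp > 1) {
    stop("fs and fwp must lie in [0, 1]", call. = FALSE)
  }
  if (!(swp >= 0 && swp < sl && sl < sh && sh <= 1)) {
    stop("need 0 <= swp < sl < sh <= 1", call. = FALSE)
  }
  if (Topt <= 0) stop("Topt must be > 0", call. = FALSE)
  structure(list(mu_max = mu_max, Km = Km, fs = fs, fwp = fwp, swp = swp,
                 sl = sl, sh = sh, e1 = e1, e2 = e2, Topt = Topt,
                 beta = beta),
            class = "nitrification_params")
}

#' Denitrification kinetic parameters
#'
#' Michaelis-Menten denitrification with a threshold water-content response
#' (`fsw = ((S - s_dn)/(1 - s_dn))^f` above the threshold), the same
#' temperature response as nitrification, and an exponential carbon-depth
#' decay `exp(-alpha_c * z)` representing declining organic carbon below the
#' infiltrative surface. Defaults use the fitted `s_dn = 0`, `f = 2.86`.
#'
#' @param mu_max Maximum denitrification rate (mg N L^-1 d^-1, pore water).
#' @param Km NO3-N half-saturation constant (mg N L^-1).
#' @param sdn Threshold saturation below which denitrification stops.
#' @param f_exp Shape exponent of the saturation response.
#' @param alpha_c Carbon depth-decay coefficient (cm^-1).
#' @param Topt Optimum temperature (degrees C).
#' @param beta Temperature-response shape parameter.
#' @return An object of class `denitrification_params`.
#' @export
denitrification_params <- function(mu_max, Km = 5, sdn = 0, f_exp = 2.86,
                                   alpha_c = 0.02, Topt = 22.5,
                                   beta = 0.177) {
  if (mu_max < 0) stop("mu_max must be >= 0", call. = FALSE)
  if (Km <= 0) stop("Km must be > 0", call. = FALSE)
  if (sdn < 0 || sdn > 1) stop("sdn must lie in [0, 1]", call. = FALSE)
  if (f_exp <= 0) stop("f_exp must be > 0", call. = FALSE)
  if (alpha_c < 0) stop("alpha_c must be >= 0", call. = FALSE)
  if (Topt <= 0) stop("Topt must be > 0", call. = FALSE)
  structure(list(mu_max = mu_max, Km = Km, sdn = sdn, f_exp = f_exp,
                 alpha_c = alpha_c, Topt = Topt, beta = beta),
            class = "denitrification_params")
}

check_saturation <- function(S) {
  if (any(!is.finite(S)) || any(S < 0 | S > 1)) {
    stop("saturation S must lie in [0, 1]", call. = FALSE)
  }
  S
}

#' Water-content dependency of nitrification
#'
#' Three-branch piecewise response: rising from `fwp` between the wilting
#' point `swp` and `sl`, optimal (1) on `(sl, sh]`, and falling towards
#' `fs` as the soil approaches saturation (oxygen limitation). Continuous at
#' both interior breakpoints.
#'
#' @param S Saturation (water-filled pore space, theta/theta_s) in `[0, 1]`,
#'   vectorised.
#' @param p A [nitrification_params()] object.
#' @return Dimensionless factor in `[0, 1]`.
#' @export
fsw_nitrification <- function(S, p) {
  check_saturation(S)
  out <- numeric(length(S))
  dry <- S <= p$swp
  low <- S > p$swp & S <= p$sl
  mid <- S > p$sl & S <= p$sh
  wet <- S > p$sh
  out[dry] <- p$fwp
  out[low] <- p$fwp + (1 - p$fwp) * ((S[low] - p$swp) / (p$sl - p$swp))^p$e2
  out[mid] <- 1
  out[wet] <- p$fs + (1 - p$fs) * ((1 - S[wet]) / (1 - p$sh))^p$e1
  out
}

#' Water-content dependency of denitrification
#'
#' Zero below the threshold saturation `sdn`, then
#' `((S - sdn)/(1 - sdn))^f_exp`, reaching 1 at full saturation.
#'
#' @param S Saturation in `[0, 1]`, vectorised.
#' @param p A [denitrification_params()] object.
#' @return Dimensionless factor in `[0, 1]`.
#' @export
fsw_denitrification <- function(S, p) {
  check_saturation(S)
  out <- numeric(length(S))
  hi <- S >= p$sdn
  out[hi] <- ((S[hi] - p$sdn) / (1 - p$sdn))^p$f_exp
  out[S >= 1] <- 1
  out
}

#' Temperature dependency of the transformation rates
#'
#' `f_t = exp(-0.5 beta Topt + beta T (1 - 0.5 T / Topt))`, a bell-shaped
#' response with maximum value 1 at `T = Topt`, symmetric about the optimum.
#'
#' @param T_C Soil temperature (degrees C), vectorised.
#' @param Topt Optimum temperature (degrees C), > 0.
#' @param beta Shape parameter; `beta = 0` gives a flat response of 1.
#' @return Dimensionless factor in `(0, 1]`.
#' @export
f_temperature <- function(T_C, Topt, beta) {
  if (Topt <= 0) stop("Topt must be > 0", call. = FALSE)
  exp(-0.5 * beta * Topt + beta * T_C * (1 - 0.5 * T_C / Topt))
}

#' Carbon-depth dependency of denitrification
#'
#' `f_z = exp(-alpha_c * z)` with `z` the depth below the infiltrative
#' surface; organic carbon supply declines with depth.
#'
#' @param z Depth below the infiltrative surface (cm), `>= 0`, vectorised.
#' @param alpha_c Decay coefficient (cm^-1), `>= 0`.
#' @return Dimensionless factor in `(0, 1]`.
#' @export
f_carbon_depth <- function(z, alpha_c) {
  if (any(z < 0)) stop("z must be >= 0", call. = FALSE)
  if (alpha_c < 0) stop("alpha_c must be >= 0", call. = FALSE)
  exp(-alpha_c * z)
}

#' Nitrification rate
#'
#' `mu = mu_max * C/(Km + C) * f_t(T) * f_sw(S)`. With ample substrate
#' (`C >> Km`) the rate is effectively zero-order at
#' `mu_max * f_t * f_sw`.
#'
#' @param C_NH4 NH4-N concentration (mg N L^-1), `>= 0`, vectorised.
#' @param S Saturation (WFPS) in `[0, 1]`.
#' @param T_C Temperature (degrees C).
#' @param p A [nitrification_params()] object.
#' @return Rate (mg N L^-1 d^-1).
#' @export
nitrification_rate <- function(C_NH4, S, T_C, p) {
  if (any(C_NH4 < 0)) stop("C_NH4 must be >= 0", call. = FALSE)
  p$mu_max * C_NH4 / (p$Km + C_NH4) *
    f_temperature(T_C, p$Topt, p$beta) * fsw_nitrification(S, p)
}

#' Denitrification rate
#'
#' `mu = mu_max * C/(Km + C) * f_t(T) * f_sw_dn(S) * f_z(z)`.
#'
#' @param C_NO3 NO3-N concentration (mg N L^-1), `>= 0`, vectorised.
#' @param S Saturation (WFPS) in `[0, 1]`.
#' @param T_C Temperature (degrees C).
#' @param z Depth below the infiltrative surface (cm), `>= 0`.
#' @param p A [denitrification_params()] object.
#' @return Rate (mg N L^-1 d^-1).
#' @export
denitrification_rate <- function(C_NO3, S, T_C, z, p) {
  if (any(C_NO3 < 0)) stop("C_NO3 must be >= 0", call. = FALSE)
  p$mu_max * C_NO3 / (p$Km + C_NO3) *
    f_temperature(T_C, p$Topt, p$beta) * fsw_denitrification(S, p) *
    f_carbon_depth(z, p$alpha_c)
}

#' Speciate influent total nitrogen
#'
#' Splits an influent total-N concentration into the NH4-N and NO3-N pools
#' dosed to the drainfield, under the convention that influent organic N is
#' mineralized to NH4 before entering the soil. Septic tank effluent (STE)
#' is therefore dosed entirely as NH4-N; advanced-treated effluent (ATE,
#' typically 18% organic N, 26% NH4 and 56% NO3) is dosed as 44% NH4-N and
#' 56% NO3-N. A recalcitrant fraction of the organic N can be passed
#' through untransformed (it then leaves the balance as inert N).
#'
#' @param TN Total nitrogen concentration (mg N L^-1), `>= 0`, vectorised.
#' @param source `"STE"` or `"ATE"`.
#' @param recalcitrant Fraction of the organic-N pool that is not
#'   mineralized (default 0 = full mineralization).
#' @return A data frame with columns `C_NH4`, `C_NO3` and `C_inert`
#'   (mg N L^-1).
#' @export
speciate_influent <- function(TN, source = c("STE", "ATE"),
                              recalcitrant = 0) {
  source <- match.arg(source)
  if (any(TN < 0)) stop("TN must be >= 0", call. = FALSE)
  if (recalcitrant < 0 || recalcitrant > 1) {
    stop("recalcitrant must lie in [0, 1]", call. = FALSE)
  }
  frac <- switch(source,
                 STE = c(org = 0.20, nh4 = 0.80, no3 = 0.00),
                 ATE = c(org = 0.18, nh4 = 0.26, no3 = 0.56))
  inert <- recalcitrant * frac[["org"]] * TN
  nh4 <- (frac[["nh4"]] + (1 - recalcitrant) * frac[["org"]]) * TN
  no3 <- frac[["no3"]] * TN
  data.frame(C_NH4 = nh4, C_NO3 = no3, C_inert = inert)
}

#' Back-calculate a maximum rate from an effective zero-order target
#'
#' The calibrated model reports layer-average effective zero-order rates,
#' not the underlying maxima. Given the target effective rate and the layer
#' reference state (WFPS, temperature and, for denitrification, depth below
#' the infiltrative surface), this returns the `mu_max` whose
#' substrate-saturated rate at that state equals the target:
#' `mu_max = target / (f_t * f_sw [* f_z])`.
#'
#' @param target Effective zero-order rate (mg N L^-1 d^-1).
#' @param S_ref Reference saturation (WFPS) of the layer.
#' @param T_ref Reference temperature (degrees C).
#' @param z_ref Reference depth below the infiltrative surface (cm); used
#'   for denitrification only.
#' @param p A [nitrification_params()] or [denitrification_params()] object
#'   carrying the dependency-function shape (its `mu_max` is ignored).
#' @param min_factor Smallest admissible combined dependency factor; an
#'   error results below it (the target would imply an unbounded `mu_max`).
#' @return The maximum rate `mu_max` (mg N L^-1 d^-1).
#' @export
mu_max_from_rate <- function(target, S_ref, T_ref = 20, z_ref = 0, p,
                             min_factor = 1e-3) {
  if (target < 0) stop("target must be >= 0", call. = FALSE)
  fac <- if (inherits(p, "nitrification_params")) {
    f_temperature(T_ref, p$Topt, p$beta) * fsw_nitrification(S_ref, p)
  } else if (inherits(p, "denitrification_params")) {
    f_temperature(T_ref, p$Topt, p$beta) * fsw_denitrification(S_ref, p) *
      f_carbon_depth(z_ref, p$alpha_c)
  } else {
    stop("p must be nitrification_params or denitrification_params",
         call. = FALSE)
  }
  if (fac < min_factor) {
    stop(sprintf(
      "dependency factor %.3g at the reference state is below min_factor; mu_max would be unbounded",
      fac), call. = FALSE)
  }
  target / fac
}

#' Tabulate transformation rates over a saturation-temperature grid
#'
#' Evaluates the substrate-saturated (zero-order) nitrification and
#' denitrification rates over a grid of saturations and temperatures,
#' handy for inspecting a parameterization before running transport.
#'
#' @param nit A [nitrification_params()] object.
#' @param denit A [denitrification_params()] object.
#' @param S Saturation grid.
#' @param T_C Temperature grid (degrees C).
#' @param z Depth below the infiltrative surface (cm) for the carbon
#'   factor.
#' @param C Substrate concentration (mg N L^-1), default well above Km.
#' @return Data frame with `S`, `T_C`, `nitrification`,
#'   `denitrification` (mg N L^-1 d^-1).
#' @export
kinetics_table <- function(nit, denit, S = seq(0, 1, by = 0.1),
                           T_C = c(15, 20, 23, 25), z = 0, C = 1e4) {
  grid <- expand.grid(S = S, T_C = T_C)
  grid$nitrification <- nitrification_rate(C, grid$S, grid$T_C, nit)
  grid$denitrification <- denitrification_rate(C, grid$S, grid$T_C, z,
                                               denit)
  grid
}
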