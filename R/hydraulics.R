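#' van Genuchten-Mualem soil hydraulic parameter set
#'
#' Bundles the closed-form retention/conductivity parameters used throughout
#' the flow solver: residual and saturated water content, inverse air-entry
#' pressure, pore-size distribution index, pore connectivity and saturated
#' hydraulic conductivity. The Mualem constraint `m = 1 - 1/n` is always
#' applied; `m` is derived, never stored.
#'
#' @param theta_r Residual volumetric water content (cm^3 cm^-3).
#' @param theta_s Saturated volumetric water content (cm^3 cm^-3).
#' @param alpha Inverse air-entry value (cm^-1).
#' @param n Pore-size distribution index (-), must exceed 1.
#' @param l Pore connectivity parameter (-), conventionally 0.5.
#' @param Ks Saturated hydraulic conductivity (cm d^-1).
#' @return An object of class `vg_params`.
#' @examples
#' p <- vg_params(0.025, 0.203, 0.0847, 2.289, Ks = 220.02)
#' water_content(-50, p)
#' @export
vg_params <- function(theta_r, theta_s, alpha, n, l = 0.5, Ks) {
  for (v in list(theta_r, theta_s, alpha, n, l, Ks)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("vg_params: all parameters must be finite numeric scalars",
           call. = FALSE)
    }
  }
  if (theta_r < 0 || theta_r >= theta_s || theta_s > 1) {
    stop("vg_params: need 0 <= theta_r < theta_s <= 1", call. = FALSE)
  }
  if (n <= 1) stop("vg_params: n must be > 1", call. = FALSE)
  if (alpha <= 0) stop("vg_params: alpha must be > 0", call. = FALSE)
  if (Ks <= 0) stop("vg_params: Ks must be > 0", call. = FALSE)
  structure(
    list(theta_r = theta_r, theta_s = theta_s, alpha = alpha, n = n,
         l = l, Ks = Ks),
    class = "vg_params"
  )
}

#' @export
print.vg_params <- function(x, ...) {
  cat(sprintf(
    "van Genuchten parameters: theta_r=%.4g theta_s=%.4g alpha=%.4g cm^-1 n=%.4g l=%.3g Ks=%.4g cm/d\n",
    x$theta_r, x$theta_s, x$alpha, x$n, x$l, x$Ks))
  invisible(x)
}

assert_vg <- function(p) {
  if (!inherits(p, "vg_params")) {
    stop("expected a 'vg_params' object (see vg_params())", call. = FALSE)
  }
  p
}

#' Water content from pressure head
#'
#' van Genuchten retention curve. Suction is expressed as negative pressure
#' head; any non-negative head returns saturation.
#'
#' @param h Pressure head (cm), vectorised. Negative under suction.
#' @param p A [vg_params()] object.
#' @return Volumetric water content (cm^3 cm^-3), bounded in
#'   `[theta_r, theta_s]`.
#' @export
water_content <- function(h, p) {
  assert_vg(p)
  m <- 1 - 1 / p$n
  th <- ifelse(h >= 0, p$theta_s,
               p$theta_r + (p$theta_s - p$theta_r) /
                 (1 + abs(p$alpha * h)^p$n)^m)
  as.numeric(th)
}

#' Specific moisture capacity d(theta)/dh
#'
#' Analytic derivative of the retention curve; zero at and above saturation.
#' Used by the mixed-form Picard iteration of the flow solver.
#'
#' @inheritParams water_content
#' @return Capacity (cm^-1).
#' @export
moisture_capacity <- function(h, p) {
  assert_vg(p)
  m <- 1 - 1 / p$n
  a <- p$alpha
  out <- numeric(length(h))
  neg <- h < 0
  ah <- abs(a * h[neg])
  out[neg] <- (p$theta_s - p$theta_r) * m * p$n * a * ah^(p$n - 1) /
    (1 + ah^p$n)^(m + 1)
  out
}

#' Effective saturation from water content
#'
#' Linear map of water content onto `[0, 1]`. Values outside
#' `[theta_r, theta_s]` by no more than `tol` are clipped with a warning;
#' larger excursions are an error.
#'
#' @param theta Volumetric water content (cm^3 cm^-3), vectorised.
#' @param p A [vg_params()] object.
#' @param tol Clipping tolerance (default `1e-9`).
#' @return Effective saturation Se in `[0, 1]`.
#' @export
effective_saturation <- function(theta, p, tol = 1e-9) {
  assert_vg(p)
  lo <- p$theta_r - tol
  hi <- p$theta_s + tol
  if (any(theta < lo | theta > hi)) {
    stop("effective_saturation: theta outside [theta_r, theta_s] beyond tolerance",
         call. = FALSE)
  }
  if (any(theta < p$theta_r | theta > p$theta_s)) {
    warning("effective_saturation: theta clipped to [theta_r, theta_s]")
  }
  Se <- (pmin(pmax(theta, p$theta_r), p$theta_s) - p$theta_r) /
    (p$theta_s - p$theta_r)
  as.numeric(Se)
}

#' Hydraulic conductivity from effective saturation
#'
#' Mualem conductivity model
#' `K(Se) = Ks * Se^l * (1 - (1 - Se^(1/m))^m)^2` with `m = 1 - 1/n`.
#' Se is clipped to `[eps, 1 - eps]` internally (`eps = 1e-12`) to avoid
#' raising zero to a negative power at the endpoints; K(0) = 0 and
#' K(1) = Ks are returned exactly.
#'
#' @param Se Effective saturation in `[0, 1]`, vectorised.
#' @param p A [vg_params()] object.
#' @return Hydraulic conductivity (cm d^-1).
#' @export
conductivity <- function(Se, p) {
  assert_vg(p)
  if (any(Se < 0 | Se > 1)) {
    stop("conductivity: Se must lie in [0, 1]", call. = FALSE)
  }
  m <- 1 - 1 / p$n
  eps <- 1e-12
  s <- pmin(pmax(Se, eps), 1 - eps)
  K <- p$Ks * s^p$l * (1 - (1 - s^(1 / m))^m)^2
  K[Se <= 0] <- 0
  K[Se >= 1] <- p$Ks
  as.numeric(K)
}

#' Hydraulic conductivity from pressure head
#'
#' Convenience composition `conductivity(Se(theta(h)))`.
#'
#' @inheritParams water_content
#' @return Hydraulic conductivity (cm d^-1).
#' @export
conductivity_h <- function(h, p) {
  conductivity(effective_saturation(water_content(h, p), p), p)
}

#' Steady gravity-driven (unit-gradient) unsaturated state
#'
#' For a steady downward flux `q` through a deep homogeneous profile the
#' pressure gradient vanishes and `K(h) = q` (unit total-head gradient).
#' This closed-form state is the analytic oracle for the interior of a
#' homogeneous column under constant infiltration, and connects a hydraulic
#' loading rate directly to a water-filled pore space.
#'
#' @param q Downward Darcy flux (cm d^-1), `0 < q <= Ks`.
#' @param p A [vg_params()] object.
#' @return A list with `h` (cm), `theta`, `Se` and `wfps` (= theta/theta_s).
#' @examples
#' p <- vg_params(0.025, 0.203, 0.0847, 2.289, Ks = 220.02)
#' unit_gradient_state(11.32, p)$wfps  # ~0.65
#' @export
unit_gradient_state <- function(q, p) {
  assert_vg(p)
  if (!is.numeric(q) || length(q) != 1L || q <= 0) {
    stop("unit_gradient_state: q must be a positive scalar", call. = FALSE)
  }
  if (q > p$Ks) {
    stop("unit_gradient_state: q exceeds Ks (ponding regime, no unit-gradient state)",
         call. = FALSE)
  }
  if (q == p$Ks) {
    return(list(h = 0, theta = p$theta_s, Se = 1, wfps = 1))
  }
  f <- function(Se) conductivity(Se, p) - q
  Se <- stats::uniroot(f, c(1e-12, 1), tol = 1e-14)$root
  theta <- p$theta_r + Se * (p$theta_s - p$theta_r)
  # invert the retention curve for the matching head
  m <- 1 - 1 / p$n
  h <- -((Se^(-1 / m) - 1)^(1 / p$n)) / p$alpha
  list(h = h, theta = theta, Se = Se, wfps = theta / p$theta_s)
}
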