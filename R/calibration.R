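#' Observation set for inverse modeling
#'
#' Validates a table of observations grouped by type (e.g. soil moisture
#' at the two probe depths, weekly effluent NH4 and NO3). Weights default
#' to `1 / sigma^2`.
#'
#' @param df Data frame with columns `group`, `time_d`, `value` and either
#'   `sigma` (> 0) or `weight` (> 0).
#' @return The validated data frame, class `observation_set`, with a
#'   `weight` column.
#' @export
observation_set <- function(df) {
  need <- c("group", "time_d", "value")
  if (!all(need %in% names(df))) {
    stop("observation_set needs columns group, time_d, value",
         call. = FALSE)
  }
  if (is.null(df$weight)) {
    if (is.null(df$sigma)) {
      stop("observation_set needs sigma or weight", call. = FALSE)
    }
    if (any(df$sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
    df$weight <- 1 / df$sigma^2
  }
  if (any(df$weight <= 0)) stop("weights must be > 0", call. = FALSE)
  class(df) <- c("observation_set", class(df))
  df
}

#' Weighted least-squares objective
#'
#' `sum_i w_i (obs_i - sim_i)^2` for a forward model evaluated at a
#' parameter vector. The forward model must return simulated values
#' aligned with the observation rows.
#'
#' @param params Named numeric parameter vector.
#' @param model Function `params -> numeric` (same length/order as `obs`).
#' @param obs An [observation_set()].
#' @return Non-negative scalar.
#' @export
weighted_sse <- function(params, model, obs) {
  sim <- model(params)
  if (length(sim) != nrow(obs)) {
    stop("forward model returned ", length(sim), " values for ",
         nrow(obs), " observations", call. = FALSE)
  }
  sum(obs$weight * (obs$value - sim)^2)
}

#' Root mean squared error
#'
#' @param sim,obs Numeric vectors of equal length.
#' @return `sqrt(mean((sim - obs)^2))`; zero iff the series are identical.
#' @export
rmse <- function(sim, obs) {
  if (length(sim) != length(obs)) {
    stop("rmse: series lengths differ", call. = FALSE)
  }
  if (length(sim) == 0) stop("rmse: empty series", call. = FALSE)
  sqrt(mean((sim - obs)^2))
}

fd_jacobian <- function(model, params, n_obs, fd_rel, fd_abs, central) {
  J <- matrix(0, n_obs, length(params))
  base <- if (central) NULL else model(params)
  for (j in seq_along(params)) {
    dp <- max(abs(params[j]) * fd_rel, fd_abs)
    up <- params; up[j] <- up[j] + dp
    if (central) {
      lo <- params; lo[j] <- lo[j] - dp
      J[, j] <- (model(up) - model(lo)) / (2 * dp)
    } else {
      J[, j] <- (model(up) - base) / dp
    }
  }
  J
}

#' Modified Gauss-Newton weighted least-squares fit
#'
#' Damped (Levenberg-style) Gauss-Newton minimization of the weighted
#' least-squares objective, with step halving until the objective
#' decreases, box constraints by projection, and forward finite-difference
#' sensitivities (1% relative perturbation by default). Converges when the
#' largest relative parameter change of an accepted step falls below
#' `tol`; on a linear forward model the first accepted step is the
#' minimizer.
#'
#' @param model Function `params -> sim vector` aligned with `obs`.
#' @param obs An [observation_set()].
#' @param init Named initial parameter vector.
#' @param lower,upper Bounds (recycled); defaults unbounded.
#' @param max_iter Iteration cap.
#' @param tol Relative parameter-change convergence criterion.
#' @param fd_rel,fd_abs Finite-difference perturbation (relative floor and
#'   absolute floor for zero-valued parameters).
#' @param central Use central differences.
#' @param lambda0 Initial Marquardt damping; `0` gives undamped
#'   Gauss-Newton steps (exact one-step convergence on linear models).
#' @return An object of class `calibration_result`: `par`, `objective`,
#'   `trajectory` (objective per accepted step), `converged`, `n_iter`,
#'   and per-group RMSE.
#' @export
gauss_newton_fit <- function(model, obs, init, lower = -Inf, upper = Inf,
                             max_iter = 50, tol = 1e-3, fd_rel = 0.01,
                             fd_abs = 1e-8, central = FALSE,
                             lambda0 = 1e-3) {
  if (nrow(obs) < length(init)) {
    stop("fewer observations than free parameters", call. = FALSE)
  }
  p <- init
  lower <- rep_len(lower, length(p))
  upper <- rep_len(upper, length(p))
  w <- sqrt(obs$weight)
  objective <- function(par) {
    r <- w * (obs$value - model(par))
    sum(r^2)
  }
  f <- objective(p)
  traj <- f
  lambda <- lambda0
  converged <- FALSE
  it <- 0
  while (it < max_iter && !converged) {
    it <- it + 1
    J <- fd_jacobian(model, p, nrow(obs), fd_rel, fd_abs, central) * w
    r <- w * (obs$value - model(p))
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    scale <- diag(JtJ)
    if (any(scale <= 0)) {
      dead <- names(p)[scale <= 0]
      stop("singular normal equations; unidentifiable parameter(s): ",
           paste(dead, collapse = ", "), call. = FALSE)
    }
    accepted <- FALSE
    for (trial in 1:12) {
      A <- JtJ + lambda * diag(scale, length(p))
      step <- tryCatch(drop(solve(A, g)), error = function(e) NULL)
      if (is.null(step)) {
        lambda <- max(lambda * 10, 1e-8)
        next
      }
      cand <- pmin(pmax(p + step, lower), upper)
      fc <- objective(cand)
      if (is.finite(fc) && fc <= f + 1e-14) {
        rel <- max(abs(cand - p) / pmax(abs(p), 1e-12))
        p <- cand
        f <- fc
        traj <- c(traj, f)
        lambda <- max(lambda / 3, 1e-12)
        accepted <- TRUE
        if (rel < tol) converged <- TRUE
        break
      }
      lambda <- max(lambda * 10, 1e-8)
    }
    if (!accepted) {
      converged <- TRUE  # no further descent possible
    }
  }
  sim <- model(p)
  groups <- unique(obs$group)
  g_rmse <- vapply(groups, function(g) {
    sel <- obs$group == g
    rmse(sim[sel], obs$value[sel])
  }, numeric(1))
  structure(list(par = p, objective = f, trajectory = traj,
                 converged = converged, n_iter = it,
                 rmse = stats::setNames(g_rmse, groups)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: objective %.4g after %d iterations (%s)\n",
              x$objective, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  print(signif(x$par, 5))
  invisible(x)
}

#' Composite scaled sensitivities
#'
#' `CSS_j = sqrt( (1/N) sum_i [ (d sim_i / d p_j) * p_j * w_i^(1/2) ]^2 )`
#' measures the total information the observations carry about each
#' parameter. Ratios are taken against the largest CSS; parameters with a
#' ratio below `threshold` (default 0.01) are flagged as insensitive and
#' recommended for exclusion from the regression.
#'
#' @param model Function `params -> sim vector`.
#' @param params Named parameter vector at which to evaluate.
#' @param obs An [observation_set()].
#' @param fd_rel,fd_abs Finite-difference controls; zero-valued parameters
#'   fall back to the absolute perturbation.
#' @param threshold Exclusion threshold on the CSS ratio.
#' @return List with `css`, `ratio` (max = 1) and logical `excluded`.
#' @export
composite_scaled_sensitivity <- function(model, params, obs,
                                         fd_rel = 0.01, fd_abs = 1e-8,
                                         threshold = 0.01) {
  J <- fd_jacobian(model, params, nrow(obs), fd_rel, fd_abs,
                   central = FALSE)
  w <- sqrt(obs$weight)
  css <- vapply(seq_along(params), function(j) {
    sqrt(mean((J[, j] * params[j] * w)^2))
  }, numeric(1))
  names(css) <- names(params)
  mx <- max(css)
  ratio <- if (mx > 0) css / mx else css * 0
  list(css = css, ratio = ratio, excluded = ratio < threshold)
}
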