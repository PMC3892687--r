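#' Continuous-discrete extended Kalman filter for SDE models
#'
#' Fits the filter once through the data at a fixed parameter point.
#' Between observations the state mean and covariance are propagated by the
#' moment equations
#' \deqn{dm/dt = f(m, u, \theta, t), \quad
#'       dP/dt = A P + P A^T + \sigma \sigma^T,}
#' with \eqn{A = \partial f/\partial x |_m}, integrated with an adaptive
#' explicit solver (relative tolerance `1e-8`).  At each observation the
#' standard EKF update is applied with \eqn{H = \partial h/\partial x|_m},
#' and the innovation-form negative log-likelihood
#' \deqn{J = \sum_k \tfrac12 [ e_k^T \Sigma_k^{-1} e_k + \ln\det(2\pi\Sigma_k) ]}
#' is accumulated.  The evaluation is fully deterministic: the same
#' parameter point always maps to the same cost, despite the model being
#' stochastic.
#'
#' The diffusion magnitudes act as "weights of trust" between data and
#' simulation: with negligible measurement noise the filtered means track
#' the measurements, and with negligible diffusion they track the ODE
#' solution.
#'
#' @param model a `dynmodel` (SDE form; all-zero diffusion is allowed and
#'   degenerates to an ODE residual likelihood).
#' @param theta free parameter vector (diffusion magnitudes must be
#'   non-negative).
#' @param data a `ta_dataset` whose observables are covered by the model's
#'   output map.
#' @param engine `"auto"` (compiled backend when available), `"r"`, `"cpp"`.
#' @param rtol,atol moment-equation solver tolerances.
#' @param guard divergence guard: any covariance entry exceeding
#'   `1e12 * data scale` flags the evaluation as diverged with cost `+Inf`
#'   instead of raising an error (samplers must survive bad points).
#' @param p0 initial state covariance diagonal (default 0: known initial
#'   state).
#' @return an object of class `ekf_fit` with per-time-point predicted and
#'   updated means/covariance diagonals, innovations and innovation
#'   variances, and the total negative log-likelihood `nll`.
#' @seealso [ekf_cost()], [infer_states()]
#' @export
ekf_filter <- function(model, theta, data, engine = c("auto", "r", "cpp"),
                       rtol = 1e-8, atol = 1e-10, guard = NULL, p0 = 0) {
  engine <- match.arg(engine)
  th <- full_theta(model, theta)
  sig <- sigma_vector(model, th)
  if (any(sig < 0)) stop("diffusion magnitudes must be non-negative")
  w <- dataset_wide(data, names(model$obs_states))
  if (length(w$times) && w$times[1] < model$t0)
    stop("observations precede the model initial time")
  if (is.null(guard))
    guard <- 1e12 * max(1, max(abs(w$Y), na.rm = TRUE)^2, na.rm = TRUE)
  use_cpp <- !is.null(model$cpp) && engine != "r"
  if (use_cpp) {
    res <- .ekf_cpp(model$cpp$id, n_states(model),
                    cpp_kinetic(model, th), sig,
                    model$cpp$iopar %||% numeric(0),
                    unname(model_x0(model, th)), model$t0, w$times, w$Y, w$SD,
                    as.integer(unname(model$obs_states)), rtol, atol, guard,
                    TRUE, numeric(0))
  } else {
    res <- ekf_r(model, th, sig, w, rtol, atol, guard, p0, grid = numeric(0),
                 keep = TRUE)
  }
  structure(list(
    times = w$times, observables = colnames(w$Y), y = w$Y, sd = w$SD,
    m_pred = name_sm(res$m_pred, model), P_pred_diag = name_sm(res$P_pred_diag, model),
    m_upd = name_sm(res$m_upd, model), P_upd_diag = name_sm(res$P_upd_diag, model),
    innovation = name_ob(res$innovation, w), innovation_var = name_ob(res$innovation_var, w),
    nll = res$nll, n_points = res$n_points, diverged = res$diverged,
    model = model, theta = th, engine = if (use_cpp) "cpp" else "r"
  ), class = "ekf_fit")
}

name_sm <- function(m, model) { colnames(m) <- model$state_names; m }
name_ob <- function(m, w) { colnames(m) <- colnames(w$Y); m }

# Pure-R reference implementation of the continuous-discrete EKF.  Works for
# arbitrary drift/output functions; Jacobians by central finite differences
# (relative step 1e-6) unless the model registers an analytic Jacobian.
ekf_r <- function(model, th, sig, w, rtol, atol, guard, p0, grid, keep) {
  n <- n_states(model)
  obs_idx <- unname(model$obs_states)
  times <- w$times; Y <- w$Y; SD <- w$SD
  K <- length(times); p <- ncol(Y)

  uf <- model$inputs
  jac <- model$jacobian
  drift <- model$drift
  snames <- model$state_names
  fd_jac <- function(x, u, t) {
    A <- matrix(0, n, n)
    for (j in seq_len(n)) {
      hstep <- 1e-6 * max(abs(x[j]), 1)
      xp <- x; xp[j] <- x[j] + hstep
      xm <- x; xm[j] <- x[j] - hstep
      A[, j] <- (drift(xp, u, th, t) - drift(xm, u, th, t)) / (2 * hstep)
    }
    A
  }
  dz <- function(t, z, parms) {
    m <- z[seq_len(n)]; names(m) <- snames
    P <- matrix(z[-seq_len(n)], n, n)
    u <- if (is.null(uf)) NULL else uf(t)
    f <- drift(m, u, th, t)
    A <- if (is.null(jac)) fd_jac(m, u, t) else jac(m, u, th, t)
    dP <- A %*% P + P %*% t(A)
    diag(dP) <- diag(dP) + sig^2
    list(c(f, as.numeric(dP)))
  }

  # merged event schedule (observations + recording grid)
  ev <- sort(unique(c(times, grid)))
  m <- unname(model_x0(model, th)); P <- diag(rep(p0, length.out = n), n)
  t_cur <- model$t0
  nll <- 0; n_pts <- 0L; diverged <- FALSE
  if (keep) {
    Mp <- matrix(NA_real_, K, n); Pp <- Mp; Mu <- Mp; Pu <- Mp
    Inn <- matrix(NA_real_, K, p); Sv <- Inn
  }
  Gm <- matrix(NA_real_, length(grid), n); Gv <- Gm

  for (tk in ev) {
    if (tk > t_cur) {
      sol <- try(deSolve::ode(y = c(m, as.numeric(P)), times = c(t_cur, tk),
                              func = dz, parms = NULL, rtol = rtol, atol = atol),
                 silent = TRUE)
      if (inherits(sol, "try-error") || nrow(sol) < 2 ||
          any(!is.finite(sol[2, -1]))) { diverged <- TRUE; break }
      z <- sol[2, -1]
      m <- z[seq_len(n)]; P <- matrix(z[-seq_len(n)], n, n)
      if (max(abs(P)) > guard || max(abs(m)) > guard) { diverged <- TRUE; break }
      t_cur <- tk
    }
    k <- match(tk, times)
    if (!is.na(k)) {
      if (keep) { Mp[k, ] <- m; Pp[k, ] <- diag(P) }
      oo <- which(is.finite(Y[k, ]))
      if (length(oo)) {
        H <- matrix(0, length(oo), n)
        H[cbind(seq_along(oo), obs_idx[oo])] <- 1
        e <- Y[k, oo] - m[obs_idx[oo]]
        Smeas <- diag(SD[k, oo]^2, length(oo))
        Sig <- H %*% P %*% t(H) + Smeas
        Sig <- (Sig + t(Sig)) / 2
        ch <- try(chol(Sig), silent = TRUE)
        if (inherits(ch, "try-error")) { diverged <- TRUE; break }
        Sinv_e <- backsolve(ch, forwardsolve(t(ch), e))
        nll <- nll + 0.5 * (sum(e * Sinv_e) + 2 * sum(log(diag(ch))) +
                              length(oo) * log(2 * pi))
        n_pts <- n_pts + length(oo)
        Kg <- P %*% t(H) %*% chol2inv(ch)
        m <- m + as.numeric(Kg %*% e)
        IKH <- diag(n) - Kg %*% H
        P <- IKH %*% P %*% t(IKH) + Kg %*% Smeas %*% t(Kg)
        P <- (P + t(P)) / 2
        eg <- eigen(P, symmetric = TRUE)
        if (any(eg$values < 0)) {
          eg$values[eg$values < 0] <- 0
          P <- eg$vectors %*% diag(eg$values, n) %*% t(eg$vectors)
          P <- (P + t(P)) / 2
        }
        if (max(abs(P)) > guard || any(!is.finite(m))) { diverged <- TRUE; break }
        if (keep) { Inn[k, oo] <- e; Sv[k, oo] <- diag(Sig)[seq_along(oo)] }
      }
      if (keep) { Mu[k, ] <- m; Pu[k, ] <- diag(P) }
    }
    gi <- match(tk, grid)
    if (!is.na(gi)) { Gm[gi, ] <- m; Gv[gi, ] <- diag(P) }
  }
  out <- list(nll = if (diverged) Inf else nll, diverged = diverged,
              n_points = n_pts)
  if (keep) {
    out$m_pred <- Mp; out$P_pred_diag <- Pp; out$m_upd <- Mu; out$P_upd_diag <- Pu
    out$innovation <- Inn; out$innovation_var <- Sv
  }
  if (length(grid)) { out$grid_mean <- Gm; out$grid_var <- Gv }
  out
}

#' Innovation-based cost of a parameter point
#'
#' The negative log-likelihood of the data under the filter (see
#' [ekf_filter()]).  Deterministic: repeated calls with identical inputs
#' return bit-identical values.  Divergence of the covariance propagation is
#' reported as `+Inf`, never `NaN`, so samplers can treat bad parameter
#' points uniformly.
#'
#' @inheritParams ekf_filter
#' @return `list(value, n_points, diverged)`.
#' @export
ekf_cost <- function(model, theta, data, engine = c("auto", "r", "cpp"),
                     rtol = 1e-8, atol = 1e-10, guard = NULL) {
  engine <- match.arg(engine)
  th <- full_theta(model, theta)
  sig <- sigma_vector(model, th)
  if (any(sig < 0)) return(list(value = Inf, n_points = 0L, diverged = TRUE))
  w <- dataset_wide(data, names(model$obs_states))
  if (nrow(w$Y) == 0)
    return(list(value = 0, n_points = 0L, diverged = FALSE))
  if (is.null(guard))
    guard <- 1e12 * max(1, max(abs(w$Y), na.rm = TRUE)^2, na.rm = TRUE)
  use_cpp <- !is.null(model$cpp) && engine != "r"
  res <- if (use_cpp) {
    .ekf_cpp(model$cpp$id, n_states(model), cpp_kinetic(model, th),
             sig, model$cpp$iopar %||% numeric(0), unname(model_x0(model, th)), model$t0,
             w$times, w$Y, w$SD, as.integer(unname(model$obs_states)),
             rtol, atol, guard, FALSE, numeric(0))
  } else {
    ekf_r(model, th, sig, w, rtol, atol, guard, 0, numeric(0), keep = FALSE)
  }
  list(value = res$nll, n_points = res$n_points, diverged = res$diverged)
}

#' Infer state trajectories (including hidden states) on a grid
#'
#' Runs the filter forward and records the filtered mean and covariance
#' diagonal at the requested grid times (moment propagation between
#' observations, measurement updates at observations).  For an extended
#' model with diffusion-driven auxiliary states this recovers the
#' trajectories of the hidden mechanisms the diffusion is standing in for.
#'
#' @inheritParams ekf_filter
#' @param grid increasing time grid (must start at or after `model$t0`).
#' @return a `ta_trajectory` whose `states` are filtered means, with a
#'   `var` matrix of per-point variances in `meta`.
#' @export
infer_states <- function(model, theta, data, grid, engine = c("auto", "r", "cpp"),
                         rtol = 1e-8, atol = 1e-10, guard = NULL) {
  engine <- match.arg(engine)
  th <- full_theta(model, theta)
  sig <- sigma_vector(model, th)
  if (any(sig < 0)) stop("diffusion magnitudes must be non-negative")
  if (is.unsorted(grid, strictly = TRUE)) stop("`grid` must be strictly increasing")
  if (grid[1] < model$t0) stop("grid precedes the model initial time")
  w <- dataset_wide(data, names(model$obs_states))
  if (is.null(guard))
    guard <- 1e12 * max(1, max(abs(w$Y), na.rm = TRUE)^2, na.rm = TRUE)
  use_cpp <- !is.null(model$cpp) && engine != "r"
  res <- if (use_cpp) {
    .ekf_cpp(model$cpp$id, n_states(model), cpp_kinetic(model, th),
             sig, model$cpp$iopar %||% numeric(0), unname(model_x0(model, th)), model$t0,
             w$times, w$Y, w$SD, as.integer(unname(model$obs_states)),
             rtol, atol, guard, FALSE, grid)
  } else {
    ekf_r(model, th, sig, w, rtol, atol, guard, 0, grid, keep = FALSE)
  }
  if (res$diverged) stop("filter diverged while inferring states")
  S <- res$grid_mean; V <- res$grid_var
  colnames(S) <- colnames(V) <- model$state_names
  new_trajectory(grid, S, meta = list(var = V, nll = res$nll))
}

# ---- ekf_fit methods -------------------------------------------------------

#' @export
print.ekf_fit <- function(x, ...) {
  cat(sprintf("<ekf_fit> model '%s', %d observation points\n",
              x$model$name, x$n_points))
  cat(sprintf("  negative log-likelihood: %s\n",
              if (x$diverged) "+Inf (diverged)" else format(x$nll, digits = 8)))
  invisible(x)
}

#' @export
summary.ekf_fit <- function(object, ...) {
  st <- innovation_sign_test(object)
  out <- list(nll = object$nll, n_points = object$n_points,
              diverged = object$diverged, sign_test = st,
              theta = object$theta, model = object$model$name)
  class(out) <- "summary.ekf_fit"
  out
}

#' @export
print.summary.ekf_fit <- function(x, ...) {
  cat(sprintf("EKF fit of model '%s'\n", x$model))
  cat(sprintf("  cost (negative log-likelihood): %s over %d points\n",
              format(x$nll, digits = 8), x$n_points))
  cat("  parameters:\n")
  print(round(x$theta, 6))
  cat("  innovation sign test (systematic bias check):\n")
  print(x$sign_test, row.names = FALSE)
  invisible(x)
}

#' @export
residuals.ekf_fit <- function(object, standardized = FALSE, ...) {
  if (standardized) object$innovation / sqrt(object$innovation_var)
  else object$innovation
}

#' @export
fitted.ekf_fit <- function(object, ...) {
  idx <- object$model$obs_states[object$observables]
  object$m_pred[, idx, drop = FALSE]
}

#' @export
logLik.ekf_fit <- function(object, ...) {
  structure(-object$nll, df = length(object$model$param_names),
            nobs = object$n_points, class = "logLik")
}

#' @export
plot.ekf_fit <- function(x, which = seq_along(x$observables), ...) {
  obs <- x$observables[which]
  old <- graphics::par(mfrow = c(1, length(obs)))
  on.exit(graphics::par(old))
  for (ob in obs) {
    j <- match(ob, x$observables)
    si <- x$model$obs_states[[ob]]
    keep <- is.finite(x$y[, j])
    graphics::plot(x$times[keep], x$y[keep, j], pch = 8,
                   xlab = "time", ylab = ob, ...)
    graphics::lines(x$times, x$m_upd[, si], col = "steelblue", lwd = 2)
    graphics::lines(x$times, x$m_pred[, si], col = "grey50", lty = 2)
  }
  invisible(x)
}
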