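#' Simulate the deterministic (ODE) part of a model
#'
#' Integrates the drift with all diffusion terms ignored, using an adaptive
#' solver with relative tolerance `1e-8`.  The first grid point must equal
#' the model's initial time; the returned trajectory starts exactly at the
#' initial state.
#'
#' @param model a `dynmodel`.
#' @param theta free parameter vector (named or in `model$param_names` order).
#' @param times strictly increasing time grid starting at `model$t0`.
#' @param rtol,atol solver tolerances.
#' @param engine `"auto"` (compiled backend when available), `"r"`
#'   (deSolve), or `"cpp"`.
#' @return a `ta_trajectory`: list with `times`, a time-by-state `states`
#'   matrix, and solver metadata.
#' @export
simulate_ode <- function(model, theta, times, rtol = 1e-8, atol = 1e-10,
                         engine = c("auto", "r", "cpp")) {
  engine <- match.arg(engine)
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  if (abs(times[1] - model$t0) > 1e-12)
    stop("first grid point must equal the model initial time t0 = ", model$t0)
  th <- full_theta(model, theta)
  use_cpp <- !is.null(model$cpp) && engine != "r"
  if (use_cpp) {
    Y <- .sim_ode_cpp(model$cpp$id, n_states(model), cpp_kinetic(model, th),
                      model$cpp$iopar %||% numeric(0), unname(model_x0(model, th)),
                      model$t0, times, rtol, atol)
  } else {
    dfun <- function(t, x, p) {
      names(x) <- model$state_names
      u <- if (is.null(model$inputs)) NULL else model$inputs(t)
      f <- model$drift(x, u, th, t)
      if (any(!is.finite(f))) {
        bad <- model$state_names[which(!is.finite(f))[1]]
        stop(sprintf("non-finite drift for state '%s' at time %g", bad, t))
      }
      list(f)
    }
    sol <- deSolve::ode(y = unname(model_x0(model, th)), times = times, func = dfun,
                        parms = NULL, rtol = rtol, atol = atol)
    if (nrow(sol) < length(times))
      stop("integration failure: solver stopped at time ", sol[nrow(sol), 1])
    Y <- unname(sol[, -1, drop = FALSE])
  }
  colnames(Y) <- model$state_names
  new_trajectory(times, Y, meta = list(rtol = rtol, atol = atol,
                                       engine = if (use_cpp) "cpp" else "r"))
}

new_trajectory <- function(times, states, meta = list()) {
  structure(list(times = times, states = states, meta = meta),
            class = "ta_trajectory")
}

#' @export
print.ta_trajectory <- function(x, ...) {
  cat(sprintf("<ta_trajectory> %d time points, states: %s\n",
              length(x$times), paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

#' Simulate SDE sample paths with the Euler-Maruyama scheme
#'
#' Each state equation receives independent Wiener increments scaled by its
#' (constant, diagonal) diffusion magnitude.  With all diffusion magnitudes
#' zero the paths coincide with the ODE solution up to the discretization
#' error of the fixed-step scheme.
#'
#' @param model a `dynmodel` (SDE form; an ODE model is accepted and treated
#'   as having zero diffusion).
#' @param theta free parameter vector, including diffusion magnitudes.
#' @param times output time grid (starting at `model$t0`).
#' @param n_paths number of sample paths.
#' @param seed integer seed; paths are bit-reproducible given the seed.
#' @param n_sub Euler-Maruyama sub-steps per grid interval (step size is at
#'   most the smallest grid spacing divided by `n_sub`).
#' @param clip_negative clip states at 0 after each sub-step (off by
#'   default: the filter works on moments and paths are simulated freely).
#' @return a `ta_ensemble`: list with `times` and a
#'   time-by-state-by-path array `states`.
#' @export
simulate_sde <- function(model, theta, times, n_paths = 1L, seed = 1L,
                         n_sub = 10L, clip_negative = FALSE) {
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  th <- full_theta(model, theta)
  sig <- sigma_vector(model, th)
  if (any(sig < 0)) stop("diffusion magnitudes must be non-negative")
  n <- n_states(model)
  TT <- length(times)
  h <- min(diff(times)) / n_sub
  out <- array(NA_real_, dim = c(TT, n, n_paths),
               dimnames = list(NULL, model$state_names, NULL))
  set.seed(seed)
  for (ip in seq_len(n_paths)) {
    x <- unname(model_x0(model, th))
    names(x) <- model$state_names
    out[1, , ip] <- x
    t <- times[1]
    for (k in 2:TT) {
      tk <- times[k]
      nst <- max(1L, ceiling((tk - t) / h - 1e-9))
      dt <- (tk - t) / nst
      sq <- sqrt(dt)
      Z <- matrix(stats::rnorm(nst * n), nst, n)
      for (s in seq_len(nst)) {
        u <- if (is.null(model$inputs)) NULL else model$inputs(t)
        f <- model$drift(x, u, th, t)
        x <- x + f * dt + sig * sq * Z[s, ]
        if (clip_negative) x[x < 0] <- 0
        t <- t + dt
      }
      t <- tk
      out[k, , ip] <- x
    }
  }
  structure(list(times = times, states = out,
                 meta = list(seed = seed, n_sub = n_sub, h = h)),
            class = "ta_ensemble")
}

#' @export
print.ta_ensemble <- function(x, ...) {
  cat(sprintf("<ta_ensemble> %d paths x %d time points, states: %s\n",
              dim(x$states)[3], length(x$times),
              paste(dimnames(x$states)[[2]], collapse = ", ")))
  invisible(x)
}
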