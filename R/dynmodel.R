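#' Construct a dynamic model (ODE or SDE)
#'
#' A `dynmodel` bundles everything needed to simulate and filter a dynamic
#' model of a biochemical system: the drift (reaction) field, an optional
#' stoichiometry factorization, a diagonal diffusion parameterization, an
#' output map, optional time-varying inputs, and the initial state.  With an
#' empty diffusion specification the model is a deterministic ODE system;
#' [reformulate_as_sde()] appends one non-negative diffusion parameter per
#' state equation, turning it into an SDE model whose diffusion magnitudes
#' quantify the uncertainty in the model structure.
#'
#' @param state_names character vector of state variable names.
#' @param param_names character vector of (kinetic) parameter names.
#' @param drift function `(x, u, theta, t)` returning the rate vector
#'   (concentration per time unit).  `x` and `theta` are named numeric
#'   vectors; `u` is the input vector (or `NULL`).
#' @param obs_states named integer vector mapping observable names to state
#'   indices (the output map; only state-selection outputs are supported by
#'   the fast filtering path).  Defaults to observing every state.
#' @param stoichiometry optional integer stoichiometry matrix `N`; if given
#'   together with `reactions`, the drift is `N %*% v(x, u, theta, t)`.
#' @param reactions optional reaction-rate function `(x, u, theta, t)`.
#' @param diffusion character vector of length `length(state_names)` naming
#'   the diffusion parameter of each state equation; `""` marks a
#'   deterministic equation.  Default: no diffusion (pure ODE model).
#' @param inputs optional function `u(t)` returning the input vector.
#' @param x0 named numeric initial state.
#' @param t0 initial time (default 0).
#' @param x0_known logical; `TRUE` (default) fixes the initial state, giving
#'   the filter a zero initial covariance.
#' @param jacobian optional analytic drift Jacobian `(x, u, theta, t)`;
#'   central finite differences are used when absent.
#' @param fixed named numeric vector of parameters held fixed (excluded from
#'   the free parameter vector).
#' @param name optional model id used in printouts and reports.
#' @param cpp optional compiled-backend descriptor (used by the bundled case
#'   studies); a list `list(id =, iopar =)`.
#'
#' @return an object of class `dynmodel`.
#' @seealso [simulate_ode()], [simulate_sde()], [reformulate_as_sde()],
#'   [promote_parameter_to_state()], [ekf_filter()]
#' @export
dyn_model <- function(state_names, param_names, drift = NULL,
                      obs_states = NULL, stoichiometry = NULL, reactions = NULL,
                      diffusion = NULL, inputs = NULL, x0, t0 = 0,
                      x0_known = TRUE, jacobian = NULL, fixed = NULL,
                      name = "model", cpp = NULL) {
  n <- length(state_names)
  if (is.null(drift) && (is.null(stoichiometry) || is.null(reactions)))
    stop("supply `drift`, or `stoichiometry` together with `reactions`")
  if (is.null(drift)) {
    N <- stoichiometry
    v <- reactions
    drift <- function(x, u, theta, t) as.numeric(N %*% v(x, u, theta, t))
  }
  if (is.null(diffusion)) diffusion <- rep("", n)
  if (length(diffusion) != n)
    stop("`diffusion` must have one entry per state equation")
  if (is.null(obs_states)) {
    obs_states <- seq_len(n)
    names(obs_states) <- state_names
  }
  if (is.null(names(obs_states)) || any(obs_states < 1L) || any(obs_states > n))
    stop("`obs_states` must be a named vector of valid state indices")
  x0 <- x0[state_names]
  if (anyNA(x0)) stop("`x0` must name every state")
  dpar <- setdiff(unique(diffusion), "")
  all_params <- c(param_names, setdiff(dpar, param_names))
  fixed <- fixed %||% numeric(0)
  if (!all(names(fixed) %in% all_params)) stop("unknown names in `fixed`")
  m <- structure(list(
    name = name,
    state_names = state_names,
    kinetic_params = param_names,
    diffusion = diffusion,
    all_params = all_params,
    param_names = setdiff(all_params, names(fixed)),
    fixed = fixed,
    drift = drift,
    stoichiometry = stoichiometry,
    reactions = reactions,
    obs_states = obs_states,
    inputs = inputs,
    x0 = x0,
    t0 = t0,
    x0_known = x0_known,
    jacobian = jacobian,
    cpp = cpp
  ), class = "dynmodel")
  validate_dynmodel(m)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_dynmodel <- function(m) {
  stopifnot(length(m$diffusion) == length(m$state_names))
  u <- if (is.null(m$inputs)) NULL else m$inputs(m$t0)
  th <- full_theta(m, rep(1, length(m$param_names)))
  f <- m$drift(m$x0, u, th, m$t0)
  if (length(f) != length(m$state_names))
    stop("drift must return one rate per state")
  if (!is.null(m$stoichiometry) && !is.null(m$reactions)) {
    v <- m$reactions(m$x0, u, th, m$t0)
    if (max(abs(as.numeric(m$stoichiometry %*% v) - f)) > 1e-8 * max(1, max(abs(f))))
      stop("drift is inconsistent with stoichiometry %*% reactions")
  }
  invisible(m)
}

#' @export
print.dynmodel <- function(x, ...) {
  nsig <- sum(x$diffusion != "")
  cat(sprintf("<dynmodel '%s'> %s model\n", x$name,
              if (nsig) "SDE" else "ODE"))
  cat("  states:      ", paste(x$state_names, collapse = ", "), "\n")
  cat("  free params: ", paste(x$param_names, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:       ", paste(sprintf("%s=%g", names(x$fixed), x$fixed),
                                 collapse = ", "), "\n")
  if (nsig)
    cat("  diffusion:   ", paste(ifelse(x$diffusion == "", "-", x$diffusion),
                                 collapse = ", "), "\n")
  cat("  observables: ", paste(names(x$obs_states), collapse = ", "), "\n")
  invisible(x)
}

# number of states
n_states <- function(model) length(model$state_names)

# merge free theta with fixed values into the full named parameter vector
full_theta <- function(model, theta) {
  if (is.null(names(theta))) {
    if (length(theta) != length(model$param_names))
      stop(sprintf("expected %d parameters (%s), got %d",
                   length(model$param_names),
                   paste(model$param_names, collapse = ", "), length(theta)))
    names(theta) <- model$param_names
  } else {
    miss <- setdiff(model$param_names, names(theta))
    if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
    theta <- theta[model$param_names]
  }
  out <- numeric(length(model$all_params))
  names(out) <- model$all_params
  out[names(theta)] <- theta
  if (length(model$fixed)) out[names(model$fixed)] <- model$fixed
  out
}

# per-state diffusion magnitudes from the full parameter vector
sigma_vector <- function(model, theta_full) {
  vapply(model$diffusion, function(d) if (d == "") 0 else unname(theta_full[d]),
         numeric(1), USE.NAMES = FALSE)
}

is_sde <- function(model) any(model$diffusion != "")

# kinetic parameter vector for the compiled backend (appends any trailing
# fixed constants the compiled drift expects, e.g. a gate threshold)
cpp_kinetic <- function(model, theta_full) {
  c(unname(theta_full[model$kinetic_params]), model$cpp$extra_kinetic)
}

# initial state, with any estimated initial-value parameters substituted
model_x0 <- function(model, theta_full) {
  x0 <- model$x0
  if (!is.null(model$x0_param))
    for (st in names(model$x0_param))
      x0[[st]] <- theta_full[[model$x0_param[[st]]]]
  x0
}

#' Reformulate an ODE model as an SDE model
#'
#' Appends one non-negative diffusion parameter per state equation, leaving
#' the drift untouched.  The diffusion magnitudes ("system noise") represent
#' the combined effect of intrinsic randomness and topological uncertainty;
#' a model whose viable parameter region only contains non-negligible
#' diffusion on some equation is signalling missing structure there.
#'
#' @param model a deterministic `dynmodel`.
#' @param sigma_names names for the new diffusion parameters; defaults to
#'   `sigma_<state>`.
#' @return a new `dynmodel` with `diffusion` filled in and the diffusion
#'   parameters appended to the free parameter vector.
#' @export
reformulate_as_sde <- function(model, sigma_names = NULL) {
  if (is_sde(model))
    stop("model is already stochastic (has diffusion parameters)")
  if (is.null(sigma_names)) sigma_names <- paste0("sigma_", model$state_names)
  if (length(sigma_names) != n_states(model))
    stop("need one diffusion parameter name per state")
  m <- model
  m$diffusion <- sigma_names
  m$all_params <- c(m$all_params, sigma_names)
  m$param_names <- setdiff(m$all_params, names(m$fixed))
  if (!is.null(m$cpp)) m$cpp$sigma_names <- sigma_names
  m
}

#' Promote a model parameter to a diffusion-driven state variable
#'
#' Replaces a (suspect) constant parameter by a new state variable with zero
#' drift and its own diffusion parameter.  The new state is free to wander
#' wherever the data pull it through the filter, so its inferred trajectory
#' reveals how the "constant" would have to change in time for the model to
#' explain the data -- the basis for proposing a replacement reaction term.
#'
#' @param model a stochastic `dynmodel` (see [reformulate_as_sde()]).
#' @param param name of the parameter appearing in the drift.
#' @param init initial value of the new state, or `NULL` (default) to
#'   estimate it: a free parameter `<param>0` then controls the initial
#'   value.
#' @param sigma_name name for the new diffusion parameter (default
#'   `sigma_<param>`).
#' @return a `dynmodel` with one more state, one more diffusion parameter,
#'   and the promoted parameter removed from the parameter vector.
#' @export
promote_parameter_to_state <- function(model, param, init = NULL,
                                       sigma_name = paste0("sigma_", param)) {
  if (!is_sde(model))
    stop("promote parameters on the SDE form of the model (see reformulate_as_sde)")
  if (!param %in% model$all_params) stop("unknown parameter: ", param)
  m <- model
  old_drift <- model$drift
  ns <- c(model$state_names, param)
  k <- length(ns)
  m$state_names <- ns
  m$kinetic_params <- setdiff(model$kinetic_params, param)
  m$all_params <- c(setdiff(model$all_params, param), sigma_name)
  m$fixed <- model$fixed[setdiff(names(model$fixed), param)]
  m$diffusion <- c(model$diffusion, sigma_name)
  if (is.null(init)) {
    init_par <- paste0(param, "0")
    m$all_params <- c(m$all_params, init_par)
    m$x0_param <- c(model$x0_param, structure(init_par, names = param))
    init <- 0
  }
  m$param_names <- setdiff(m$all_params, names(m$fixed))
  m$x0 <- c(model$x0, structure(init, names = param))
  m$drift <- function(x, u, theta, t) {
    th <- theta
    th[param] <- x[[param]]
    c(old_drift(x[seq_len(k - 1)], u, th, t), 0)
  }
  m$jacobian <- NULL # analytic Jacobian of the parent no longer applies
  m$stoichiometry <- NULL
  m$reactions <- NULL
  m$name <- paste0(model$name, "+", param)
  # compiled backend: known promotions are re-targeted in the case studies
  m$cpp <- promoted_cpp_backend(model, param)
  m
}

#' Fix parameters of a model at given values
#'
#' Used e.g. to construct model variants with individual diffusion terms
#' eliminated (fixed at zero), dropping them from the free parameter vector.
#'
#' @param model a `dynmodel`.
#' @param ... named parameter values, or a single named numeric vector.
#' @return a `dynmodel` with a reduced free parameter vector.
#' @export
fix_params <- function(model, ...) {
  vals <- c(...)
  if (is.list(vals)) vals <- unlist(vals)
  if (is.null(names(vals)) || !all(names(vals) %in% model$all_params))
    stop("fix_params needs named values of existing parameters")
  m <- model
  m$fixed <- c(m$fixed[setdiff(names(m$fixed), names(vals))], vals)
  m$param_names <- setdiff(m$all_params, names(m$fixed))
  m
}
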