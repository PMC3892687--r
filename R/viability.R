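#' Viability rules for parameter points
#'
#' A parameter point is *viable* when its cost passes a model-compatibility
#' criterion.  Two modes exist.  For ODE models the criterion is based on
#' the expected log-likelihood of a correct model: under Gaussian noise the
#' standardized squared-residual sum is chi-squared with `N` degrees of
#' freedom, so the cost cutoff is
#' \deqn{J_{max} = \tfrac12 (N + \alpha\sqrt{2N}) + \sum_k \tfrac12 \ln\det(2\pi S_k),}
#' with `alpha` the acceptable deviation in numbers of standard deviations.
#' For SDE models (where that algebra does not apply) the cutoff is a
#' distance from the optimum: points within `delta_orders` orders of
#' likelihood magnitude of the best point are viable,
#' \eqn{J_{max} = J_{best} + \delta \ln 10}.
#'
#' @param mode `"ode"` or `"sde"`.
#' @param alpha acceptable deviation in SDs (ODE mode), `>= 0`.
#' @param delta_orders likelihood orders of magnitude (SDE mode), `>= 0`;
#'   the bundled case studies use the default 5.
#' @return a `viability_rule` object; bind it to data / a best cost with
#'   [ode_threshold()] / [sde_cutoff()] or let [classify_viable()] do so.
#' @export
viability_rule <- function(mode = c("sde", "ode"), alpha = 3, delta_orders = 5) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, delta_orders >= 0)
  structure(list(mode = mode, alpha = alpha, delta_orders = delta_orders),
            class = "viability_rule")
}

#' Cost cutoff for ODE-model viability
#'
#' @param data a `ta_dataset` (the per-point noise SDs set the constant
#'   term of the cost).
#' @param alpha acceptable deviation in numbers of standard deviations.
#' @return the cost cutoff (upper bound on the negative log-likelihood).
#' @export
ode_threshold <- function(data, alpha) {
  N <- nrow(data)
  if (N == 0) stop("dataset has no points")
  const <- 0.5 * sum(log(2 * pi * data$sd^2))
  0.5 * (N + alpha * sqrt(2 * N)) + const
}

#' Cost cutoff for SDE-model viability
#'
#' One order of likelihood magnitude equals `ln 10` units of negative
#' log-likelihood.
#'
#' @param best_cost finite cost of the most likely parameter point found.
#' @param delta_orders orders of magnitude of likelihood distance accepted.
#' @return the cost cutoff.
#' @export
sde_cutoff <- function(best_cost, delta_orders = 5) {
  if (!is.finite(best_cost)) stop("best cost must be finite")
  best_cost + delta_orders * log(10)
}

#' Classify sampled parameter points as viable or non-viable
#'
#' Sets viability flags `J <= threshold` and normalized likelihood weights
#' `w_i = exp(J_best - J_i) / sum(...)` over the viable subset.
#'
#' @param sample a `viable_sample` (see [explore()]) or a list with
#'   `points` and `costs`.
#' @param rule a `viability_rule`, or a numeric cost threshold.
#' @param data dataset needed to bind an ODE-mode rule.
#' @return the sample with updated `viable`, `weights`, `cutoff`.
#' @export
classify_viable <- function(sample, rule, data = NULL) {
  thr <- if (is.numeric(rule)) {
    rule
  } else if (rule$mode == "ode") {
    if (is.null(data)) stop("ODE-mode rule needs the dataset to derive its threshold")
    ode_threshold(data, rule$alpha)
  } else {
    best <- suppressWarnings(min(sample$costs[is.finite(sample$costs)]))
    if (!is.finite(best)) best <- Inf
    if (is.finite(best)) sde_cutoff(best, rule$delta_orders) else Inf
  }
  sample$cutoff <- thr
  sample$viable <- is.finite(sample$costs) & sample$costs <= thr
  sample$weights <- viability_weights(sample$costs, sample$viable)
  if (!is.numeric(rule)) sample$rule <- rule
  sample
}

viability_weights <- function(costs, viable) {
  w <- rep(0, length(costs))
  if (any(viable)) {
    b <- min(costs[viable])
    w[viable] <- exp(b - costs[viable])
    w <- w / sum(w)
  }
  w
}

#' Sign and runs tests for systematic model bias in the innovations
#'
#' Step-2 style check that the model predictions do not systematically over-
#' or underestimate the observations, per observable: an exact binomial
#' test of the number of positive innovations (detects a global imbalance)
#' and a Wald-Wolfowitz runs test on the innovation signs (detects the
#' blocked over-then-under pattern a structural defect typically leaves,
#' which a pure count can miss).  Systematic bias is flagged when either
#' test rejects at the 5% level, with `direction = "under"` when the
#' observations mostly exceed the predictions (the model underestimates).
#' Reported as a diagnostic, never as a viability veto.
#'
#' @param fit an `ekf_fit`, or a numeric matrix/vector of innovations.
#' @param observable optional observable name(s) to restrict to.
#' @param window optional `c(from, to)` time window: the sign count and
#'   direction are taken from innovations inside it (e.g. a post-shift
#'   response phase), while the runs test always uses the full series.
#'   Requires an `ekf_fit` input.
#' @return data.frame with columns `observable`, `n`, `n_pos`, `p_sign`,
#'   `p_runs`, `p_value` (the smaller of the two), `direction`
#'   (`"under"`, `"over"`, `"none"`).
#' @export
innovation_sign_test <- function(fit, observable = NULL, window = NULL) {
  is_fit <- inherits(fit, "ekf_fit")
  E <- if (is_fit) fit$innovation else as.matrix(fit)
  if (is.null(colnames(E))) colnames(E) <- paste0("obs", seq_len(ncol(E)))
  if (!is.null(window) && !is_fit)
    stop("`window` needs an ekf_fit (times are required)")
  obs <- observable %||% colnames(E)
  out <- lapply(obs, function(ob) {
    e_all <- E[, ob]
    keep <- is.finite(e_all) & e_all != 0
    e_full <- e_all[keep]
    e_win <- if (is.null(window)) e_full else {
      tt <- fit$times[keep]
      e_full[tt > window[1] & tt <= window[2]]
    }
    n <- length(e_win); np <- sum(e_win > 0)
    p_sign <- if (n) stats::binom.test(np, n, 0.5)$p.value else NA_real_
    p_runs <- runs_test_p(sign(e_full))
    pv <- suppressWarnings(min(p_sign, p_runs, na.rm = TRUE))
    if (!is.finite(pv)) pv <- NA_real_
    dir <- if (!n || is.na(pv) || pv > 0.05) "none"
           else if (np > n / 2) "under" else "over"
    data.frame(observable = ob, n = n, n_pos = np, p_sign = p_sign,
               p_runs = p_runs, p_value = pv, direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# two-sided normal-approximation Wald-Wolfowitz runs test on a sign vector
runs_test_p <- function(s) {
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n < 2) return(NA_real_)
  if (n1 == 0 || n2 == 0) return(NA_real_)  # one sign only: sign test's job
  r <- 1 + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(NA_real_)
  2 * stats::pnorm(-abs((r - mu) / sqrt(v)))
}
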