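#' Monte-Carlo marginal likelihood of a model
#'
#' Estimates the marginal likelihood
#' \eqn{P(Y | M) = \int_\Theta P(Y | \theta, M) p(\theta) d\theta}
#' by plain Monte Carlo over the declared prior: \eqn{\theta} is drawn
#' uniformly over the prior box (in log10 units by default, matching the
#' sampling boxes) and `exp(-J(theta))` averaged, computed stably via
#' log-sum-exp.  The Monte-Carlo standard error of the log10 estimate comes
#' from the delta method on the draw variance.
#'
#' @param model a `dynmodel`.
#' @param data a `ta_dataset`; an empty dataset gives marginal likelihood 1
#'   (log10 value 0) by the empty-product convention.
#' @param prior_box 2 x d box over the model's free parameters (rows `lo`,
#'   `hi`), in log10 units when `scale = "log10"`.
#' @param n_draws number of prior draws (1000 or more recommended).
#' @param seed integer seed.
#' @param scale `"log10"` (default) or `"linear"` prior parameterization.
#' @param costfn optional override of the cost function
#'   (`theta -> negative log-likelihood`); defaults to [ekf_cost()].
#' @param regions optional list of `ellipsoid_region`s (from
#'   [characterize()]): switches on the *stratified* estimator, which draws
#'   half the points uniformly from the box and half uniformly from inside
#'   the regions, and reweights by the exact mixture importance density.
#'   Plain Monte Carlo is hopeless when the high-likelihood basin occupies
#'   a tiny fraction of a wide prior box; the stratified draws put mass
#'   where the likelihood lives while the weights keep the estimate
#'   unbiased for the same normalized-uniform-prior integral.
#' @return `list(log10_ml, se, n_draws, n_finite)`; `log10_ml = -Inf` with
#'   a warning when every draw diverged.
#' @export
marginal_likelihood <- function(model, data, prior_box, n_draws = 1000L,
                                seed = 1L, scale = c("log10", "linear"),
                                costfn = NULL, regions = NULL) {
  scale <- match.arg(scale)
  box <- as_box(prior_box)
  d <- ncol(box)
  if (is.null(costfn))
    costfn <- function(th) ekf_cost(model, th, data)$value
  if (nrow(data) == 0)
    return(list(log10_ml = 0, se = 0, n_draws = 0L, n_finite = 0L))
  set.seed(seed)

  if (is.null(regions) || length(regions) == 0) {
    Z <- matrix(stats::runif(n_draws * d), n_draws, d)
    Z <- sweep(sweep(Z, 2, box[2, ] - box[1, ], "*"), 2, box[1, ], "+")
    logw <- rep(0, n_draws)                  # p/q = 1 for plain MC
  } else {
    draws <- stratified_draws(n_draws, box, regions)
    Z <- draws$Z
    logw <- draws$logw
  }
  colnames(Z) <- colnames(box)

  negJ <- apply(Z, 1, function(z) {
    th <- if (scale == "log10") 10^z else z
    names(th) <- colnames(box)
    -costfn(th)
  })
  ln_t <- negJ + logw                        # log of exp(-J) * p/q
  fin <- is.finite(ln_t)
  if (!any(fin)) {
    warning("all prior draws diverged; marginal likelihood is 0")
    return(list(log10_ml = -Inf, se = NA_real_, n_draws = n_draws, n_finite = 0L))
  }
  M <- max(ln_t[fin])
  a <- exp(ifelse(fin, ln_t - M, -Inf))      # in [0, 1]
  mean_a <- mean(a)
  log10_ml <- (M + log(mean_a)) / log(10)
  se <- stats::sd(a) / (mean_a * sqrt(n_draws) * log(10))
  list(log10_ml = log10_ml, se = se, n_draws = n_draws, n_finite = sum(fin))
}

# half-box, half-ellipsoid mixture draws in log10 space with exact mixture
# log importance weights log(p/q); ellipsoid draws falling outside the box
# are redrawn and the in-box fraction of each region is estimated from the
# rejection rate (entering the region's effective density)
stratified_draws <- function(n, box, regions) {
  d <- ncol(box)
  R <- length(regions)
  vol_box <- prod(box[2, ] - box[1, ])
  n_box <- ceiling(n / 2)
  n_ell <- n - n_box
  Zb <- matrix(stats::runif(n_box * d), n_box, d)
  Zb <- sweep(sweep(Zb, 2, box[2, ] - box[1, ], "*"), 2, box[1, ], "+")

  Ls <- lapply(regions, function(r) t(chol(r$shape + diag(1e-10, d))))
  # log volume of each (unclipped) ellipsoid in log10 units
  log_vol <- vapply(seq_len(R), function(i) {
    r <- regions[[i]]
    (d / 2) * log(pi) - lgamma(d / 2 + 1) + d * log(r$radius) +
      sum(log(diag(Ls[[i]])))
  }, numeric(1))

  per <- rep(floor(n_ell / R), R)
  if (n_ell - sum(per) > 0) per[seq_len(n_ell - sum(per))] <- per[1] + 1
  Ze <- NULL
  frac_in <- numeric(R)
  for (i in seq_len(R)) {
    r <- regions[[i]]
    got <- NULL; tries <- 0L; total <- 0L
    while (is.null(got) || nrow(got) < per[i]) {
      m <- max(per[i] * 2L, 32L)
      U <- matrix(stats::rnorm(m * d), m, d)
      U <- U / sqrt(rowSums(U^2))
      rad <- r$radius * stats::runif(m)^(1 / d)
      P <- sweep((U * rad) %*% t(Ls[[i]]), 2, r$center, "+")
      total <- total + m
      inb <- apply(P, 1, function(z) all(z >= box[1, ] & z <= box[2, ]))
      got <- rbind(got, P[inb, , drop = FALSE])
      tries <- tries + 1L
      if (tries > 200L) stop("ellipsoid region lies (almost) outside the box")
    }
    frac_in[i] <- max(nrow(got) / total, 1e-6)
    Ze <- rbind(Ze, got[seq_len(per[i]), , drop = FALSE])
  }
  Z <- rbind(Zb, Ze)

  # mixture density q(z) = 0.5/Vbox + 0.5 * mean_r [ 1{z in E_r} / (V_r f_r) ]
  log_q <- apply(Z, 1, function(z) {
    dens <- 0.5 / vol_box
    for (i in seq_len(R)) {
      r <- regions[[i]]
      md <- stats::mahalanobis(matrix(z, 1), r$center, r$shape + diag(1e-10, d))
      if (md <= r$radius^2)
        dens <- dens + 0.5 / R / (exp(log_vol[i]) * frac_in[i])
    }
    log(dens)
  })
  list(Z = Z, logw = -log(vol_box) - log_q)
}

#' Bayes factor between two models
#'
#' Difference of log10 marginal likelihoods; antisymmetric by construction,
#' so `BF(i, j) * BF(j, i) = 1` exactly.
#'
#' @param model_i,model_j `dynmodel`s.
#' @param data shared `ta_dataset`.
#' @param prior_i,prior_j prior boxes (see [marginal_likelihood()]).
#' @param n_draws,seed Monte-Carlo settings.  Both marginals use the same
#'   draw stream (common random numbers), so the Bayes factor of a model
#'   against itself is exactly 0 in log10 and `BF(i, j) = 1 / BF(j, i)`
#'   holds exactly.
#' @param regions_i,regions_j optional characterized regions enabling the
#'   stratified estimator per model (see [marginal_likelihood()]).
#' @return `list(log10_bf, se, ml_i, ml_j)`.
#' @export
bayes_factor <- function(model_i, model_j, data, prior_i, prior_j,
                         n_draws = 1000L, seed = 1L,
                         regions_i = NULL, regions_j = NULL) {
  mi <- marginal_likelihood(model_i, data, prior_i, n_draws, seed = seed,
                            regions = regions_i)
  mj <- marginal_likelihood(model_j, data, prior_j, n_draws, seed = seed,
                            regions = regions_j)
  list(log10_bf = mi$log10_ml - mj$log10_ml,
       se = sqrt(mi$se^2 + mj$se^2), ml_i = mi, ml_j = mj)
}

#' Posterior probabilities over a set of candidate models
#'
#' \eqn{p_i \propto prior_i \cdot P(Y | M_i)}, normalized; with equal model
#' priors the posterior ratio of two models equals their Bayes factor.
#'
#' @param models named list of `dynmodel`s.
#' @param data shared `ta_dataset`.
#' @param priors named list of prior boxes, one per model.
#' @param prior_model_probs prior model probabilities (default equal); must
#'   sum to 1.
#' @param n_draws,seed Monte-Carlo settings.
#' @param regions optional list (one entry per model, `NULL` entries
#'   allowed) of characterized regions enabling the stratified estimator.
#' @return a `model_comparison`: table of log10 marginal likelihoods with
#'   MC standard errors, posterior probabilities, and the pairwise log10
#'   Bayes factor matrix.
#' @export
posterior_probs <- function(models, data, priors, prior_model_probs = NULL,
                            n_draws = 1000L, seed = 1L, regions = NULL) {
  stopifnot(length(models) == length(priors))
  ids <- names(models) %||% paste0("M", seq_along(models))
  prior_model_probs <- prior_model_probs %||% rep(1 / length(models), length(models))
  if (abs(sum(prior_model_probs) - 1) > 1e-8)
    stop("prior model probabilities must sum to 1")
  mls <- vector("list", length(models))
  for (i in seq_along(models))
    mls[[i]] <- marginal_likelihood(models[[i]], data, priors[[i]],
                                    n_draws, seed = seed + i - 1L,
                                    regions = if (is.null(regions)) NULL
                                              else regions[[i]])
  l10 <- vapply(mls, `[[`, numeric(1), "log10_ml")
  se <- vapply(mls, `[[`, numeric(1), "se")
  lpost <- l10 * log(10) + log(prior_model_probs)
  M <- max(lpost[is.finite(lpost)])
  p <- exp(lpost - M)
  p[!is.finite(p)] <- 0
  p <- p / sum(p)
  bf <- outer(l10, l10, "-")
  dimnames(bf) <- list(ids, ids)
  structure(list(
    table = data.frame(model = ids, log10_ml = l10, mc_se = se,
                       prior = prior_model_probs, posterior = p,
                       stringsAsFactors = FALSE),
    log10_bf = bf, n_draws = n_draws, seed = seed,
    priors = priors
  ), class = "model_comparison")
}

#' Characterized high-likelihood regions for stratified evidence estimation
#'
#' Convenience wrapper: explores a model's parameter space ([explore()]),
#' characterizes the viable regions ([characterize()]) and returns the
#' ellipsoid list ready for the `regions` argument of
#' [marginal_likelihood()] / [posterior_probs()].  Falls back to `NULL`
#' (plain Monte Carlo) when no region can be characterized.
#'
#' @param model a `dynmodel`.
#' @param data a `ta_dataset`.
#' @param box log10 prior/sampling box.
#' @param seed integer seed.
#' @param settings [explore_settings()] for the exploration stage.
#' @param delta_orders viability band used to delimit the regions.
#' @return list of `ellipsoid_region`s, or `NULL`.
#' @export
evidence_regions <- function(model, data, box, seed = 1L,
                             settings = explore_settings(n_chains = 2L,
                                                         n_steps = 200L,
                                                         n_screen = 300L,
                                                         n_polish = 4L),
                             delta_orders = 5) {
  costfn <- function(th) ekf_cost(model, th, data)$value
  s <- explore(costfn, box, settings, seed = seed,
               rule = viability_rule("sde", delta_orders = delta_orders))
  if (!any(s$viable)) return(NULL)
  ch <- characterize(s, costfn, n_test = 50L)
  if (length(ch$regions) == 0) NULL else ch$regions
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d models, %d prior draws each\n",
              nrow(x$table), x$n_draws))
  tab <- x$table
  tab$log10_ml <- round(tab$log10_ml, 3)
  tab$mc_se <- signif(tab$mc_se, 3)
  tab$posterior <- signif(tab$posterior, 4)
  print(tab, row.names = FALSE)
  best <- tab$model[which.max(tab$posterior)]
  cat("highest posterior:", best, "\n")
  invisible(x)
}
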