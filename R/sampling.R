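#' Explore the viable parameter space
#'
#' Staged exploration in log10 parameter space.  Phase 1 screens the box
#' with a stratified Latin-hypercube design; the screening points double as
#' (i) seeds for the later stages and (ii) a uniform sample for estimating
#' the viable volume fraction.  A local Nelder-Mead polish of the best
#' screening points then anchors the viability cutoff at the approximate
#' global optimum.  Phase 2 runs multiple Metropolis-Hastings chains on the
#' flattened target `exp(-max(J(theta), cutoff))`, which is uniform over the
#' viable region once costs fall below the cutoff, so chains spread out over
#' viable plateaus instead of collapsing onto the optimum.  In SDE mode the
#' cutoff tracks the running best cost (`best + delta_orders * ln 10`) and
#' all evaluated points are re-classified against the final cutoff.
#'
#' All parameters must be positive; sampling is in log10 units and the box
#' is given in log10 units (`zero` diffusion is represented by the box lower
#' edge).
#'
#' @param costfn function `theta -> cost` taking a *natural-scale* named
#'   parameter vector and returning a finite cost or `Inf`.  Typically a
#'   closure over [ekf_cost()].
#' @param box 2 x d matrix (rows `lo`, `hi`) of log10 bounds, with
#'   parameter names as column names.
#' @param settings list; see [explore_settings()].
#' @param seed integer seed; the full sample is bit-reproducible.
#' @param rule a [viability_rule()] (SDE mode by default) or a fixed numeric
#'   cutoff (e.g. an ODE-mode threshold from [ode_threshold()]).
#' @return a `viable_sample`: log10 `points` (all evaluated), `costs`,
#'   `viable` flags, likelihood `weights`, `box`, final `cutoff`,
#'   `vol_fraction` (screening-based viable volume fraction of the box),
#'   acceptance rates and provenance.  Status `"no viable points"` when
#'   nothing passed.
#' @export
explore <- function(costfn, box, settings = explore_settings(), seed = 1L,
                    rule = viability_rule("sde")) {
  box <- as_box(box)
  d <- ncol(box)
  s <- utils::modifyList(explore_settings(), settings)
  set.seed(seed)

  # evaluation recorder: every cost evaluation anywhere in the run (screen,
  # polish, chains) becomes part of the returned sample
  rec <- new.env(parent = emptyenv())
  rec$pts <- matrix(NA_real_, 0, d)
  rec$costs <- numeric(0)
  rec$chain <- integer(0)
  add_rec <- function(z, cost, chain) {
    rec$pts <- rbind(rec$pts, z)
    rec$costs <- c(rec$costs, cost)
    rec$chain <- c(rec$chain, chain)
  }
  eval_cost <- function(z, chain = NA_integer_, record = TRUE) {
    z <- pmin(pmax(z, box[1, ]), box[2, ])
    th <- 10^z
    names(th) <- colnames(box)
    v <- costfn(th)
    if (!is.finite(v)) v <- Inf
    if (record) add_rec(z, v, chain)
    v
  }

  # phase 1: stratified LHS screening
  Z <- lhs::randomLHS(s$n_screen, d)
  Z <- sweep(sweep(Z, 2, box[2, ] - box[1, ], "*"), 2, box[1, ], "+")
  cost_scr <- apply(Z, 1, eval_cost, chain = 0L)

  fixed_cutoff <- is.numeric(rule)

  # phase 1b: local polish of the best screening points, so the viability
  # cutoff is anchored at the (approximate) global optimum rather than at
  # whatever the screening happened to hit
  nm2 <- function(z0, chain) {
    # Nelder-Mead with one restart (a fresh simplex escapes degenerate
    # collapse on ridge-shaped likelihood surfaces)
    o <- try(stats::optim(z0, eval_cost, chain = chain,
                          method = "Nelder-Mead",
                          control = list(maxit = s$polish_maxit)),
             silent = TRUE)
    if (!inherits(o, "try-error"))
      try(stats::optim(o$par, eval_cost, chain = chain,
                       method = "Nelder-Mead",
                       control = list(maxit = s$polish_maxit)),
          silent = TRUE)
    invisible(NULL)
  }
  if (s$n_polish > 0 && any(is.finite(cost_scr))) {
    ord0 <- order(cost_scr)
    for (i in seq_len(min(s$n_polish, sum(is.finite(cost_scr)))))
      nm2(Z[ord0[i], ], -1L)
  }

  cutoff <- if (fixed_cutoff) rule else {
    best <- suppressWarnings(min(rec$costs[is.finite(rec$costs)]))
    if (is.finite(best)) sde_cutoff(best, rule$delta_orders) else Inf
  }

  # phase 2: MH chains from the best points found so far
  ord <- order(rec$costs)
  dup <- duplicated(round(rec$pts[ord, , drop = FALSE], 6))
  starts <- ord[!dup][seq_len(min(s$n_chains, sum(!dup)))]
  CAP <- 1e10 # finite stand-in for +Inf in MH arithmetic
  acc_rates <- numeric(s$n_chains)
  n_chains_run <- length(starts)
  for (ci in seq_len(n_chains_run)) {
    z <- rec$pts[starts[ci], ]
    jz <- min(rec$costs[starts[ci]], CAP)
    sc <- s$prop_scale
    n_acc <- 0L
    for (it in seq_len(s$n_steps)) {
      zp <- z + stats::rnorm(d, 0, sc)
      zp <- reflect_box(zp, box)
      jp_raw <- eval_cost(zp, chain = ci)
      jp <- min(jp_raw, CAP)
      if (!fixed_cutoff && jp_raw < cutoff - rule$delta_orders * log(10))
        cutoff <- sde_cutoff(jp_raw, rule$delta_orders)
      # flattened target: exp(-max(J, cutoff))
      la <- max(jz, min(cutoff, CAP)) - max(jp, min(cutoff, CAP))
      if (la >= 0 || log(stats::runif(1)) < la) {
        z <- zp; jz <- jp; n_acc <- n_acc + 1L
      }
      if (s$adapt && it %% 50 == 0) {
        r <- n_acc / it
        sc <- sc * exp(0.5 * (r - s$target_accept))
        sc <- min(max(sc, 1e-3), max(box[2, ] - box[1, ]))
      }
    }
    acc_rates[ci] <- n_acc / s$n_steps
  }

  # final polish from the best point found anywhere, so the cutoff used for
  # classification is anchored at the sharpest optimum available
  if (s$n_polish > 0 && any(is.finite(rec$costs)))
    nm2(rec$pts[which.min(rec$costs), ], -2L)

  # corner probes: test elimination of the named (diffusion) parameters by
  # clamping each subset to the box floor and re-optimizing the remaining
  # dimensions.  Random-walk chains rarely wander into these corners on
  # their own, yet whether a corner holds a viable point is exactly the
  # question the diffusion diagnosis asks.
  if (!is.null(s$corner_ids) && any(is.finite(rec$costs))) {
    cid <- intersect(s$corner_ids, colnames(box))
    subsets <- list()
    for (k in seq_len(min(3L, length(cid))))
      subsets <- c(subsets, utils::combn(cid, k, simplify = FALSE))
    zbest <- rec$pts[which.min(rec$costs), ]
    names(zbest) <- colnames(box)
    for (ss in subsets) {
      zc <- zbest
      zc[ss] <- box[1, ss] + 0.25
      free <- setdiff(colnames(box), ss)
      fsub <- function(zf) {
        z <- zc
        z[free] <- zf
        eval_cost(z, chain = -3L)
      }
      # two starts: the incumbent's coordinates, and one with the other
      # clamp-candidates lifted to mid-box (the incumbent often sits with
      # all diffusion magnitudes tiny, far from the corner's own optimum)
      start2 <- zc
      other <- setdiff(cid, ss)
      if (length(other)) start2[other] <- colMeans(box)[other]
      for (st in list(zc[free], start2[free]))
        try(stats::optim(st, fsub, method = "Nelder-Mead",
                         control = list(maxit = s$corner_maxit)),
            silent = TRUE)
    }
  }

  pts <- rec$pts
  rownames(pts) <- NULL
  colnames(pts) <- colnames(box)
  out <- structure(list(
    points = pts, costs = rec$costs, box = box, chain = rec$chain,
    seed = seed, settings = s, n_screen = s$n_screen,
    acc_rates = acc_rates
  ), class = "viable_sample")
  # final classification against the fixed cutoff / the global best
  out <- classify_viable(out, rule)
  out$vol_fraction <- mean(out$viable[out$chain == 0L])
  out$status <- if (!any(out$viable)) "no viable points" else "ok"
  out
}

#' @rdname explore
#' @param n_chains,n_steps,n_screen,prop_scale,adapt,target_accept sampler
#'   settings: number of MH chains, steps per chain, LHS screening points,
#'   initial proposal SD in log10 units, whether to adapt the proposal
#'   scale, and the target acceptance rate.
#' @param n_polish,polish_maxit number of best screening points refined by
#'   Nelder-Mead before the chains start (anchors the viability cutoff at
#'   the approximate global optimum), and iterations per refinement.
#' @param corner_ids optional parameter names (typically the diffusion
#'   magnitudes) whose negligibility corners are probed explicitly: each
#'   subset (up to size 3) is clamped to the box floor and the remaining
#'   dimensions re-optimized, with every evaluation recorded in the sample.
#' @param corner_maxit Nelder-Mead iterations per corner probe.
#' @export
explore_settings <- function(n_chains = 8L, n_steps = 1000L, n_screen = 2000L,
                             prop_scale = 0.4, adapt = TRUE,
                             target_accept = 0.3, n_polish = 6L,
                             polish_maxit = 400L, corner_ids = NULL,
                             corner_maxit = 250L) {
  list(n_chains = n_chains, n_steps = n_steps, n_screen = n_screen,
       prop_scale = prop_scale, adapt = adapt, target_accept = target_accept,
       n_polish = n_polish, polish_maxit = polish_maxit,
       corner_ids = corner_ids, corner_maxit = corner_maxit)
}

as_box <- function(box) {
  if (is.list(box) && !is.null(box$lo)) {
    b <- rbind(lo = box$lo, hi = box$hi)
  } else {
    b <- as.matrix(box)
    if (nrow(b) != 2) stop("box must be a 2 x d matrix (rows lo, hi)")
  }
  if (is.null(colnames(b))) stop("box columns must be named after parameters")
  if (any(b[2, ] <= b[1, ])) stop("box upper bounds must exceed lower bounds")
  b
}

reflect_box <- function(z, box) {
  lo <- box[1, ]; hi <- box[2, ]
  span <- hi - lo
  z <- (z - lo) %% (2 * span)
  z <- ifelse(z > span, 2 * span - z, z)
  z + lo
}

#' @export
print.viable_sample <- function(x, ...) {
  cat(sprintf("<viable_sample> %d evaluated points in %d dims, %d viable (cutoff %.4g)\n",
              nrow(x$points), ncol(x$points), sum(x$viable), x$cutoff))
  if (!is.null(x$vol_fraction))
    cat(sprintf("  viable volume fraction of box (screening estimate): %.4g\n",
                x$vol_fraction))
  if (!is.null(x$status) && x$status != "ok") cat("  status:", x$status, "\n")
  invisible(x)
}

#' @export
summary.viable_sample <- function(object, ...) {
  v <- object$points[object$viable, , drop = FALSE]
  rng <- if (nrow(v)) apply(v, 2, range) else
    matrix(NA_real_, 2, ncol(object$points),
           dimnames = list(NULL, colnames(object$points)))
  rownames(rng) <- c("lo", "hi")
  out <- list(n_eval = nrow(object$points), n_viable = sum(object$viable),
              cutoff = object$cutoff, best = suppressWarnings(min(object$costs)),
              ranges = rng, vol_fraction = object$vol_fraction)
  class(out) <- "summary.viable_sample"
  out
}

#' @export
print.summary.viable_sample <- function(x, ...) {
  cat(sprintf("viable sample: %d / %d points viable, best cost %.6g, cutoff %.6g\n",
              x$n_viable, x$n_eval, x$best, x$cutoff))
  cat("marginal viable ranges (log10):\n")
  print(round(x$ranges, 3))
  invisible(x)
}

#' @export
plot.viable_sample <- function(x, dims = colnames(x$points)[1:2], ...) {
  pr <- project_sample(x, dims)
  graphics::plot(pr$points[, 1], pr$points[, 2], pch = 16, cex = 0.4,
                 col = grDevices::hcl.colors(100, "viridis")[
                   cut(pr$points[, "cost"], 100, labels = FALSE)],
                 xlab = dims[1], ylab = dims[2],
                 xlim = x$box[, dims[1]], ylim = x$box[, dims[2]], ...)
  invisible(x)
}

#' Characterize viable regions with ellipsoid expansions
#'
#' Clusters the viable points (single linkage in log10 space, cut at a
#' configurable gap), fits a covariance ellipsoid per cluster, and expands
#' each ellipsoid radius while uniform test draws inside keep a viable
#' fraction of at least `min_frac`.  Newly evaluated viable draws are
#' merged into the returned sample.
#'
#' @param sample a `viable_sample`.
#' @param costfn cost function as in [explore()].
#' @param cutoff cost cutoff (default: the sample's).
#' @param gap single-linkage cut height in log10 units.
#' @param n_test uniform draws per expansion step.
#' @param min_frac minimal viable fraction to accept an expansion.
#' @param expand radius growth factor per step.
#' @param max_steps cap on expansion steps per region.
#' @return `list(regions = list of ellipsoid_region, sample = updated
#'   sample)`; empty region list (with a `status` attribute) when there are
#'   too few viable points.
#' @export
characterize <- function(sample, costfn, cutoff = sample$cutoff, gap = 1.0,
                         n_test = 200L, min_frac = 0.5, expand = 1.25,
                         max_steps = 20L) {
  d <- ncol(sample$points)
  vidx <- which(sample$viable)
  if (length(vidx) < d + 1) {
    regions <- list()
    attr(regions, "status") <- "too few viable points"
    return(list(regions = regions, sample = sample))
  }
  V <- sample$points[vidx, , drop = FALSE]
  cl <- if (nrow(V) > 1) {
    stats::cutree(stats::hclust(stats::dist(V), method = "single"), h = gap)
  } else 1L

  eval_cost <- function(z) {
    th <- 10^z; names(th) <- colnames(sample$points)
    v <- costfn(th)
    if (!is.finite(v)) Inf else v
  }

  new_pts <- NULL; new_costs <- NULL
  regions <- list()
  for (g in sort(unique(cl))) {
    M <- V[cl == g, , drop = FALSE]
    ctr <- colMeans(M)
    Sh <- stats::cov(M)
    if (nrow(M) <= d || any(!is.finite(Sh)))
      Sh <- diag(d) * max(1e-4, stats::var(as.numeric(M)))
    Sh <- Sh + diag(1e-6, d)
    L <- t(chol(Sh))
    md <- sqrt(mahalanobis_sq(M, ctr, Sh))
    r <- max(md, 1e-3)
    for (step in seq_len(max_steps)) {
      r_try <- r * expand
      U <- draw_in_ellipsoid(n_test, ctr, L, r_try, sample$box)
      if (nrow(U) == 0) break
      cc <- apply(U, 1, eval_cost)
      ok <- is.finite(cc) & cc <= cutoff
      if (any(ok)) {
        new_pts <- rbind(new_pts, U[ok, , drop = FALSE])
        new_costs <- c(new_costs, cc[ok])
      }
      if (mean(ok) >= min_frac) r <- r_try else break
    }
    regions[[length(regions) + 1]] <- structure(
      list(center = ctr, shape = Sh, radius = r,
           members = vidx[cl == g], n_members = nrow(M)),
      class = "ellipsoid_region")
  }
  if (!is.null(new_pts)) {
    colnames(new_pts) <- colnames(sample$points)
    sample$points <- rbind(sample$points, new_pts)
    sample$costs <- c(sample$costs, new_costs)
    sample$chain <- c(sample$chain, rep(-1L, nrow(new_pts)))
    sample$viable <- c(sample$viable, rep(TRUE, nrow(new_pts)))
    sample$weights <- viability_weights(sample$costs, sample$viable)
  }
  list(regions = regions, sample = sample)
}

mahalanobis_sq <- function(X, center, S) {
  stats::mahalanobis(X, center, S)
}

# uniform draws in {z : (z-c)' S^-1 (z-c) <= r^2} intersected with the box
draw_in_ellipsoid <- function(n, center, L, r, box) {
  d <- length(center)
  U <- matrix(stats::rnorm(n * d), n, d)
  U <- U / sqrt(rowSums(U^2))
  rad <- r * stats::runif(n)^(1 / d)
  Z <- sweep(U * rad, 1, rep(1, n), "*") %*% t(L)
  Z <- sweep(Z, 2, center, "+")
  inbox <- apply(Z, 1, function(z) all(z >= box[1, ] & z <= box[2, ]))
  Z[inbox, , drop = FALSE]
}

#' @export
print.ellipsoid_region <- function(x, ...) {
  cat(sprintf("<ellipsoid_region> %d member points, radius %.3g, center:\n",
              x$n_members, x$radius))
  print(round(x$center, 3))
  invisible(x)
}

#' Project viable points onto selected parameter axes
#'
#' @param sample a `viable_sample`.
#' @param dims parameter names to project onto.
#' @param bins number of occupancy-grid bins per axis (2-D projections).
#' @return list with `points` (viable points restricted to `dims`, with a
#'   `cost` column) and, for 2-D projections, an `occupancy` matrix with
#'   `breaks`.
#' @export
project_sample <- function(sample, dims, bins = 20L) {
  if (!all(dims %in% colnames(sample$points)))
    stop("unknown parameter id(s): ",
         paste(setdiff(dims, colnames(sample$points)), collapse = ", "))
  V <- sample$points[sample$viable, dims, drop = FALSE]
  out <- list(points = cbind(V, cost = sample$costs[sample$viable]))
  if (length(dims) == 2) {
    bx <- seq(sample$box[1, dims[1]], sample$box[2, dims[1]], length.out = bins + 1)
    by <- seq(sample$box[1, dims[2]], sample$box[2, dims[2]], length.out = bins + 1)
    occ <- matrix(FALSE, bins, bins)
    if (nrow(V)) {
      ix <- pmin(pmax(findInterval(V[, 1], bx, all.inside = TRUE), 1), bins)
      iy <- pmin(pmax(findInterval(V[, 2], by, all.inside = TRUE), 1), bins)
      occ[cbind(ix, iy)] <- TRUE
    }
    out$occupancy <- occ
    out$breaks <- list(bx, by)
  }
  out
}

#' Likelihood-weighted prediction bands over the viable space
#'
#' For each grid time, the likelihood-weighted mean of the deterministic
#' model prediction across viable parameter points, plus the weighted
#' standard error of that mean,
#' \eqn{SE = \sqrt{\sum_i w_i^2 (x_i - \mu)^2} / \sum_i w_i}.
#'
#' @param model a `dynmodel`.
#' @param sample a `viable_sample` whose columns cover the model's free
#'   parameters.
#' @param grid prediction time grid (starting at `model$t0`).
#' @param subsample optional number of viable points to draw (weighted
#'   bookkeeping is preserved); the bundled studies use a few thousand.
#' @param seed seed for the subsample draw.
#' @param states return bands for all states (`TRUE`) or observables only.
#' @return data.frame `time, variable, mean, se`.
#' @export
weighted_prediction <- function(model, sample, grid, subsample = NULL,
                                seed = 1L, states = TRUE) {
  vidx <- which(sample$viable)
  if (!length(vidx)) stop("no viable points in the sample")
  if (!is.null(subsample) && length(vidx) > subsample) {
    set.seed(seed)
    vidx <- sample(vidx, subsample)
  }
  w <- sample$weights[vidx]
  w <- w / sum(w)
  vars <- if (states) model$state_names else names(model$obs_states)
  acc_m <- matrix(0, length(grid), length(vars))
  acc_s <- matrix(0, length(grid), length(vars))
  trajs <- vector("list", length(vidx))
  for (i in seq_along(vidx)) {
    th <- 10^sample$points[vidx[i], ]
    names(th) <- colnames(sample$points)
    tr <- simulate_ode(model, th[model$param_names], grid)
    X <- if (states) tr$states[, vars, drop = FALSE]
         else tr$states[, model$obs_states[vars], drop = FALSE]
    trajs[[i]] <- X
    acc_m <- acc_m + w[i] * X
  }
  for (i in seq_along(vidx))
    acc_s <- acc_s + (w[i] * (trajs[[i]] - acc_m))^2
  se <- sqrt(acc_s)
  out <- data.frame(
    time = rep(grid, times = length(vars)),
    variable = rep(vars, each = length(grid)),
    mean = as.numeric(acc_m), se = as.numeric(se))
  out
}
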