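#' Diagnose which diffusion terms are non-negligible over the viable space
#'
#' A diffusion magnitude is *eliminable* when the viable space contains a
#' point with that magnitude in the negligibility corner (within
#' `epsilon_log10` units of the box lower edge) while all other diffusion
#' magnitudes stay free.  Subsets of diffusion parameters are *jointly
#' eliminable* when a single viable witness has every member in the corner
#' simultaneously.  Equations whose diffusion can never be eliminated are
#' the candidates for structural model improvements.
#'
#' The negligibility heuristic (lowest `epsilon_log10` decade of the box)
#' automates what is otherwise a visual inspection of the viable-space
#' projections.
#'
#' @param sample a `viable_sample`.
#' @param sigma_ids names of the diffusion parameters among the sample's
#'   columns.
#' @param epsilon_log10 width of the negligibility corner above the box
#'   lower edge, in log10 units.
#' @param max_subset cap on the size of jointly-eliminable subsets searched
#'   (combinatorial guard).
#' @return a `diffusion_diagnosis`: per-sigma table (`eliminable`,
#'   marginal viable range), subset table with witness indices, and the
#'   thresholds used.  With an empty viable sample all flags are `NA`
#'   ("unknown").
#' @export
diagnose_diffusion <- function(sample, sigma_ids, epsilon_log10 = 1.0,
                               max_subset = 3L) {
  stopifnot(all(sigma_ids %in% colnames(sample$points)))
  V <- sample$points[sample$viable, , drop = FALSE]
  thr <- sample$box[1, sigma_ids] + epsilon_log10
  vidx <- which(sample$viable)

  subsets <- list()
  for (k in seq_len(min(max_subset, length(sigma_ids))))
    subsets <- c(subsets, utils::combn(sigma_ids, k, simplify = FALSE))

  rows <- lapply(subsets, function(ss) {
    if (nrow(V) == 0)
      return(data.frame(subset = paste(ss, collapse = "+"), size = length(ss),
                        eliminable = NA, witness = NA_integer_,
                        stringsAsFactors = FALSE))
    ok <- rep(TRUE, nrow(V))
    for (sg in ss) ok <- ok & V[, sg] <= thr[[sg]]
    wit <- if (any(ok)) vidx[which(ok)[which.min(sample$costs[vidx][ok])]] else NA_integer_
    data.frame(subset = paste(ss, collapse = "+"), size = length(ss),
               eliminable = any(ok), witness = wit, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  per_sigma <- data.frame(
    sigma = sigma_ids,
    eliminable = tab$eliminable[match(sigma_ids, tab$subset)],
    lo = if (nrow(V)) apply(V[, sigma_ids, drop = FALSE], 2, min) else NA_real_,
    hi = if (nrow(V)) apply(V[, sigma_ids, drop = FALSE], 2, max) else NA_real_,
    corner = unname(thr), stringsAsFactors = FALSE)

  structure(list(per_sigma = per_sigma, subsets = tab,
                 epsilon_log10 = epsilon_log10,
                 n_viable = nrow(V)),
            class = "diffusion_diagnosis")
}

#' @export
print.diffusion_diagnosis <- function(x, ...) {
  cat(sprintf("<diffusion_diagnosis> over %d viable points (corner: lowest %.2g decades)\n",
              x$n_viable, x$epsilon_log10))
  cat("per diffusion parameter:\n")
  print(x$per_sigma, row.names = FALSE)
  cat("subset eliminability:\n")
  print(x$subsets[, c("subset", "eliminable")], row.names = FALSE)
  invisible(x)
}

#' Infer the trajectory of a hidden mechanism over the viable space
#'
#' Runs the filter ([infer_states()]) at each viable parameter point (or a
#' seeded subsample) of an extended model with diffusion-driven auxiliary
#' states, and aggregates the auxiliary state across points into a
#' likelihood-weighted mean with a weighted standard error band.
#'
#' @param model_ext the extended `dynmodel` (at least one auxiliary /
#'   promoted state).
#' @param sample a `viable_sample` drawn on `model_ext`.
#' @param data the `ta_dataset` the sample was fitted to.
#' @param grid time grid for the inferred trajectory.
#' @param state name of the auxiliary state (default: the last state).
#' @param subsample optional cap on the number of viable points used.
#' @param seed seed for the subsample draw.
#' @return a `hidden_trajectory`: `time`, weighted `mean`, weighted `se`,
#'   and the number of viable points aggregated.
#' @export
infer_hidden <- function(model_ext, sample, data, grid, state = NULL,
                         subsample = 300L, seed = 1L) {
  state <- state %||% model_ext$state_names[n_states(model_ext)]
  if (!state %in% model_ext$state_names) stop("unknown state: ", state)
  vidx <- which(sample$viable)
  if (!length(vidx)) stop("no viable points in the sample")
  if (!is.null(subsample) && length(vidx) > subsample) {
    set.seed(seed)
    vidx <- sample(vidx, subsample)
  }
  w <- sample$weights[vidx]
  w <- w / sum(w)
  M <- matrix(NA_real_, length(grid), length(vidx))
  for (i in seq_along(vidx)) {
    th <- 10^sample$points[vidx[i], ]
    names(th) <- colnames(sample$points)
    tr <- try(infer_states(model_ext, th[model_ext$param_names], data, grid),
              silent = TRUE)
    if (!inherits(tr, "try-error")) M[, i] <- tr$states[, state]
  }
  ok <- which(colSums(is.na(M)) == 0)
  if (!length(ok)) stop("state inference failed at every viable point")
  M <- M[, ok, drop = FALSE]
  w <- w[ok] / sum(w[ok])
  mu <- as.numeric(M %*% w)
  se <- sqrt(as.numeric(((M - mu)^2) %*% (w^2)))
  structure(list(time = grid, mean = mu, se = se, n = length(ok),
                 state = state),
            class = "hidden_trajectory")
}

#' @export
print.hidden_trajectory <- function(x, ...) {
  cat(sprintf("<hidden_trajectory> state '%s' on %d grid points (aggregated over %d viable points)\n",
              x$state, length(x$time), x$n))
  invisible(x)
}

#' @export
plot.hidden_trajectory <- function(x, ...) {
  graphics::plot(x$time, x$mean, type = "l", lwd = 2,
                 ylim = range(c(x$mean - x$se, x$mean + x$se)),
                 xlab = "time", ylab = x$state, ...)
  graphics::polygon(c(x$time, rev(x$time)),
                    c(x$mean - x$se, rev(x$mean + x$se)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$time, x$mean, lwd = 2)
  invisible(x)
}

#' Rank simple reaction-term templates against an inferred hidden trajectory
#'
#' Least-squares fits each closed-form template family to the hidden mean
#' (weighted by inverse squared standard error) as a function of one
#' covariate trajectory, and ranks the families by a small-sample-corrected
#' information score (residual-based, penalized by parameter count).  The
#' intent is Occam's razor on candidate deterministic replacement terms:
#' the simplest form that tracks the inferred mechanism wins.
#'
#' Template families over a covariate `z`: `constant` `a`; `linear` `a*z`;
#' `saturating` `a/(b+z)`; `switch` `a*1{z<b}`.
#'
#' @param hidden a `hidden_trajectory`.
#' @param covariates named list of `ta_trajectory`-like objects (or
#'   data.frames with `time` plus a value column) providing candidate
#'   covariates `z(t)`; linearly interpolated onto the hidden grid.
#' @param templates subset of the four family names.
#' @return data.frame ranked by score: `family`, `covariate`, `a`, `b`,
#'   `score`, `rss`, `n_par`.
#' @export
match_term <- function(hidden, covariates,
                       templates = c("constant", "linear", "saturating", "switch")) {
  templates <- match.arg(templates, several.ok = TRUE)
  y <- hidden$mean
  n <- length(y)
  # inverse-SE^2 weights, floored at 2% of the trajectory's dynamic range so
  # pinned points (e.g. a fixed initial value with SE 0) cannot dominate
  se_floor <- max(0.02 * diff(range(y)), 1e-12)
  w <- 1 / pmax(hidden$se, se_floor)^2
  w <- w / mean(w)

  # degenerate (constant) trajectory: only the constant family applies
  if (stats::sd(y) < 1e-10 * max(1, mean(abs(y)))) {
    a <- sum(w * y) / sum(w)
    return(data.frame(family = "constant", covariate = NA_character_,
                      a = a, b = NA_real_,
                      score = aicc(sum(w * (y - a)^2), n, 1),
                      rss = sum(w * (y - a)^2), n_par = 1,
                      stringsAsFactors = FALSE))
  }

  cov_on_grid <- function(cv) {
    if (inherits(cv, "ta_trajectory"))
      return(stats::approx(cv$times, cv$states[, 1], xout = hidden$time, rule = 2)$y)
    if (is.data.frame(cv))
      return(stats::approx(cv$time, cv[[setdiff(names(cv), "time")[1]]],
                           xout = hidden$time, rule = 2)$y)
    if (is.numeric(cv) && length(cv) == n) return(cv)
    stop("covariate must be a trajectory, data.frame or numeric vector on the grid")
  }

  fits <- list()
  for (nm in names(covariates)) {
    z <- cov_on_grid(covariates[[nm]])
    for (fam in templates) {
      f <- fit_template(fam, z, y, w)
      if (is.null(f)) next
      fits[[length(fits) + 1]] <- data.frame(
        family = fam, covariate = if (fam == "constant") NA_character_ else nm,
        a = f$a, b = f$b, score = aicc(f$rss, n, f$k), rss = f$rss,
        n_par = f$k, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, fits)
  out <- out[!duplicated(paste(out$family, out$covariate)), , drop = FALSE]
  out[order(out$score), , drop = FALSE]
}

aicc <- function(rss, n, k) {
  rss <- max(rss, 1e-300)
  n * log(rss / n) + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
}

fit_template <- function(family, z, y, w) {
  switch(family,
    constant = {
      a <- sum(w * y) / sum(w)
      list(a = a, b = NA_real_, rss = sum(w * (y - a)^2), k = 1)
    },
    linear = {
      a <- sum(w * y * z) / sum(w * z^2)
      list(a = a, b = NA_real_, rss = sum(w * (y - a * z)^2), k = 1)
    },
    saturating = {
      if (min(z) < 0) return(NULL)
      rng <- range(z[z > 0])
      if (!all(is.finite(rng)) || rng[2] <= 0) return(NULL)
      obj <- function(lb) {
        b <- 10^lb
        g <- 1 / (b + z)
        a <- sum(w * y * g) / sum(w * g^2)
        sum(w * (y - a * g)^2)
      }
      lo <- log10(max(rng[1] * 1e-3, 1e-12)); hi <- log10(rng[2] * 1e3)
      op <- stats::optimize(obj, c(lo, hi))
      b <- 10^op$minimum
      g <- 1 / (b + z)
      a <- sum(w * y * g) / sum(w * g^2)
      list(a = a, b = b, rss = sum(w * (y - a * g)^2), k = 2)
    },
    switch = {
      cand <- sort(unique(z))
      if (length(cand) < 2) return(NULL)
      mids <- (cand[-1] + cand[-length(cand)]) / 2
      best <- NULL
      for (b in mids) {
        g <- as.numeric(z < b)
        if (sum(w * g^2) == 0) next
        a <- sum(w * y * g) / sum(w * g^2)
        rss <- sum(w * (y - a * g)^2)
        if (is.null(best) || rss < best$rss) best <- list(a = a, b = b, rss = rss, k = 2)
      }
      best
    })
}
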