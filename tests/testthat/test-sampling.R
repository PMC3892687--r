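# analytic cost surfaces in log10 space
quad_cost <- function(th) sum(log10(th)^2)
two_well_cost <- function(th) {
  z <- log10(th)
  if (abs(z[1]) < 0.5) return(Inf)            # impassable ridge
  c1 <- c(-1.5, 0); c2 <- c(1.5, 0)
  5 * min(sum((z - c1)^2), sum((z - c2)^2))
}

test_that("exploration recovers the viable ball and its volume fraction", {
  box <- cbind(a = c(-2, 2), b = c(-2, 2), c = c(-2, 2))
  rownames(box) <- c("lo", "hi")
  s <- explore(quad_cost, box,
               settings = explore_settings(n_chains = 4, n_steps = 500,
                                           n_screen = 20000),
               seed = 3, rule = 1.0)           # fixed cutoff: unit ball
  V <- s$points[s$viable, , drop = FALSE]
  expect_true(all(rowSums(V^2) <= 1 + 1e-9))   # viable set inside unit ball
  truth <- (4 / 3 * pi) / 4^3
  expect_lt(abs(s$vol_fraction - truth) / truth, 0.2)
  expect_identical(s$status, "ok")
})

test_that("exploration is bit-reproducible for a fixed seed", {
  box <- cbind(a = c(-2, 2), b = c(-2, 2))
  rownames(box) <- c("lo", "hi")
  st <- explore_settings(n_chains = 2, n_steps = 200, n_screen = 200)
  s1 <- explore(quad_cost, box, st, seed = 42, rule = 1.0)
  s2 <- explore(quad_cost, box, st, seed = 42, rule = 1.0)
  expect_identical(s1$points, s2$points)
  expect_identical(s1$costs, s2$costs)
})

test_that("an always-infinite cost yields an explicit empty-sample status", {
  box <- cbind(a = c(-1, 1))
  rownames(box) <- c("lo", "hi")
  s <- explore(function(th) Inf, box,
               explore_settings(n_chains = 1, n_steps = 50, n_screen = 50),
               seed = 1, rule = viability_rule("sde"))
  expect_identical(s$status, "no viable points")
  expect_false(any(s$viable))
})

test_that("ellipsoid characterization finds one isotropic region or two wells", {
  box <- cbind(a = c(-2, 2), b = c(-2, 2))
  rownames(box) <- c("lo", "hi")
  s <- explore(quad_cost, box,
               explore_settings(n_chains = 4, n_steps = 400, n_screen = 2000),
               seed = 5, rule = 1.0)
  ch <- characterize(s, quad_cost)
  expect_length(ch$regions, 1)
  ev <- eigen(ch$regions[[1]]$shape, symmetric = TRUE)$values
  axis_ratio <- sqrt(ev[1] / ev[2])
  expect_gt(axis_ratio, 1 / 1.4)               # isotropy of the spherical well
  expect_lt(axis_ratio, 1.4)

  s2 <- explore(two_well_cost, box,
                explore_settings(n_chains = 6, n_steps = 400, n_screen = 3000),
                seed = 6, rule = 1.0)
  ch2 <- characterize(s2, two_well_cost)
  expect_length(ch2$regions, 2)
  # expansion never swallows the infinite ridge: merged points stay viable
  expect_true(all(ch2$sample$costs[ch2$sample$viable] <= 1.0))

  # empty viable sample: empty region list with a status
  s3 <- classify_viable(s2, -Inf)
  ch3 <- characterize(s3, two_well_cost)
  expect_length(ch3$regions, 0)
  expect_match(attr(ch3$regions, "status"), "too few")
})

test_that("reported viable points re-classify identically from scratch", {
  box <- cbind(a = c(-2, 2), b = c(-2, 2))
  rownames(box) <- c("lo", "hi")
  s <- explore(quad_cost, box,
               explore_settings(n_chains = 2, n_steps = 300, n_screen = 500),
               seed = 9, rule = 1.0)
  recomputed <- apply(10^s$points, 1, quad_cost)
  expect_identical(recomputed <= s$cutoff, s$viable)
})

test_that("projections restrict viable points and build occupancy grids", {
  box <- cbind(a = c(-2, 2), b = c(-2, 2), c = c(-2, 2))
  rownames(box) <- c("lo", "hi")
  s <- explore(quad_cost, box,
               explore_settings(n_chains = 2, n_steps = 200, n_screen = 1000),
               seed = 4, rule = 1.0)
  pr_all <- project_sample(s, c("a", "b", "c"))
  expect_equal(unname(pr_all$points[, 1:3]),
               unname(s$points[s$viable, , drop = FALSE]))
  pr2 <- project_sample(s, c("a", "b"), bins = 8)
  expect_identical(dim(pr2$occupancy), c(8L, 8L))
  # the ball never reaches the box corner cells
  expect_false(pr2$occupancy[1, 1])
  expect_error(project_sample(s, "nope"), "unknown parameter")
})

test_that("weighted prediction bands collapse and average as expected", {
  decay <- dyn_model("x", "a", function(x, u, theta, t) -theta[["a"]] * x,
                     x0 = c(x = 1), name = "decay")
  grid <- seq(0, 2, 0.5)
  mk_sample <- function(zs, weights) {
    structure(list(points = matrix(zs, ncol = 1,
                                   dimnames = list(NULL, "a")),
                   costs = rep(0, length(zs)),
                   viable = rep(TRUE, length(zs)),
                   weights = weights, box = cbind(a = c(-2, 2))),
              class = "viable_sample")
  }
  one <- weighted_prediction(decay, mk_sample(0, 1), grid)
  expect_equal(one$mean, exp(-grid), tolerance = 1e-7)
  expect_true(all(one$se == 0))

  two <- weighted_prediction(decay, mk_sample(c(0, log10(2)), c(0.5, 0.5)), grid)
  expect_equal(two$mean, (exp(-grid) + exp(-2 * grid)) / 2, tolerance = 1e-7)
})
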