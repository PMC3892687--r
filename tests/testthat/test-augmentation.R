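fake_sample <- function(points, costs, box) {
  v <- is.finite(costs) & costs <= max(costs[is.finite(costs)])
  s <- structure(list(points = points, costs = costs, box = box),
                 class = "viable_sample")
  classify_viable(s, max(costs[is.finite(costs)]) + 1)
}

test_that("diffusion diagnosis reports individual and joint eliminability", {
  box <- cbind(sigma_1 = c(-6, 2), sigma_2 = c(-6, 2))
  rownames(box) <- c("lo", "hi")
  # boomerang-like viable set: each sigma reaches its corner alone, never both
  pts <- rbind(c(-6, 0), c(-5.5, -1), c(0, -6), c(-1, -5.5), c(-2, -2))
  colnames(pts) <- colnames(box)
  s <- fake_sample(pts, rep(0, 5), box)
  dg <- diagnose_diffusion(s, c("sigma_1", "sigma_2"), epsilon_log10 = 1)
  expect_true(all(dg$per_sigma$eliminable))
  joint <- dg$subsets[dg$subsets$subset == "sigma_1+sigma_2", ]
  expect_false(joint$eliminable)

  # add a witness in the joint corner: now jointly eliminable, with a
  # verifiable stored witness index
  pts2 <- rbind(pts, c(-5.8, -5.9))
  s2 <- fake_sample(pts2, rep(0, 6), box)
  dg2 <- diagnose_diffusion(s2, c("sigma_1", "sigma_2"))
  joint2 <- dg2$subsets[dg2$subsets$subset == "sigma_1+sigma_2", ]
  expect_true(joint2$eliminable)
  w <- joint2$witness
  expect_true(all(s2$points[w, ] <= box[1, ] + 1))
  expect_true(s2$viable[w])

  # empty viable sample: all flags unknown
  s3 <- classify_viable(s, -Inf)
  dg3 <- diagnose_diffusion(s3, c("sigma_1", "sigma_2"))
  expect_true(all(is.na(dg3$per_sigma$eliminable)))
})

test_that("hidden-state inference aggregates viable points into a band", {
  b <- pk_model("extended")
  d <- pk_generate(11)
  box <- b$box
  # small hand-built sample around plausible values
  set.seed(13)
  zs <- cbind(C_L = log10(2) + rnorm(6, 0, 0.05),
              V = log10(5) + rnorm(6, 0, 0.05),
              sigma_k_A = runif(6, -1.3, -1),
              k_A0 = log10(0.2) + rnorm(6, 0, 0.1))
  costs <- apply(zs, 1, function(z)
    ekf_cost(b$model, setNames(10^z, colnames(zs)), d)$value)
  s <- structure(list(points = zs, costs = costs, box = box),
                 class = "viable_sample")
  s <- classify_viable(s, max(costs) + 1)
  grid <- seq(0, 10, 0.5)
  hid <- infer_hidden(b$model, s, d, grid, state = "k_A")
  expect_s3_class(hid, "hidden_trajectory")
  expect_identical(hid$time, grid)
  expect_true(all(is.finite(hid$mean)))
  expect_true(all(hid$se >= 0))

  # zero auxiliary diffusion across the sample: flat at the initial value
  zs0 <- zs; zs0[, "sigma_k_A"] <- -300   # 10^-300, numerically zero
  zs0[, "k_A0"] <- log10(0.2)
  costs0 <- rep(0, nrow(zs0))
  s0 <- classify_viable(structure(list(points = zs0, costs = costs0, box = box),
                                  class = "viable_sample"), 1)
  hid0 <- infer_hidden(b$model, s0, d, grid, state = "k_A")
  expect_lt(max(abs(hid0$mean - 0.2)), 1e-6)

  expect_error(infer_hidden(pk_model("linear_sde")$model, s, d, grid,
                            state = "k_A"), "unknown state")
})

test_that("term matching recovers a planted saturating law and respects Occam", {
  tt <- seq(0, 10, 0.25)
  Qtr <- new_trajectory(tt, matrix(10 * exp(-0.4 * tt), ncol = 1,
                                   dimnames = list(NULL, "Q")))
  a_true <- 2; b_true <- 1.5
  set.seed(31)
  y <- a_true / (b_true + Qtr$states[, 1]) + rnorm(length(tt), 0, 1e-4)
  hid <- structure(list(time = tt, mean = y, se = rep(1e-3, length(tt)),
                        n = 10, state = "k_A"), class = "hidden_trajectory")
  rk <- match_term(hid, list(Q = Qtr))
  expect_identical(rk$family[1], "saturating")
  expect_lt(abs(rk$a[1] - a_true) / a_true, 0.05)
  expect_lt(abs(rk$b[1] - b_true) / b_true, 0.05)
  # saturating beats linear in particular
  expect_lt(rk$score[rk$family == "saturating"][1],
            rk$score[rk$family == "linear"][1])

  # degenerate flat trajectory: only the constant family
  hidc <- structure(list(time = tt, mean = rep(3, length(tt)),
                         se = rep(1e-3, length(tt)), n = 10, state = "k_A"),
                    class = "hidden_trajectory")
  rkc <- match_term(hidc, list(Q = Qtr))
  expect_identical(rkc$family, "constant")
  expect_equal(rkc$a, 3, tolerance = 1e-9)
})

test_that("term ranking is invariant to affine rescaling of the time grid", {
  tt <- seq(0, 10, 0.5)
  z <- 5 * exp(-0.3 * tt)
  set.seed(7)
  y <- 1 / (1 + z) + rnorm(length(tt), 0, 0.01)
  se <- rep(0.02, length(tt))
  mk <- function(times) {
    hid <- structure(list(time = times, mean = y, se = se, n = 5, state = "s"),
                     class = "hidden_trajectory")
    cov <- data.frame(time = times, value = z)
    match_term(hid, list(z = cov))
  }
  r1 <- mk(tt)
  r2 <- mk(100 + 7 * tt)        # affine rescaling of both grids
  expect_identical(paste(r1$family, r1$covariate),
                   paste(r2$family, r2$covariate))
  expect_equal(r1$score, r2$score, tolerance = 1e-10)
})
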