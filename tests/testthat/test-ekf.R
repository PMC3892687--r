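test_that("EKF equals the exact scalar Kalman recursion on a 1-state model", {
  skip_if_not_installed("Matrix")
  a <- 0.8; sig <- 0.3
  A <- matrix(-a, 1, 1)
  m <- linear_dynmodel(A, x0 = 1, sig_names = "sigma")
  set.seed(21)
  times <- seq(0.5, 4, 0.5)
  y <- exp(-a * times) + rnorm(length(times), 0, 0.2)
  d <- make_dataset(times, y, 0.2, "x1")
  fit <- ekf_filter(m, c(sigma = sig), d, engine = "r")
  orc <- kalman_oracle(A, sig, matrix(1, 1, 1), 1, 0, times,
                       matrix(y, ncol = 1), matrix(0.2, length(times), 1))
  expect_equal(fit$nll, orc$nll, tolerance = 1e-6)
  expect_equal(unname(fit$m_upd[, 1]), orc$means[, 1], tolerance = 1e-6)
})

test_that("EKF matches the matrix-exponential Kalman oracle on random linear models", {
  skip_if_not_installed("Matrix")
  for (s in 1:12) {
    sys <- random_linear_system(n = 2, p = 1, seed = 100 + s)
    m <- linear_dynmodel(sys$A, sys$x0,
                         sig_names = paste0("s", 1:2),
                         obs_states = setNames(sys$obs, paste0("x", sys$obs)))
    H <- matrix(0, 1, 2); H[1, sys$obs] <- 1
    ytrue <- t(vapply(sys$times, function(t)
      as.numeric(as.matrix(Matrix::expm(sys$A * t)) %*% sys$x0), numeric(2)))
    set.seed(200 + s)
    y <- ytrue[, sys$obs] + rnorm(length(sys$times), 0, 0.15)
    d <- make_dataset(sys$times, y, 0.15, paste0("x", sys$obs))
    fit <- ekf_filter(m, setNames(sys$sig, paste0("s", 1:2)), d, engine = "r")
    orc <- kalman_oracle(sys$A, sys$sig, H, sys$x0, 0, sys$times,
                         matrix(y, ncol = 1),
                         matrix(0.15, length(sys$times), 1))
    expect_equal(fit$nll, orc$nll, tolerance = 1e-6)
    expect_lt(max(abs(fit$m_upd - orc$means)) / max(1, max(abs(orc$means))), 1e-6)
  }
})

test_that("zero diffusion plus exact data gives zero innovations and the constant cost", {
  b <- pk_model("mm_final")
  th0 <- c(V_max = 2, K_m = 1, C_L = 2, V = 5, sigma_Q = 0, sigma_C = 0)
  d <- pk_generate(1, rho = 0)        # noiseless outputs (placeholder sd 1)
  fit <- ekf_filter(b$model, th0, d)
  expect_lt(max(abs(fit$innovation), na.rm = TRUE), 1e-6)
  expect_equal(fit$nll, sum(0.5 * log(2 * pi * d$sd^2)), tolerance = 1e-6)
})

test_that("filter limits: large diffusion tracks data, zero diffusion tracks ODE", {
  b <- pk_model("mm_final")
  d <- pk_generate(2)
  th_big <- c(V_max = 2, K_m = 2, C_L = 2, V = 5, sigma_Q = 50, sigma_C = 50)
  fit_big <- ekf_filter(b$model, th_big, d)
  yv <- fit_big$y[, "C"]
  expect_lt(max(abs(fit_big$m_upd[, "C"] - yv)), 1e-3 * max(abs(yv)))

  th0 <- c(V_max = 1.5, K_m = 3, C_L = 2.5, V = 4, sigma_Q = 0, sigma_C = 0)
  fit0 <- ekf_filter(b$model, th0, d)
  ode <- simulate_ode(b$model, th0, c(b$model$t0, fit0$times))
  expect_lt(max(abs(fit0$m_pred[, "C"] - ode$states[-1, "C"])), 1e-5)
})

test_that("cost is deterministic, finite-or-Inf, and discriminates parameters", {
  b <- pk_model("mm_final")
  d <- pk_generate(4)
  th <- c(V_max = 2, K_m = 1, C_L = 2, V = 5, sigma_Q = 0.01, sigma_C = 0.01)
  c1 <- ekf_cost(b$model, th, d)
  c2 <- ekf_cost(b$model, th, d)
  expect_identical(c1$value, c2$value)   # bit-identical
  expect_false(c1$diverged)

  # true parameters beat a x100 perturbation in one kinetic parameter
  wins <- 0L
  for (s in 1:20) {
    ds <- pk_generate(1000 + s)
    good <- ekf_cost(b$model, th, ds)$value
    bad <- ekf_cost(b$model, replace(th, "V_max", th[["V_max"]] * 100), ds)$value
    wins <- wins + (good <= bad)
  }
  expect_gte(wins, 18L)
})

test_that("a single observation reproduces the one-step closed form", {
  m <- constant_dynmodel(x0 = 2)
  m <- reformulate_as_sde(m, "sigma")
  d <- make_dataset(1, 2.5, 0.4, "x")
  sig <- 0.7
  fit <- ekf_filter(m, c(sigma = sig), d, engine = "r")
  S <- sig^2 * 1 + 0.4^2            # P grows as sigma^2 * t for zero drift
  e <- 2.5 - 2
  expect_equal(fit$nll, 0.5 * (e^2 / S + log(2 * pi * S)), tolerance = 1e-7)
})

test_that("updates never decrease precision on the observed component", {
  b <- pk_model("mm_final")
  d <- pk_generate(5)
  th <- c(V_max = 2, K_m = 2, C_L = 2, V = 5, sigma_Q = 0.3, sigma_C = 0.2)
  fit <- ekf_filter(b$model, th, d)
  expect_true(all(fit$P_upd_diag[, "C"] <= fit$P_pred_diag[, "C"] + 1e-12))
})

test_that("Kalman gain vanishes for huge measurement noise and saturates for tiny", {
  b <- pk_model("mm_final")
  th <- c(V_max = 2, K_m = 2, C_L = 2, V = 5, sigma_Q = 0.2, sigma_C = 0.2)
  base <- pk_generate(6)
  big <- ta_dataset(transform(as.data.frame(base), sd = 1e6))
  small <- ta_dataset(transform(as.data.frame(base), sd = 1e-8))
  fit_big <- ekf_filter(b$model, th, big)
  # K -> 0: update leaves the mean unchanged
  expect_lt(max(abs(fit_big$m_upd - fit_big$m_pred)), 1e-4)
  fit_small <- ekf_filter(b$model, th, small)
  # m+ -> y on the observed subspace
  expect_lt(max(abs(fit_small$m_upd[, "C"] - fit_small$y[, "C"])), 1e-6)
})

test_that("compiled and reference filter implementations agree", {
  cases <- list(
    list(b = pk_model("linear_sde"),
         th = c(k_A = 0.2, C_L = 2, V = 5, sigma_Q = 0.1, sigma_C = 0.05),
         d = pk_generate(7)),
    list(b = pk_model("extended_full"),
         th = c(C_L = 2, V = 5, sigma_Q = 0.1, sigma_C = 0.02,
                sigma_k_A = 0.05, k_A0 = 0.2),
         d = pk_generate(7)),
    list(b = gln_model("rmm"),
         th = c(V_max = 3, K_m = 2.5, V_2 = 6, K_2 = 2.5, k_w = 0.05, D = 0.08),
         d = gln_generate(7)),
    list(b = gln_model("mm_ext_W"),
         th = c(V_max = 3, K_m = 2.5, V_2 = 6, K_2 = 2.5, D = 0.08,
                sigma_Q = 0.05, sigma_C = 0.3, sigma_W = 0.02),
         d = gln_generate(7)))
  for (cs in cases) {
    c_cpp <- ekf_cost(cs$b$model, cs$th, cs$d, engine = "cpp")
    c_r <- ekf_cost(cs$b$model, cs$th, cs$d, engine = "r")
    expect_equal(c_cpp$value, c_r$value, tolerance = 1e-6)
  }
})

test_that("state inference records filtered moments on the requested grid", {
  b <- pk_model("extended")
  th <- c(C_L = 2, V = 5, sigma_k_A = 0.05, k_A0 = 0.2)
  d <- pk_generate(8)
  grid <- seq(0, 10, 0.5)
  tr <- infer_states(b$model, th, d, grid)
  expect_identical(tr$times, grid)
  expect_true(all(is.finite(tr$states)))
  expect_true(all(is.finite(tr$meta$var)))

  # auxiliary state with zero diffusion stays at its init
  th0 <- replace(th, "sigma_k_A", 0)
  tr0 <- infer_states(b$model, th0, d, grid)
  expect_lt(max(abs(tr0$states[, "k_A"] - 0.2)), 1e-8)

  # linear-Gaussian case: filtered means match the oracle on the obs grid
  skip_if_not_installed("Matrix")
  sys <- random_linear_system(n = 2, p = 1, seed = 77)
  m <- linear_dynmodel(sys$A, sys$x0, sig_names = paste0("s", 1:2),
                       obs_states = setNames(sys$obs, paste0("x", sys$obs)))
  set.seed(78)
  y <- rnorm(length(sys$times))
  d2 <- make_dataset(sys$times, y, 0.2, paste0("x", sys$obs))
  tr2 <- infer_states(m, setNames(sys$sig, paste0("s", 1:2)), d2, sys$times)
  H <- matrix(0, 1, 2); H[1, sys$obs] <- 1
  orc <- kalman_oracle(sys$A, sys$sig, H, sys$x0, 0, sys$times,
                       matrix(y, ncol = 1), matrix(0.2, length(sys$times), 1))
  expect_lt(max(abs(tr2$states - orc$means)) / max(1, max(abs(orc$means))), 1e-6)
})

test_that("divergent parameter points yield +Inf cost, not an error", {
  b <- pk_model("linear_sde")
  d <- pk_generate(9)
  res <- ekf_cost(b$model,
                  c(k_A = 1e8, C_L = 1e-8, V = 1e-8, sigma_Q = 1e4, sigma_C = 1e4),
                  d)
  expect_true(is.infinite(res$value) || is.finite(res$value))
  expect_false(is.nan(res$value))
  # negative sigma is invalid, reported as +Inf for sampler robustness
  expect_true(is.infinite(
    ekf_cost(b$model, c(k_A = 1, C_L = 1, V = 1, sigma_Q = -1, sigma_C = 0), d)$value))
})

test_that("ekf_fit methods expose innovations, fitted values and summaries", {
  b <- pk_model("mm_final")
  th <- c(V_max = 2, K_m = 2, C_L = 2, V = 5, sigma_Q = 0.05, sigma_C = 0.02)
  d <- pk_generate(10)
  fit <- ekf_filter(b$model, th, d)
  expect_s3_class(fit, "ekf_fit")
  expect_equal(dim(residuals(fit)), c(20, 1))
  expect_equal(unname(logLik(fit))[1], -fit$nll)
  s <- summary(fit)
  expect_s3_class(s, "summary.ekf_fit")
  expect_output(print(fit), "negative log-likelihood")
})
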