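test_that("ODE simulation reproduces closed-form solutions", {
  decay <- dyn_model("x", "a", function(x, u, theta, t) -theta[["a"]] * x,
                     x0 = c(x = 1), name = "decay")
  tr <- simulate_ode(decay, c(a = 1), c(0, 0.5, 1))
  expect_equal(unname(tr$states[1, "x"]), 1)               # exactly the initial state
  expect_equal(unname(tr$states[3, "x"]), exp(-1), tolerance = 1e-7)

  still <- dyn_model("x", character(0), function(x, u, theta, t) 0,
                     x0 = c(x = 3.7), name = "still")
  tr2 <- simulate_ode(still, numeric(0), seq(0, 5, 1))
  expect_true(all(tr2$states[, "x"] == 3.7 | abs(tr2$states[, "x"] - 3.7) < 1e-10))
})

test_that("PK truth trajectory matches an independently coded RK4 oracle", {
  b <- pk_model("truth")
  th <- c(V_max = 2, K_m = 2, C_L = 2, V = 5)
  times <- seq(0, 10, 0.5)
  tr <- simulate_ode(b$model, th, times)
  f <- function(t, x) {
    r1 <- th[["V_max"]] * x[1] / (th[["K_m"]] + x[1])
    c(-r1, r1 / th[["V"]] - th[["C_L"]] / th[["V"]] * x[2])
  }
  ref <- rk4_oracle(f, c(10, 0), times)
  expect_lt(max(abs(tr$states - ref)) / max(abs(ref)), 1e-6)
})

test_that("non-finite drift raises an integration failure naming the state", {
  bad <- dyn_model("x", character(0),
                   function(x, u, theta, t) if (t > 0.5) NaN else -x[[1]],
                   x0 = c(x = 1), name = "bad")
  expect_error(simulate_ode(bad, numeric(0), c(0, 1)), "x")
})

test_that("SDE paths with zero diffusion collapse onto the ODE solution", {
  bundles <- list(pk_model("mm_final"), pk_model("linear_sde"),
                  gln_model("mm_ext_W"))
  thetas <- list(c(V_max = 2, K_m = 2, C_L = 2, V = 5, sigma_Q = 0, sigma_C = 0),
                 c(k_A = 0.3, C_L = 2, V = 5, sigma_Q = 0, sigma_C = 0),
                 c(V_max = 3, K_m = 2.5, V_2 = 6, K_2 = 2.5, D = 0.08,
                   sigma_Q = 0, sigma_C = 0, sigma_W = 0))
  for (i in seq_along(bundles)) {
    m <- bundles[[i]]$model
    times <- seq(m$t0, m$t0 + 10, length.out = 21)
    ens <- simulate_sde(m, thetas[[i]], times, n_paths = 2, seed = 7, n_sub = 10)
    ens_fine <- simulate_sde(m, thetas[[i]], times, n_paths = 1, seed = 7,
                             n_sub = 20)
    ode <- simulate_ode(m, thetas[[i]], times)
    # first-order scheme: step error estimated by Richardson extrapolation
    step_err <- 2 * max(abs(ens$states[, , 1] - ens_fine$states[, , 1]))
    expect_lt(max(abs(ens$states[, , 1] - ode$states)), 10 * step_err)
    expect_identical(ens$states[, , 1], ens$states[, , 2])  # sigma = 0: no noise
  }
})

test_that("Wiener and Ornstein-Uhlenbeck moments match closed forms", {
  # pure diffusion dx = sigma dW: Var[x(t)] = sigma^2 t
  pure <- dyn_model("x", character(0), function(x, u, theta, t) 0,
                    x0 = c(x = 0), name = "wiener")
  pure <- reformulate_as_sde(pure, "sigma")
  sig <- 0.5
  n_paths <- 1e4
  ens <- simulate_sde(pure, c(sigma = sig), c(0, 1), n_paths = n_paths,
                      seed = 11, n_sub = 20)
  v <- var(ens$states[2, 1, ])
  mc_se <- v * sqrt(2 / (n_paths - 1))
  expect_lt(abs(v - sig^2 * 1), 3 * mc_se)

  # OU dx = -x dt + sigma dW: stationary variance sigma^2 / 2
  ou <- dyn_model("x", character(0), function(x, u, theta, t) -x[[1]],
                  x0 = c(x = 0), name = "ou")
  ou <- reformulate_as_sde(ou, "sigma")
  ens2 <- simulate_sde(ou, c(sigma = sig), seq(0, 8, 0.5), n_paths = n_paths,
                       seed = 12, n_sub = 8)
  v2 <- var(ens2$states[17, 1, ])
  mc_se2 <- v2 * sqrt(2 / (n_paths - 1))
  # allow Euler-Maruyama bias ~ dt on top of the MC band
  expect_lt(abs(v2 - sig^2 / 2), 3 * mc_se2 + 0.0625 * sig^2 / 2)

  # reproducibility
  ens3 <- simulate_sde(ou, c(sigma = sig), seq(0, 8, 0.5), n_paths = 3,
                       seed = 99, n_sub = 8)
  ens4 <- simulate_sde(ou, c(sigma = sig), seq(0, 8, 0.5), n_paths = 3,
                       seed = 99, n_sub = 8)
  expect_identical(ens3$states, ens4$states)
  expect_error(simulate_sde(ou, c(sigma = -1), c(0, 1)), "non-negative")
})

test_that("reformulate_as_sde appends one diffusion parameter per state", {
  lin <- pk_model("linear")$model
  sde <- reformulate_as_sde(lin)
  expect_setequal(sde$param_names, c("k_A", "C_L", "V", "sigma_Q", "sigma_C"))
  expect_identical(sde$drift, lin$drift)

  one <- dyn_model("x", "a", function(x, u, theta, t) -theta[["a"]] * x,
                   x0 = c(x = 1))
  expect_length(setdiff(reformulate_as_sde(one)$param_names, one$param_names), 1)
  expect_error(reformulate_as_sde(sde), "already stochastic")
})

test_that("parameter promotion adds a zero-drift diffusion-driven state", {
  ext <- pk_model("extended_full")$model
  expect_identical(ext$state_names, c("Q", "C", "k_A"))
  expect_setequal(grep("^sigma", ext$param_names, value = TRUE),
                  c("sigma_Q", "sigma_C", "sigma_k_A"))
  expect_error(promote_parameter_to_state(pk_model("linear_sde")$model, "nope", 1),
               "unknown parameter")

  # with its diffusion at 0 the promoted state stays at its init and the
  # model is dynamically identical to the unpromoted model at matched theta
  kA <- 0.25
  sde <- pk_model("linear_sde")$model
  ext2 <- promote_parameter_to_state(sde, "k_A", init = kA)
  th_ext <- c(C_L = 2, V = 5, sigma_Q = 0.1, sigma_C = 0.05, sigma_k_A = 0)
  th_lin <- c(k_A = kA, C_L = 2, V = 5, sigma_Q = 0.1, sigma_C = 0.05)
  tr <- simulate_ode(ext2, th_ext, seq(0, 10, 1))
  expect_true(all(abs(tr$states[, "k_A"] - kA) < 1e-9))
  d <- pk_generate(3)
  c_ext <- ekf_cost(ext2, th_ext, d)$value
  c_lin <- ekf_cost(sde, th_lin, d)$value
  expect_equal(c_ext, c_lin, tolerance = 1e-8)
})

test_that("stoichiometric factorization is honoured and mass is conserved", {
  # truth model: d(Q + V C)/dt = -C_L * C along any trajectory
  b <- pk_model("truth")
  th <- c(V_max = 2, K_m = 2, C_L = 2, V = 5)
  tr <- simulate_ode(b$model, th, seq(0, 10, 0.25))
  for (i in seq_along(tr$times)) {
    x <- tr$states[i, ]
    f <- b$model$drift(x, NULL, th, tr$times[i])
    expect_lt(abs(f[1] + th[["V"]] * f[2] + th[["C_L"]] * x[["C"]]), 1e-8)
  }

  # N * v form: drift must equal the factorization (validated at build)
  N <- matrix(c(-1, 1), 2, 1)
  m <- dyn_model(c("a", "b"), "k", reactions = function(x, u, theta, t)
                   theta[["k"]] * x[["a"]],
                 stoichiometry = N, x0 = c(a = 1, b = 0), name = "iso")
  tr2 <- simulate_ode(m, c(k = 1), seq(0, 2, 0.5))
  # left-null-vector (1, 1) of N is conserved
  expect_lt(max(abs(rowSums(tr2$states) - 1)), 1e-8)
})

test_that("proportional observation noise has the declared magnitude", {
  still <- dyn_model("x", character(0), function(x, u, theta, t) 0,
                     x0 = c(x = 1), name = "unit")
  times <- seq(0, 9999)
  tr <- simulate_ode(still, numeric(0), times)

  noiseless <- generate_observations(tr, still,
                                     list(type = "proportional", rho = 0),
                                     seed = 5)
  expect_equal(noiseless$value, rep(1, length(times)))

  noisy <- generate_observations(tr, still,
                                 list(type = "proportional", rho = 0.1),
                                 seed = 5)
  s <- sd(noisy$value)
  mc_se <- s / sqrt(2 * (length(times) - 1))
  expect_lt(abs(s - 0.1), 3 * mc_se)
  expect_error(generate_observations(tr, still,
                                     list(type = "proportional", rho = -1)),
               "rho")
})
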