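test_that("the PK model family is complete and internally consistent", {
  expect_length(grep("^pk_M", list_bundles(), value = TRUE), 8)  # M1..M8
  # sigma eliminations across the M-series
  expect_setequal(pk_model("M1")$model$param_names,
                  c("k_A", "C_L", "V", "sigma_Q", "sigma_C"))
  expect_setequal(pk_model("M4")$model$param_names, c("k_A", "C_L", "V"))
  expect_setequal(pk_model("M8")$model$param_names,
                  c("V_max", "K_m", "C_L", "V"))
  expect_error(pk_model("M9"))
})

test_that("linear and MM uptake agree in the low-occupancy limit", {
  # k_A = V_max / K_m, Q0 << K_m: trajectories converge as Q0 shrinks
  th_mm <- c(V_max = 2, K_m = 2, C_L = 2, V = 5)
  maxdiff <- function(Q0) {
    mm <- pk_model("truth")$model
    lin <- pk_model("linear")$model
    mm$x0["Q"] <- lin$x0["Q"] <- Q0
    times <- seq(0, 10, 0.5)
    a <- simulate_ode(mm, th_mm, times)
    b <- simulate_ode(lin, c(k_A = 1, C_L = 2, V = 5), times)
    max(abs(a$states - b$states)) / Q0
  }
  d1 <- maxdiff(0.5)
  d2 <- maxdiff(0.05)
  d3 <- maxdiff(0.005)
  expect_lt(d2, d1)
  expect_lt(d3, d2)
  expect_lt(d3, 0.01)
})

test_that("the PK generator delivers 20 reproducible proportional-noise points", {
  d <- pk_generate(17)
  expect_s3_class(d, "ta_dataset")
  expect_equal(nrow(d), 20)
  expect_setequal(unique(d$observable), "C")
  expect_identical(pk_generate(17), d)                 # bit-reproducible
  expect_false(identical(pk_generate(18)$value, d$value))
  d0 <- pk_generate(17, rho = 0)
  tr <- simulate_ode(pk_model("truth")$model, c(V_max = 2, K_m = 1, C_L = 2, V = 5),
                     sort(unique(c(0, d0$time))))
  expect_equal(d0$value, tr$states[match(d0$time, tr$times), "C"],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("glutamine variants nest and their parameter counts increase", {
  np <- vapply(c("mm", "rmm", "e1rmm", "e2rmm"),
               function(v) length(gln_model(v)$model$param_names), numeric(1))
  expect_true(all(diff(np) > 0))

  # rmm with V_2 = 0 collapses onto mm (on the shared states)
  times <- seq(-150, 150, 10)
  th_r <- c(V_max = 3, K_m = 2.5, V_2 = 0, K_2 = 1, k_w = 0.05, D = 0.08)
  a <- simulate_ode(gln_model("rmm")$model, th_r, times)
  bq <- simulate_ode(gln_model("mm")$model, c(V_max = 3, K_m = 2.5, D = 0.08), times)
  expect_lt(max(abs(a$states[, c("Q", "C")] - bq$states)), 1e-5)

  # e1rmm with V_3 = 0 collapses onto rmm
  th_e1 <- c(V_max = 3, K_m = 2.5, V_2 = 6, K_2 = 2.5, k_w = 0.05,
             V_3 = 0, K_3 = 1, D = 0.08)
  th_r2 <- c(V_max = 3, K_m = 2.5, V_2 = 6, K_2 = 2.5, k_w = 0.05, D = 0.08)
  e1 <- simulate_ode(gln_model("e1rmm")$model, th_e1, times)
  r2 <- simulate_ode(gln_model("rmm")$model, th_r2, times)
  expect_lt(max(abs(e1$states - r2$states)), 1e-5)
})

test_that("the activation state W stays off while glutamine is plentiful", {
  m <- gln_model("rmm")$model
  m$x0["Q"] <- 40            # far above the 4 mM threshold all window long
  th <- c(V_max = 0.5, K_m = 2.5, V_2 = 6, K_2 = 2.5, k_w = 0.05, D = 0.08)
  tr <- simulate_ode(m, th, seq(-150, 0, 10))
  expect_lt(max(tr$states[, "W"]), 1e-8)
})

test_that("the glutamine generator matches the declared study design", {
  d <- gln_generate(19)
  expect_equal(sum(d$observable == "C"), 14)   # intracellular
  expect_equal(sum(d$observable == "Q"), 23)   # extracellular
  expect_identical(gln_generate(19), d)
  # noiseless extracellular glutamine is monotone nonincreasing
  b <- gln_model("rmm")
  tr <- simulate_ode(b$model, b$theta_true, seq(-150, 160, 2))
  expect_true(all(diff(tr$states[, "Q"]) <= 1e-10))
  # the activation threshold is crossed near the metabolic shift
  iq <- which.min(abs(tr$states[, "Q"] - 4))
  expect_lt(abs(tr$times[iq]), 10)
})

test_that("datasets round-trip through CSV including noise annotations", {
  d <- gln_generate(23)
  p <- tempfile(fileext = ".csv")
  write_dataset(d, p)
  d2 <- read_dataset(p)
  expect_equal(d2$value, d$value, tolerance = 1e-12)
  expect_equal(d2$sd, d$sd, tolerance = 1e-12)
  expect_identical(d2$observable, d$observable)
  unlink(p)
})

test_that("fitting the simplistic MM model to shift data exposes its bias", {
  d <- gln_generate(29)
  mmod <- gln_model("mm")$model
  f <- function(z) {
    v <- ekf_cost(mmod, setNames(10^z, c("V_max", "K_m", "D")), d)$value
    if (is.finite(v)) v else 1e10
  }
  o <- optim(log10(c(1, 1, 0.1)), f, control = list(maxit = 400))
  o <- optim(o$par, f, control = list(maxit = 300))
  fit <- ekf_filter(mmod, setNames(10^o$par, c("V_max", "K_m", "D")), d)
  # intracellular glutamine is systematically underestimated during the
  # post-shift response
  st <- innovation_sign_test(fit, "C", window = c(0, Inf))
  expect_identical(st$direction, "under")
  expect_lt(st$p_value, 0.05)
})
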