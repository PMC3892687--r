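# Independent oracles used across the suite.  These deliberately avoid the
# package's own integration/filtering code paths: the discrete Kalman
# recursion below uses exact matrix-exponential (Van Loan) discretization,
# and the RK4 integrator is a separately coded fixed-step scheme.

# exact discretization of dx = A x dt + diag(sig) dW over a step of length h:
# returns Ad and the discrete process noise Qd (Van Loan 1978)
vanloan_disc <- function(A, sig, h) {
  n <- nrow(A)
  Qc <- diag(sig^2, n)
  M <- rbind(cbind(-A, Qc), cbind(matrix(0, n, n), t(A))) * h
  E <- as.matrix(Matrix::expm(M))
  F22 <- E[(n + 1):(2 * n), (n + 1):(2 * n), drop = FALSE]
  F12 <- E[1:n, (n + 1):(2 * n), drop = FALSE]
  Ad <- t(F22)
  Qd <- Ad %*% F12
  list(Ad = Ad, Qd = (Qd + t(Qd)) / 2)
}

# exact discrete-time Kalman filter for dx = A x dt + diag(sig) dW observed
# as y_k = H x(t_k) + N(0, diag(sd_k^2)); Y and SDm are K x p matrices with
# NA marking unobserved entries.  Returns nll and filtered means.
kalman_oracle <- function(A, sig, H, x0, t0, times, Y, SDm, P0 = NULL) {
  n <- nrow(A)
  m <- x0
  P <- if (is.null(P0)) matrix(0, n, n) else P0
  t_cur <- t0
  nll <- 0
  Mu <- matrix(NA_real_, length(times), n)
  for (k in seq_along(times)) {
    h <- times[k] - t_cur
    if (h > 0) {
      d <- vanloan_disc(A, sig, h)
      m <- as.numeric(d$Ad %*% m)
      P <- d$Ad %*% P %*% t(d$Ad) + d$Qd
      t_cur <- times[k]
    }
    oo <- which(is.finite(Y[k, ]))
    if (length(oo)) {
      Hk <- H[oo, , drop = FALSE]
      e <- Y[k, oo] - as.numeric(Hk %*% m)
      S <- Hk %*% P %*% t(Hk) + diag(SDm[k, oo]^2, length(oo))
      Si <- solve(S)
      nll <- nll + 0.5 * (sum(e * (Si %*% e)) +
                            determinant(S)$modulus[1] +
                            length(oo) * log(2 * pi))
      K <- P %*% t(Hk) %*% Si
      m <- m + as.numeric(K %*% e)
      P <- (diag(n) - K %*% Hk) %*% P
      P <- (P + t(P)) / 2
    }
    Mu[k, ] <- m
  }
  list(nll = nll, means = Mu)
}

# wrap a linear system dx = A x dt (+ diffusion) as a dynmodel
linear_dynmodel <- function(A, x0, sig_names = NULL, obs_states = NULL,
                            t0 = 0) {
  n <- nrow(A)
  sn <- paste0("x", seq_len(n))
  names(x0) <- sn
  m <- dyn_model(
    state_names = sn,
    param_names = character(0),
    drift = local({ A_ <- A; function(x, u, theta, t) as.numeric(A_ %*% x) }),
    jacobian = local({ A_ <- A; function(x, u, theta, t) A_ }),
    obs_states = obs_states,
    x0 = x0, t0 = t0, name = "linear")
  if (!is.null(sig_names)) m <- reformulate_as_sde(m, sig_names)
  m
}

# draw a random stable linear-Gaussian test system
random_linear_system <- function(n = 2, p = 1, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(rnorm(n * n, sd = 0.8), n, n)
    diag(A) <- -abs(diag(A)) - 0.3   # push eigenvalues leftwards
    if (max(Re(eigen(A)$values)) < -0.05) break
  }
  x0 <- rnorm(n)
  sig <- runif(n, 0.05, 0.5)
  obs <- sort(sample(n, p))
  times <- sort(runif(6, 0.2, 4))
  list(A = A, x0 = x0, sig = sig, obs = obs, times = times)
}

# independently coded fixed-step classical RK4 integrator
rk4_oracle <- function(f, x0, times, nsub = 200) {
  out <- matrix(NA_real_, length(times), length(x0))
  out[1, ] <- x <- x0
  for (k in 2:length(times)) {
    h <- (times[k] - times[k - 1]) / nsub
    t <- times[k - 1]
    for (s in seq_len(nsub)) {
      k1 <- f(t, x); k2 <- f(t + h / 2, x + h / 2 * k1)
      k3 <- f(t + h / 2, x + h / 2 * k2); k4 <- f(t + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[k, ] <- x
  }
  out
}

# closed-form marginal likelihood for y_k ~ N(mu, s_k^2) with mu uniform on
# [a, b]: Gaussian-integral (Phi-difference) formula
gaussian_marginal_oracle <- function(y, s, a, b) {
  v <- 1 / sum(1 / s^2)
  mu_hat <- sum(y / s^2) * v
  logC <- -0.5 * (sum(log(2 * pi * s^2)) + sum(y^2 / s^2) - mu_hat^2 / v)
  logC + 0.5 * log(2 * pi * v) +
    log(stats::pnorm((b - mu_hat) / sqrt(v)) - stats::pnorm((a - mu_hat) / sqrt(v))) -
    log(b - a)
}

# constant-state model (dx/dt = 0), x observed: the conjugate Gaussian toy
constant_dynmodel <- function(x0 = 1, t0 = 0) {
  dyn_model("x", character(0), function(x, u, theta, t) 0,
            jacobian = function(x, u, theta, t) matrix(0, 1, 1),
            x0 = c(x = x0), t0 = t0, name = "constant")
}

make_dataset <- function(times, values, sd, observable = "x") {
  ta_dataset(data.frame(time = times, observable = observable,
                        value = values, sd = sd))
}
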