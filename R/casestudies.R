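#' Pharmacokinetic case-study models
#'
#' A two-compartment model for the absorption of an orally administered
#' drug: availability in the gastrointestinal tract (`Q`, mg) and
#' concentration in the blood plasma (`C`, mg/l), with only `C` observed.
#' The generating ("truth") model uses saturating Michaelis-Menten uptake,
#' \deqn{dQ/dt = -V_{max} Q/(K_m+Q), \quad
#'       dC/dt = (1/V) V_{max} Q/(K_m+Q) - (C_L/V) C,}
#' while the naive starting model replaces the uptake by the mass-action
#' term `k_A * Q`.
#'
#' Variants: `"truth"`/`"mm"` (MM ODE), `"mm_final"` (MM SDE),
#' `"linear"` (linear ODE), `"linear_sde"`, `"extended"` (linear SDE with
#' `k_A` promoted to a diffusion-driven state and the two eliminable
#' diffusions fixed at zero -- the step-6 configuration used to infer the
#' hidden uptake mechanism), `"extended_full"` (same promotion with all
#' three diffusion magnitudes free), and `"M1"`..`"M8"`: the
#' eight models constructed by eliminating combinations of the two
#' diffusion magnitudes from the linear (`M1`-`M4`) and MM (`M5`-`M8`) SDE
#' models (`M1`/`M5`: both free; `M2`/`M6`: only `sigma_Q`; `M3`/`M7`: only
#' `sigma_C`; `M4`/`M8`: both eliminated, i.e. the plain ODE models).
#'
#' @param variant model variant id.
#' @return a `case_bundle`: list with the `dynmodel` (`$model`), the
#'   default log10 sampling/prior `$box`, and (for generating variants) the
#'   true parameters and generation settings.
#' @export
pk_model <- function(variant = c("truth", "mm", "mm_final", "linear",
                                 "linear_sde", "extended", "extended_full",
                                 paste0("M", 1:8))) {
  variant <- match.arg(variant)
  cs <- .pk

  mm_drift <- function(x, u, theta, t) {
    r1 <- theta[["V_max"]] * x[["Q"]] / (theta[["K_m"]] + x[["Q"]])
    c(-r1, r1 / theta[["V"]] - theta[["C_L"]] / theta[["V"]] * x[["C"]])
  }
  mm_jac <- function(x, u, theta, t) {
    den <- theta[["K_m"]] + x[["Q"]]
    dr1 <- theta[["V_max"]] * theta[["K_m"]] / den^2
    matrix(c(-dr1, dr1 / theta[["V"]],
             0, -theta[["C_L"]] / theta[["V"]]), 2, 2)
  }
  lin_drift <- function(x, u, theta, t) {
    r1 <- theta[["k_A"]] * x[["Q"]]
    c(-r1, r1 / theta[["V"]] - theta[["C_L"]] / theta[["V"]] * x[["C"]])
  }
  lin_jac <- function(x, u, theta, t) {
    matrix(c(-theta[["k_A"]], theta[["k_A"]] / theta[["V"]],
             0, -theta[["C_L"]] / theta[["V"]]), 2, 2)
  }

  mm <- dyn_model(c("Q", "C"), c("V_max", "K_m", "C_L", "V"), mm_drift,
                  obs_states = c(C = 2L), x0 = cs$x0, t0 = cs$t0,
                  jacobian = mm_jac, name = "pk_mm",
                  cpp = list(id = .cpp_ids[["pk_mm"]], iopar = numeric(0)))
  lin <- dyn_model(c("Q", "C"), c("k_A", "C_L", "V"), lin_drift,
                   obs_states = c(C = 2L), x0 = cs$x0, t0 = cs$t0,
                   jacobian = lin_jac, name = "pk_linear",
                   cpp = list(id = .cpp_ids[["pk_linear"]], iopar = numeric(0)))

  kin_box <- function(m) {
    kp <- m$kinetic_params
    b <- matrix(rep(cs$box_kinetic, length(m$param_names)), 2)
    colnames(b) <- m$param_names
    sg <- intersect(m$param_names, m$diffusion)
    if (length(sg)) b[, sg] <- cs$box_sigma
    rownames(b) <- c("lo", "hi")
    b
  }

  model <- switch(variant,
    truth = , mm = mm,
    mm_final = reformulate_as_sde(mm),
    linear = lin,
    linear_sde = reformulate_as_sde(lin),
    # step-6 configuration: the individually eliminable diffusions of the
    # linear SDE are dropped and the promoted k_A state carries the system
    # noise (the extended model is viable with sigma_Q = sigma_C = 0 but
    # not with sigma_k_A = 0)
    extended = fix_params(
      promote_parameter_to_state(reformulate_as_sde(lin), "k_A", init = NULL),
      sigma_Q = 0, sigma_C = 0),
    extended_full = promote_parameter_to_state(reformulate_as_sde(lin), "k_A",
                                               init = NULL),
    M1 = reformulate_as_sde(lin),
    M2 = fix_params(reformulate_as_sde(lin), sigma_C = 0),
    M3 = fix_params(reformulate_as_sde(lin), sigma_Q = 0),
    M4 = fix_params(reformulate_as_sde(lin), sigma_Q = 0, sigma_C = 0),
    M5 = reformulate_as_sde(mm),
    M6 = fix_params(reformulate_as_sde(mm), sigma_C = 0),
    M7 = fix_params(reformulate_as_sde(mm), sigma_Q = 0),
    M8 = fix_params(reformulate_as_sde(mm), sigma_Q = 0, sigma_C = 0))
  model$name <- paste0("pk_", variant)

  structure(list(id = paste0("pk_", variant), model = model,
                 box = kin_box(model),
                 theta_true = if (variant %in% c("truth", "mm")) cs$theta_true,
                 gen = list(schedule = cs$schedule, rho = cs$rho)),
            class = "case_bundle")
}

#' Generate the synthetic pharmacokinetic dataset
#'
#' Simulates the truth model at the declared (reconstructed) true
#' parameters, samples the plasma concentration `C` at 20 equally spaced
#' times over the absorption-clearance window, and applies proportional
#' measurement noise (`rho = 0.1` by default).  Bit-reproducible per seed.
#'
#' @param seed integer seed.
#' @param rho proportional noise coefficient.
#' @return a 20-point `ta_dataset` on observable `C`.
#' @export
pk_generate <- function(seed = 1L, rho = .pk$rho) {
  b <- pk_model("truth")
  grid <- sort(unique(c(b$model$t0, .pk$schedule)))
  tr <- simulate_ode(b$model, .pk$theta_true, grid)
  generate_observations(tr, b$model,
                        noise = list(type = "proportional", rho = rho),
                        seed = seed,
                        schedule = list(C = .pk$schedule))
}

#' Yeast glutamine transport case-study models
#'
#' Models of glutamine uptake in a *S. cerevisiae* batch culture across the
#' metabolic shift from glutamine to proline consumption (shift at
#' t = 0 min).  States: extracellular (`Q`, mM) and intracellular (`C`, mM)
#' glutamine, both observed.  Uptake is scaled to the medium by the culture
#' input `eps(t) = U(t) Vc / Vf` (cell count times cell/medium volume
#' ratio, a supplied logistic input):
#' \deqn{dQ/dt = -\epsilon(t) r_1, \quad dC/dt = r_1 - D C.}
#'
#' Variants: `"mm"` (single MM uptake term,
#' \eqn{r_1 = V_{max} Q/(K_m+Q)}); `"rmm"` (regulated MM: adds
#' \eqn{W V_2 Q/(K_2+Q)} with the activity state `W` rising from 0 by
#' \eqn{dW/dt = k_w (1-W) 1\{Q \le K\}}, activation threshold `K = 4` mM);
#' `"e1rmm"` (adds a third, constitutive millimolar MM term
#' \eqn{V_3 Q/(K_3+Q)}); `"e2rmm"` (adds a fourth regulated micromolar
#' term \eqn{W V_4 Q/(K_4+Q)}); `"mm_ext_W"` (SDE with `W` as a
#' diffusion-driven auxiliary state modulating the hypothetical
#' \eqn{W V_2 Q/(K_2+Q)} term).  The activation indicator is smoothed over
#' 0.1 mM; the bounded (`1-W`) activation form is the default, with
#' `w_form = "capped"` clipping an unbounded rate at 1 instead.
#'
#' @param variant model variant id.
#' @param w_form `"bounded"` (default) or `"capped"` activation dynamics.
#' @return a `case_bundle` (see [pk_model()]).
#' @export
gln_model <- function(variant = c("mm", "rmm", "e1rmm", "e2rmm", "mm_ext_W"),
                      w_form = c("bounded", "capped")) {
  variant <- match.arg(variant)
  w_form <- match.arg(w_form)
  cs <- .gln
  eps <- function(t) gln_eps(t, cs$iopar)
  Kg <- cs$K_gate

  wrate <- function(W, Q, kw) {
    g <- gln_gate(Q, Kg)
    if (w_form == "bounded") kw * (1 - W) * g else kw * g * as.numeric(W < 1)
  }

  mk <- function(states, params, drift, cpp_id, extra_fixed = NULL,
                 name = variant) {
    dyn_model(states, params, drift,
              obs_states = c(Q = 1L, C = 2L),
              inputs = eps, x0 = cs$x0[states], t0 = cs$t0,
              fixed = extra_fixed, name = paste0("gln_", name),
              cpp = if (w_form == "bounded")
                list(id = cpp_id, iopar = cs$iopar) else NULL)
  }

  model <- switch(variant,
    mm = {
      drift <- function(x, u, theta, t) {
        r1 <- theta[["V_max"]] * x[["Q"]] / (theta[["K_m"]] + x[["Q"]])
        c(-u * r1, r1 - theta[["D"]] * x[["C"]])
      }
      mk(c("Q", "C"), c("V_max", "K_m", "D"), drift, .cpp_ids[["gln_mm"]])
    },
    rmm = {
      drift <- function(x, u, theta, t) {
        r1 <- theta[["V_max"]] * x[["Q"]] / (theta[["K_m"]] + x[["Q"]]) +
          x[["W"]] * theta[["V_2"]] * x[["Q"]] / (theta[["K_2"]] + x[["Q"]])
        c(-u * r1, r1 - theta[["D"]] * x[["C"]],
          wrate(x[["W"]], x[["Q"]], theta[["k_w"]]))
      }
      m <- mk(c("Q", "C", "W"), c("V_max", "K_m", "V_2", "K_2", "k_w", "D"),
              drift, .cpp_ids[["gln_rmm"]])
      # compiled backend carries the gate threshold as a trailing parameter
      if (!is.null(m$cpp)) m$cpp$extra_kinetic <- Kg
      m
    },
    e1rmm = {
      drift <- function(x, u, theta, t) {
        r1 <- theta[["V_max"]] * x[["Q"]] / (theta[["K_m"]] + x[["Q"]]) +
          x[["W"]] * theta[["V_2"]] * x[["Q"]] / (theta[["K_2"]] + x[["Q"]]) +
          theta[["V_3"]] * x[["Q"]] / (theta[["K_3"]] + x[["Q"]])
        c(-u * r1, r1 - theta[["D"]] * x[["C"]],
          wrate(x[["W"]], x[["Q"]], theta[["k_w"]]))
      }
      m <- mk(c("Q", "C", "W"),
              c("V_max", "K_m", "V_2", "K_2", "k_w", "V_3", "K_3", "D"),
              drift, .cpp_ids[["gln_e1rmm"]])
      if (!is.null(m$cpp)) m$cpp$extra_kinetic <- Kg
      m
    },
    e2rmm = {
      drift <- function(x, u, theta, t) {
        r1 <- theta[["V_max"]] * x[["Q"]] / (theta[["K_m"]] + x[["Q"]]) +
          x[["W"]] * theta[["V_2"]] * x[["Q"]] / (theta[["K_2"]] + x[["Q"]]) +
          theta[["V_3"]] * x[["Q"]] / (theta[["K_3"]] + x[["Q"]]) +
          x[["W"]] * theta[["V_4"]] * x[["Q"]] / (theta[["K_4"]] + x[["Q"]])
        c(-u * r1, r1 - theta[["D"]] * x[["C"]],
          wrate(x[["W"]], x[["Q"]], theta[["k_w"]]))
      }
      m <- mk(c("Q", "C", "W"),
              c("V_max", "K_m", "V_2", "K_2", "k_w", "V_3", "K_3",
                "V_4", "K_4", "D"),
              drift, .cpp_ids[["gln_e2rmm"]])
      if (!is.null(m$cpp)) m$cpp$extra_kinetic <- Kg
      m
    },
    mm_ext_W = {
      drift <- function(x, u, theta, t) {
        r1 <- theta[["V_max"]] * x[["Q"]] / (theta[["K_m"]] + x[["Q"]]) +
          x[["W"]] * theta[["V_2"]] * x[["Q"]] / (theta[["K_2"]] + x[["Q"]])
        c(-u * r1, r1 - theta[["D"]] * x[["C"]], 0)
      }
      m <- mk(c("Q", "C", "W"), c("V_max", "K_m", "V_2", "K_2", "D"),
              drift, .cpp_ids[["gln_mm_ext"]])
      reformulate_as_sde(m)
    })

  box <- gln_box(model)
  structure(list(id = paste0("gln_", variant), model = model, box = box,
                 theta_true = if (variant == "rmm") cs$theta_true,
                 gen = list(sched_Q = cs$sched_Q, sched_C = cs$sched_C,
                            rho = cs$rho, sd_floor = cs$sd_floor)),
            class = "case_bundle")
}

gln_box <- function(model) {
  cs <- .gln
  b <- vapply(model$param_names, function(p) {
    if (p %in% names(cs$box)) cs$box[[p]] else cs$box_sigma
  }, numeric(2))
  rownames(b) <- c("lo", "hi")
  b
}

#' Generate the synthetic glutamine shift dataset
#'
#' Simulates the rMM model at the declared synthetic true parameters with
#' the logistic culture input and the metabolic shift at t = 0 (the initial
#' extracellular glutamine is calibrated so `Q` crosses the activation
#' threshold of about 4 mM near t = 0), then samples 14 intracellular and
#' 23 extracellular points on schedules straddling the shift with
#' proportional noise floored at the detection limit.  Bit-reproducible per
#' seed.
#'
#' @param seed integer seed.
#' @param rho proportional noise coefficient.
#' @return a `ta_dataset` with observables `Q` (23 points) and `C` (14
#'   points).
#' @export
gln_generate <- function(seed = 1L, rho = .gln$rho) {
  b <- gln_model("rmm")
  grid <- sort(unique(c(b$model$t0, .gln$sched_Q, .gln$sched_C)))
  tr <- simulate_ode(b$model, .gln$theta_true, grid)
  generate_observations(tr, b$model,
                        noise = list(type = "proportional", rho = rho,
                                     sd_floor = .gln$sd_floor),
                        seed = seed,
                        schedule = list(Q = .gln$sched_Q, C = .gln$sched_C))
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case_bundle '%s'>\n", x$id))
  print(x$model)
  if (!is.null(x$theta_true)) {
    cat("  true parameters (synthetic generator):\n  ")
    print(round(x$theta_true, 4))
  }
  invisible(x)
}
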