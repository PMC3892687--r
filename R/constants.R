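# Declared constants for the bundled case studies.
#
# The pharmacokinetic (PK) "true" parameters, sampling schedule and noise
# coefficient are RECONSTRUCTED defaults, chosen so that absorption
# saturates and the drug clears within the observation window; they are not
# literature values.  Likewise the glutamine culture input U(t)*Vc/Vf, the
# initial concentrations, the sampling schedules and the "true" rMM
# parameters are SYNTHETIC stand-ins emulating a batch-culture shift
# experiment (14 intracellular + 23 extracellular points around a metabolic
# shift at t = 0 min, with permease activation triggering near Q = 4 mM).
# All tunables live here so the study conditions are declared in one place.

# ---- pharmacokinetic case study (time in hours, Q in mg, C in mg/l) -------

.pk <- list(
  theta_true = c(V_max = 2, K_m = 1, C_L = 2, V = 5),
  x0 = c(Q = 10, C = 0),
  t0 = 0,
  schedule = seq(0.5, 14, length.out = 20),
  rho = 0.05,
  box_kinetic = c(-4, 4), # log10, eight orders of magnitude
  box_sigma = c(-6, 2)    # log10, eight orders of magnitude
)

# ---- glutamine case study (time in minutes, concentrations in mM) ---------

.gln <- list(
  # rMM "truth" used by the synthetic generator; slow intracellular
  # turnover (D) and a strong regulated term make the minimal-model misfit
  # a clear systematic bias around the shift, as in the emulated study
  theta_true = c(V_max = 0.45, K_m = 2.5, V_2 = 6, K_2 = 2.5, k_w = 0.05,
                 D = 0.01),
  K_gate = 4,             # mM; activation threshold of the regulated term
  x0 = c(Q = 11, C = 36, W = 0),
  t0 = -150,
  # logistic culture input eps(t) = U(t) Vc / Vf: (e0, e1, tmid, tau)
  iopar = c(0.1, 0.25, 0, 60),
  sched_Q = c(seq(-140, -20, by = 20), seq(-10, 60, by = 10),
              seq(80, 150, by = 10)),                  # 23 extracellular
  sched_C = c(seq(-120, 0, by = 20), seq(10, 70, by = 10)), # 14 intracellular,
                          # concentrated around the shift response
  rho = 0.05,
  sd_floor = 0.05,        # mM; detection-limit floor on the noise SD
  # log10 prior/sampling boxes
  box = list(V_max = c(-2, 2), K_m = c(-1, 2), V_2 = c(-2, 2),
             K_2 = c(-1, 2), k_w = c(-3, 0), D = c(-3, 0),
             V_3 = c(-2, 2), K_3 = c(-1, 2),
             V_4 = c(-2, 2), K_4 = c(-4, -0.5)),
  box_sigma = c(-4, 1)
)

# compiled-backend ids (must match src/ekf_core.cpp)
.cpp_ids <- c(pk_mm = 1L, pk_linear = 2L, pk_ext = 3L, gln_mm = 4L,
              gln_rmm = 5L, gln_e1rmm = 6L, gln_e2rmm = 7L, gln_mm_ext = 8L)

# known parameter promotions with a dedicated compiled backend
promoted_cpp_backend <- function(model, param) {
  if (!is.null(model$cpp) && model$cpp$id == .cpp_ids[["pk_linear"]] &&
      param == "k_A")
    return(list(id = .cpp_ids[["pk_ext"]], iopar = model$cpp$iopar))
  NULL
}

# smooth stand-in for the activation indicator 1{Q <= K} (width 0.1 mM),
# shared by the R drift closures and the compiled backend
.gate_w <- 0.1
gln_gate <- function(Q, K) 1 / (1 + exp((Q - K) / .gate_w))

gln_eps <- function(t, iopar = .gln$iopar) {
  iopar[1] + (iopar[2] - iopar[1]) / (1 + exp(-(t - iopar[3]) / iopar[4]))
}
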