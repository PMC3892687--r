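# topaug

Topological augmentation for dynamic models of biochemical systems:
detect *where* an ODE model's structure is wrong and infer *what* is
missing, from time-series data.

## The problem

A kinetic model of a metabolic, signalling or transport process encodes a
topology — the state variables and the functional form of their
interactions.  When no parameter choice makes the model compatible with
the data, the usual fixes (more candidate models, bigger master models)
scale exponentially.  `topaug` takes the opposite route: start from a
minimal model, reformulate it as stochastic differential equations
(SDEs)

```
dx = f(x, u, θ, t) dt + σ dW,      y_k = h(x(t_k)) + e_k
```

and let the per-equation diffusion magnitudes σ absorb whatever the drift
`f` cannot explain.  A continuous-discrete extended Kalman filter turns
any parameter point (kinetic parameters plus σ) into a deterministic
negative log-likelihood cost, the *viable space* — all parameter points
whose cost passes a viability criterion — is explored globally, and the
distribution of σ over that space localizes the defect: an equation whose
diffusion is never negligible over the viable space is missing structure.
Diffusion-driven auxiliary states (e.g. a rate "constant" promoted to a
state variable) then reveal the time course of the missing mechanism, a
small term dictionary proposes its functional form, and Monte-Carlo Bayes
factors rank the resulting model versions.

Intended users: modellers in systems biology, pharmacokinetics and
related fields who have a mechanistic ODE model, time-series data with
known measurement error, and a suspicion that the model is structurally
incomplete.

## Worked example

The bundled pharmacokinetic study: drug amount in the gut `Q` and plasma
concentration `C` (only `C` observed), data generated from saturating
Michaelis-Menten uptake, fitted with a naive linear-uptake model.

```r
library(topaug)

d <- pk_generate(seed = 1)        # 20 noisy plasma-concentration points
lin <- pk_model("linear_sde")     # linear uptake + two diffusion magnitudes

s <- explore(function(th) ekf_cost(lin$model, th, d)$value, lin$box,
             explore_settings(corner_ids = c("sigma_Q", "sigma_C")),
             seed = 1, rule = viability_rule("sde", delta_orders = 5))
diagnose_diffusion(s, c("sigma_Q", "sigma_C"))
```

```
<diffusion_diagnosis> over 6238 viable points (corner: lowest 1 decades)
per diffusion parameter:
   sigma eliminable    lo         hi corner
 sigma_Q       TRUE -5.75  0.7786504     -5
 sigma_C       TRUE -6.00 -1.1379755     -5
subset eliminability:
          subset eliminable
         sigma_Q       TRUE
         sigma_C       TRUE
 sigma_Q+sigma_C      FALSE
```

Either diffusion magnitude alone can rescue the linear model (each is
individually eliminable), but no viable point has *both* negligible: the
model is structurally wrong, and the defect is in the uptake reaction.
Promoting `k_A` to a diffusion-driven state and filtering over the viable
ensemble recovers the hidden mechanism's time course, and the term
dictionary identifies its form:

```r
ext <- pk_model("extended")       # k_A promoted to a state variable
se <- explore(function(th) ekf_cost(ext$model, th, d)$value, ext$box,
              explore_settings(), seed = 1, rule = viability_rule("sde", 5))
grid <- seq(0, 14, 0.25)
hid <- infer_hidden(ext$model, se, d, grid, state = "k_A")
Q <- weighted_prediction(ext$model, se, grid)
Qm <- subset(Q, variable == "Q")
match_term(hid, list(Q = data.frame(time = Qm$time, value = Qm$mean)))
```

```
      family covariate          a       b     score       rss n_par
3 saturating         Q 2.48924856 1.31687 -257.0097 0.5827688     2
4     switch         Q 0.48399545 6.93705 -200.0624 1.5826648     2
1   constant      <NA> 0.38378553      NA -180.9330 2.2988847     1
2     linear         Q 0.04693611      NA -127.3154 5.8889928     1
```

The inferred `k_A(t)` rises and saturates, and the saturating family
`a/(b + Q)` wins by a wide margin — i.e. the uptake term should be
`V_max Q/(K_m + Q)`, which is exactly the mechanism the data were
generated from (`a` estimates `V_max`, `b` estimates `K_m`).  Replacing
the linear term accordingly and re-running the diagnosis makes both
diffusion magnitudes jointly eliminable, and the eight-model posterior
comparison (`posterior_probs()` over `pk_model("M1")` … `"M8"`) puts the
recovered saturating ODE model (M8) first.

A second bundled study applies the same workflow to glutamine transport
in yeast across a metabolic shift (`gln_model()`, `gln_generate()`),
where the hidden mechanism is a regulated permease activity that switches
on when extracellular glutamine runs low.

A command-line front end for the workflow steps is in
`inst/scripts/topaug.R` (`generate-data`, `explore`, `diagnose`,
`infer-hidden`, `match-term`, `compare`, ...).

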