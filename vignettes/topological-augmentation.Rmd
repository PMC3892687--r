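---
title: "Inferring missing model structure by topological augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring missing model structure by topological augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topaug)
```

## The problem

Deterministic ODE models of biochemical systems encode a *topology*: which
molecular species matter and what functional form their interactions take.
When a model systematically misses the data, the question is not only
"which parameters fit" but "which part of the structure is wrong".
`topaug` implements an iterative workflow that localizes structural error
and proposes the mathematical form of what is missing:

1. build a minimal ODE model;
2. check whether any parameter point makes it compatible with the data
   (a formal viability criterion plus a systematic-bias sign test);
3. reformulate the ODEs as SDEs by adding one diffusion magnitude per
   state equation — the diffusion ("system noise") absorbs whatever the
   drift cannot explain;
4. evaluate parameter points with a continuous-discrete extended Kalman
   filter (EKF) and characterize the *viable space*, the whole region of
   parameter space compatible with the data;
5. inspect the viable diffusion magnitudes: an equation whose diffusion is
   never negligible over the viable space is structurally wrong;
6. optionally add diffusion-driven auxiliary states (e.g. promote a suspect
   constant to a state variable) and let the filter infer their
   trajectories over the viable ensemble;
7. match the inferred trajectory against a small dictionary of candidate
   reaction terms, add the winning term to the ODE model, and go back
   to step 2.  Competing model versions are ranked by Monte-Carlo Bayes
   factors at the end.

Conclusions are always drawn from the *distribution* of viable parameter
points, never from one optimum: different viable points can imply opposite
structural conclusions, which is precisely what single-point analyses miss.

## Models and the filter

A model is $dx = f(x, u, \theta, t)\,dt + \sigma\,dW$ with output
$y_k = h(x(t_k)) + e_k$, $e_k \sim N(0, S_k)$.  The diffusion matrix is
diagonal with constant entries, one per state equation (both bundled case
studies use this form); an empty entry marks a deterministic equation.
With all entries zero the model is the original ODE system.

Because SDE paths differ at every simulation, parameters cannot be scored
by a least-squares distance.  The EKF provides a deterministic cost
instead: between observations the mean and covariance propagate by
$\dot m = f(m)$, $\dot P = AP + PA^\top + \sigma\sigma^\top$ with
$A = \partial f/\partial x|_m$; at each observation the standard update is
applied and the innovation-form negative log-likelihood
$J = \sum_k \tfrac12 (e_k^\top \Sigma_k^{-1} e_k + \ln\det 2\pi\Sigma_k)$
accumulates.  Repeated evaluations are bit-identical, so samplers can
treat $J(\theta)$ as an ordinary objective.  The measurement covariance
and the diffusion act as complementary "weights of trust": as
$S \to 0$ the filtered means track the data; as $\sigma \to 0$ they track
the ODE solution.

Numerical choices: the moment equations are integrated by an adaptive
Dormand–Prince (RK45) scheme at relative tolerance $10^{-8}$ (absolute
$10^{-10}$); covariances are symmetrized after every update and negative
eigenvalues are clipped at zero (Joseph-form updates keep this rare);
Jacobians come from registered analytic functions for the bundled models
and central finite differences (relative step $10^{-6}$) otherwise.  A
divergence guard declares a parameter point dead (cost $+\infty$, never an
error or `NaN`) when any moment exceeds $10^{12}\times$ the data scale or
when the integrator needs pathologically many steps in one
inter-observation interval — such points are irrecoverably bad and the
samplers must survive them.  Smoothing (a backward pass) is deliberately
absent: all inference here is filtering, which is what the workflow needs.
The bundled models run through a compiled (C++) implementation of the same
algorithm; the reference R implementation accepts arbitrary user models,
and the test suite pins the two against each other and against an exact
matrix-exponential Kalman recursion on linear models.

## Viability

For ODE models the viability cutoff comes from the expected
log-likelihood of a model that captures all regularities: the standardized
squared-residual sum is $\chi^2_N$, so
$J_{\max} = \tfrac12\left(N + \alpha\sqrt{2N}\right) + \sum_k \tfrac12 \ln\det 2\pi S_k$,
with $\alpha$ the accepted deviation in standard deviations (one-sided,
an upper cost bound; default $\alpha = 3$).  For SDE models that algebra
does not apply and the cutoff is relative: points within $\delta$ orders
of likelihood magnitude of the best point are viable,
$J_{\max} = J_{best} + \delta \ln 10$, with $\delta = 5$ as in the
bundled studies.  The systematic-bias check pairs an exact binomial sign
test with a Wald-Wolfowitz runs test on the innovation signs per
observable (optionally restricted to a declared response window); it
warns, it never vetoes.

## Exploring the viable space

All sampling happens in $\log_{10}$ parameter space (parameters are
positive; a "zero" diffusion is the box lower edge).  `explore()` stages:

* **Screening** — a stratified Latin-hypercube design over the box.  Its
  points double as a uniform sample, so the fraction of them that end up
  viable is an unbiased estimate of the viable volume fraction.
* **Polish** — Nelder–Mead (with one restart) from the best screening
  points, and again from the overall best at the end.  This anchors the
  relative cutoff at the approximate global optimum; without it the
  cutoff floats on whatever the screening happened to find and the whole
  classification drifts.
* **Chains** — multi-chain Metropolis–Hastings on the flattened target
  $\exp(-\max(J, J_{\max}))$: uniform over the viable region, likelihood-
  shaped outside it, so chains climb toward viability and then spread
  over viable plateaus instead of collapsing onto the optimum.  Proposals
  are Gaussian with a per-chain scale adapted toward 30% acceptance;
  box bounds are handled by reflection.
* **Corner probes** — for diagnosis runs, each subset (up to size 3) of
  the declared diffusion parameters is clamped to the box floor and the
  remaining dimensions re-optimized from two starts.  Random walks
  essentially never visit these measure-near-zero corners, yet "is there
  a viable point with these magnitudes negligible?" is exactly the
  question step 5 asks, so the corners are tested directly and the
  evaluations join the sample.  This automates what is otherwise a visual
  inspection of the viable-space projections.

Every cost evaluation from every stage is recorded in the returned
sample; classification (flags, normalized likelihood weights
$w_i \propto e^{J_{best} - J_i}$) is recomputed once at the end against
the final cutoff, so all reported viable points re-classify identically
from their stored costs.

`characterize()` then clusters the viable points (single linkage, cut at
a 1.0 $\log_{10}$ gap), fits one covariance ellipsoid per cluster and
expands each radius while at least half of 200 fresh uniform draws inside
remain viable — a cheap description of the viable region's extent that
also densifies the sample.  `weighted_prediction()` and `infer_hidden()`
aggregate deterministic predictions / filtered hidden-state trajectories
over the viable ensemble with likelihood weights, reporting the weighted
mean and the weighted standard error
$\sqrt{\sum_i w_i^2 (x_i - \mu)^2} / \sum_i w_i$.

`match_term()` closes the loop: four closed-form families over one
covariate $z$ (constant $a$; linear $az$; saturating $a/(b+z)$; switch
$a\,1\{z<b\}$) are fitted to the inferred hidden mean by weighted least
squares and ranked by a small-sample-corrected information score
($n\ln(\mathrm{WRSS}/n) + 2k + 2k(k+1)/(n-k-1)$).  Weights are
inverse-squared standard errors floored at 2% of the trajectory's dynamic
range, so pinned points (a fixed initial value has SE 0) cannot dominate
the fit.  The dictionary is deliberately minimal — Occam's razor over
biologically plausible elementary forms, not symbolic regression.

## Model comparison

`marginal_likelihood()` integrates the EKF likelihood over a *normalized*
uniform prior on the declared $\log_{10}$ box by plain Monte Carlo
(log-sum-exp, delta-method standard error).  Normalization matters: it is
what makes extra, unneeded dimensions (e.g. a diffusion magnitude the
data do not require) cost prior mass, so simpler adequate models win —
the Occam penalty that drives the final rankings.  The prior box is
therefore part of the comparison's declared configuration and is logged
in every report.  Model variants with a diffusion term "eliminated" fix
that magnitude at zero and drop the dimension from the prior.
`bayes_factor()` evaluates both models on the same draw stream (common
random numbers), making the self-comparison exactly zero and the
antisymmetry exact.

Plain Monte Carlo is the default, but over wide boxes it is hopeless
whenever the high-likelihood basin occupies a tiny volume fraction: at
$10^4$ draws the best random draw can sit a hundred log-units above the
optimum, and rankings degenerate into flukes that flatter the most
flexible (largest-noise) model.  The bundled case-study comparisons
therefore use the *stratified* estimator: half the draws come uniformly
from the prior box and half uniformly from inside the model's
characterized ellipsoid regions ([evidence_regions()]), reweighted by the
exact mixture importance density so the estimate still targets the same
normalized-uniform-prior integral.  Ellipsoid draws falling outside the
box are redrawn and the in-box fraction enters the density.

## The bundled case studies

**Pharmacokinetics (PK).**  Drug amount in the gut $Q$ (mg) and plasma
concentration $C$ (mg/l), only $C$ observed:
$\dot Q = -V_{max} Q/(K_m+Q)$,
$\dot C = (1/V)V_{max}Q/(K_m+Q) - (C_L/V)C$.
The synthetic dataset is generated from this saturating model and fitted
with the naive linear-uptake model ($r_1 = k_A Q$).  The generator's
parameters are *reconstructions*, declared once in `R/constants.R`:
$V_{max}=2$, $K_m=1$ mg, $C_L=2$, $V=5$ l, $Q_0=10$ mg, 20 equally spaced
samples on $[0.5, 14]$ h (the window covers absorption, clearance and a
well-sampled saturated tail), proportional noise $\rho = 0.05$.  They were
chosen so the study sits in the qualitative regime the workflow is built
for: absorption saturates and clears within the window, the linear ODE is
systematically (not marginally) incompatible with the data — its best
cost lies far beyond the 5-order viability band — while each *single*
diffusion magnitude can rescue the linear SDE, and the two together are
never simultaneously negligible.  The step-6 extension promotes $k_A$ to
a diffusion-driven state with an estimated initial value (`k_A0`), fixing
the two eliminable diffusions at zero so the promoted state, not a raw
diffusion term, carries the structural error.  The eight comparison models
M1–M8 are the linear/MM SDE variants with all four $\{\sigma_Q, \sigma_C\}$
elimination combinations.

**Glutamine transport in yeast.**  Extracellular and intracellular
glutamine $Q, C$ (mM, both observed) across a metabolic shift at
$t = 0$ min, with a logistic culture input $\epsilon(t) = U(t)V_c/V_f$
scaling uptake to the medium.  The minimal model has one
Michaelis–Menten uptake term; the regulated model (rMM) adds a second
term $W V_2 Q/(K_2+Q)$ gated by an activity state $W$ that rises from 0
by $\dot W = k_w (1-W)\,1\{Q \le K\}$ with threshold $K = 4$ mM (the
bounded form; a capped variant sits behind `w_form = "capped"`).  The
indicator is smoothed over 0.1 mM for integrator and filter robustness.
Extended variants add a third constitutive (e1rMM) and a fourth regulated
micromolar (e2rMM) term.  All generator settings are synthetic stand-ins
for a batch-culture shift experiment: initial $Q$ calibrated so the
activation threshold is crossed near $t = 0$; slow intracellular turnover
($D = 0.01$/min) with a strong regulated term, so the minimal MM model's
misfit appears as a systematic overestimate-then-underestimate bias
around the shift rather than diffuse noise; 23 extracellular points
across the window and 14 intracellular points concentrated on the shift
response (where the hidden mechanism acts); proportional noise
$\rho = 0.05$ floored at a 0.05 mM detection limit (post-depletion points
would otherwise get unrealistically tiny error bars).  The
systematic-bias check combines an exact binomial sign test (optionally on
a declared response window) with a Wald-Wolfowitz runs test on the full
innovation sign sequence; the runs test is what catches the blocked
over/under pattern that a flexible misfitted model leaves after
least-squares level splitting.

What the generators deliberately do *not* emulate: biological replicates,
non-Gaussian or autocorrelated measurement error, sampling jitter,
intrinsic copy-number noise, and any mechanistic transcriptional
regulation behind $W$.  Green tests therefore demonstrate that the
workflow recovers planted structure under its own assumptions — clean
Gaussian proportional noise and a correctly specified error model — not
that it is robust to the full messiness of wet-lab data.

## Problem sizes and defaults

The shipped analyses use deliberately moderate budgets: screening
500–2000 points, 4–8 chains of 400–1000 steps, 6 polish starts, 200
draws per ellipsoid expansion step, a few thousand prior draws per
marginal likelihood (10^4 for the PK Bayes factors).  These reproduce the
qualitative results reliably; all knobs are exposed
(`explore_settings()`, `n_draws`) for heavier runs.

## Known limitations

* Plain Monte-Carlo marginal likelihoods over eight-decade boxes are
  noisy; rankings between closely matched models (within a fraction of a
  log10 unit) fluctuate between seeds.  Orderings asserted by the tests
  are the clearly separated ones.
* The EKF is a first-order Gaussian approximation; strongly nonlinear or
  multimodal state posteriors (and very sparse data) can bias both the
  cost and the inferred hidden trajectories.
* Single-linkage clustering with a fixed 1.0-decade gap can merge viable
  regions connected by thin viable bridges.
* Eliminability is decided by witnesses (corner probes + sampling); a
  corner whose optimum is pathologically narrow could in principle be
  missed.  The probes make this unlikely, not impossible.
* The term dictionary is one-covariate and four families by design;
  structure outside it (products, delays, feedback on unobserved species)
  must be proposed by the modeler.
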