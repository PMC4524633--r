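---
title: "Inferring time-varying enzyme activities in the yeast ceramide subsystem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring time-varying enzyme activities in the yeast ceramide subsystem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ceradyn)
```

## The problem

When baker's yeast is shifted from 30°C to 39°C, the concentrations of its
ceramide species change within minutes — long before any transcriptional
response can act. Those changes are driven by rapid modulation of the
activities of the enzymes that synthesize, interconvert and degrade
ceramides. Enzyme activities cannot be observed directly on this time
scale; what can be measured (by HPLC-MS) are concentrations of the
ceramide species themselves, sampled every 5 minutes over a 30-minute
stress window, in duplicate.

`ceradyn` infers the hidden activity trends from such data. It treats the
ceramide subsystem as a Generalized Mass Action (GMA) model and works in
three stages: (i) smooth and resample the concentration data to a
per-minute grid, (ii) estimate the full flux distribution minute by minute
(dynamic flux estimation), and (iii) convert fluxes to Vmax-like activity
proxies and refine them against the data with a multiple-shooting-style
windowed optimization.

## The model

The subsystem has 15 metabolite pools: five dihydroceramide (DHC) species,
five phytoceramide (PHC) species, and five fatty-acyl-CoA pools, one per
chain-length class (C14/C16, C18, C18:1, C24/C24:1, C26/C26:1). They are
connected by 53 fluxes grouped into nine enzyme classes: ceramide synthase
(10 reactions), dihydroceramidase (5), phytoceramidase (5), IPC synthase
(10), IPCase/Isc1 (10), DHC hydroxylase (5), a remodelase, six elongases
and a desaturase. Sphingoid bases (DHS, PHS), the lumped complex
sphingolipid pool (IPC with its mannosylated forms) and the free-fatty-acid
supply are *boundary drivers* — time-dependent inputs, not states.

Every flux has the GMA form

$$v_j(t) \;=\; a_j(t) \,\prod_{i \in \text{substrates}(j)} X_i(t)
          \,\prod_{d \in \text{drivers}(j)} u_d(t),$$

with all kinetic orders fixed at 1 and the activity $a_j$ — the product of
a rate constant and the enzyme activity, analogous to a $V_{max}$ —
entering linearly. Ceramide synthase fluxes consume the matching
fatty-acyl-CoA pool as a co-substrate, so their inferred activities are
really the product of synthase activity and acyl-CoA availability; the two
cannot be separated from concentration data alone and no attempt is made
to do so.

The pool dynamics are $\dot{x} = S v$ with the 15×53 signed incidence
matrix $S$. `ceramide_network()` builds and validates the bundled default
topology; any alternative wiring can be supplied as a YAML/JSON file.

### Choices where the wiring is genuinely open

The chain-length-resolved wiring of the elongation column is not fully
determined by the pathway literature at this resolution. The default used
here is: remodelase feeds the C14/C16 CoA pool; elongation proceeds
C14/C16 → C18; the desaturase branches C18 → C18:1; both C18 (saturated
route) and C18:1 (desaturated route) elongate into the lumped C24/C24:1
pool; C24/C24:1 elongates to C26/C26:1; and both very-long-chain pools
carry drain fluxes. A literal "two parallel C18 → C24 edges" reading would
make the two elongase fluxes structurally indistinguishable, and the
C24/C24:1 pool must receive C18:1-derived material from somewhere, so the
branched wiring is preferred. It is encoded in the default topology and
fully overridable.

## Stage 1 — preprocessing

Duplicate measurements are pooled and fitted with a cubic smoothing spline
per pool (`fit_smoothing_spline()`), with the smoothing level chosen by
generalized cross-validation by default; the spline degrees of freedom can
be fixed instead, and `"interpolate"` forces the interpolation limit. The
fit is resampled at integer minutes 0–30, and the slope used downstream is
the *discrete difference* $X(t) - X(t-1)$, matching the per-minute
formulation of the flux estimator (the analytic spline derivative is
available for diagnostics only). Negative spline values — smoothing
artifacts, since concentrations are positive — are floored at
$10^{-9}\times$ the mean observed value with a warning.

Pooling the duplicates yields one consensus trajectory per pool;
per-replicate fits remain possible by subsetting the observation table.

## Stage 2 — dynamic flux estimation

At each minute $t = 1,\dots,30$ the 53 fluxes are estimated from the
bound-constrained least-squares problem

$$\min_{0 \le v \le u} \;
  w_s \,\lVert S v - \Delta X(t)\rVert^2
+ w_b \,\lVert A v - b(t)\rVert^2
+ w_m \,\lVert v - v_{t-1}\rVert^2 ,$$

where $A$ sums fluxes over *boundary groups* — subsets whose totals $b(t)$
are known from a prior whole-pathway model (for synthetic data they are
exported from the ground truth by `export_boundary_table()`) — and the
third term asks fluxes to change smoothly between minutes. The three
requirements are combined into a single weighted objective with defaults
$w_s = w_b = 1$, $w_m = 0.1$; no published values exist for these weights,
so they are exposed as configuration. Bounds default to $[0,\,100 \times
v_j(0)]$, with the baseline floored at 1% of its mean so that fluxes with
a tiny baseline are not frozen at zero.

Because 53 fluxes against 15 slope equations and 16 group totals are
underdetermined, the solver is run from `n_restart` random initial
vectors drawn from $U(0.01, 100)$ and the whole ensemble is kept;
mean, median and 20th/80th percentiles per flux and minute are the
reported aggregates, and both mean and median are first-class. The
minute-0 anchor $v_0$ — also the $v_{prev}$ of the first minute — is the
minimum-norm nonnegative flux vector balancing the minute-0 state under
the minute-0 group totals (`baseline_activities()`). Each single solve is
a convex bound-constrained quadratic program, solved by L-BFGS-B on a
precomputed quadratic form; a restart counts as converged when the
optimizer reports success, and only converged restarts enter the
aggregates.

Two diagnostics mirror the validation logic of the approach:
`sse_range_check()` verifies that the slope-fit SSE of the ensemble-mean
flux lies within the range of the individual restarts' SSEs at every
minute (the property that justifies averaging), and `noise_robustness()`
multiplies the per-minute concentrations by independent
$U(1/1.5,\,1.5)$ factors, re-fits the smoothing spline to the perturbed
series (the estimator always consumes splined data; raw independent
per-minute factors would inject arbitrarily large artificial slopes that
no estimator could absorb), re-estimates, and reports two per-flux
quantities: the Pearson correlation between perturbed and clean mean flux
time courses, and their relative RMS deviation. The correlation captures
shared *dynamics* and is only meaningful when the fluxes actually move —
on a steady-state scenario both courses are constants plus estimation
noise, the correlation strips the agreeing means, and its value is
uninformative by construction; the relative RMS deviation measures
closeness regardless of dynamics and is the robust summary there. When
two courses are numerically identical the correlation is defined as 1; if
exactly one is constant it is undefined and reported as `NA`.

## Stage 3 — activities and windowed refinement

Dividing each estimated flux by its mass-action substrate/driver product
yields the activity proxy $a_j(t) = v_j(t) / m_j(X(t))$
(`activity_proxies()`), reported both raw and as fold change of its
minute-0 value. Proxies are smoothed into continuous trends $f_j(t)$ with
nonnegativity flooring (`smooth_activities()`).

The smoothed trends are then refined by a strategy gleaned from multiple
shooting (`shooting_refine()`): the 30 minutes are cut into 3-minute
windows (10 windows; the length is configurable — 5- and 10-minute windows
are known to fit poorly), and within window $w$ the activities are
$C_{j,w} \cdot f_j(t)$. Because the refinement looks for *adjustments* of
the current activity forms, the unrefined point $C = 1$ is always included
as one deterministic start alongside the random starts; the random starts
map the wider solution space and the per-window best-fitting member is
available via `best_coefficients()`. Each window is an independent
initial-value problem starting from the splined concentrations at the
window start —
deliberately *not* from the previous window's simulated endpoint — and the
coefficients minimize the SSE between simulated and splined concentrations
at the minutes inside the window, with every pool divided by its baseline
so that the most abundant species (C26 PHC) does not dominate. With all
$C = 1$ the model is unchanged. The search runs from `n_inits` random
starts per window (drawn from $U(0.1, 10)$, box bounds $[0.01, 100]$), in
log-coefficient space for conditioning, and the whole ensemble of
solutions is retained. `assemble_activity_report()` normalizes every
member's trend to its minute-0 value and averages; discontinuities at
window boundaries are a property of the windowed optimization and are
preserved on purpose.

### Identifiability of window coefficients

Whether one coefficient should be refined per flux or per enzyme class is
genuinely open; the package defaults to per-flux (`by = "flux"`) and
offers `by = "class"`. The choice has a practical consequence: a 3-minute
window of ten measured pools provides 30 residuals, so 53 per-flux
coefficients are underdetermined and random restarts legitimately return
an *ensemble* of equally well-fitting solutions rather than a unique
optimum — which is exactly how the refined trends are reported. Per-class
refinement (9 coefficients) is close to identifiable, with two systematic
exceptions worth knowing about:

* at an exact steady state, scaling *all* activities by a common factor
  leaves the state unchanged, so windows without dynamics cannot pin the
  overall scale;
* the elongation column acts on the unobserved fatty-acyl-CoA pools and
  is only weakly visible through the measured ceramides within a 3-minute
  window, so remodelase/elongase/desaturase coefficients are poorly
  constrained unless the CoA pools are included in the fit.

Self-consistency checks in the test suite therefore use dynamic scenarios
and, where the machinery itself is being verified, full-state
observations.

## The synthetic-data generator

No public accession provides the raw measurements, so the package ships a
generator that emulates the study design: 10 measured pools × 7 sampling
times (0–30 min, every 5 minutes) × 2 replicates, a steady-state start,
heat-stress-like activity perturbations, and independent multiplicative
replicate noise $U(1/1.5, 1.5)$ — the same factor law used for the
robustness analysis; a log-normal option exists for sensitivity studies.
Scenario presets (`scenario_presets()`) encode the qualitative response
shapes — immediate synthase spike, delayed IPCase peak, very-long-chain
synthase undershoot, a sustained step — with all magnitudes synthetic and
labelled as such.

The baseline operating point (`baseline_state()`) spreads pool abundances
over roughly three orders of magnitude with very-long-chain PHC the most
abundant species, mirroring the large spread in ceramide prevalence; the
reference flux circulation is a hand-built strictly positive balanced
flow, and the boundary-group totals it implies make the minimum-norm
balanced flux coincide with it, so the generator's ground truth is exactly
the flux vector the estimator's selection principle targets. This is a
deliberate design decision: with 53 fluxes constrained by 31 equations the
per-minute problem is underdetermined, and recovery of a ground truth is
only a well-posed expectation when that truth is pinned by the same
information the estimator receives. What passing recovery tests show is
therefore that the machinery loses nothing; they cannot show that real
fluxes outside the constrained subspace would be identified, and no such
claim is made. The generator also does not emulate HPLC-MS artifacts
(detection limits, batch effects) beyond multiplicative noise.

## Numerical choices

* ODE integration: stiff-capable adaptive `lsoda`, relative tolerance
  1e-8 / absolute 1e-10 for trajectory simulation; window solves in the
  refinement use a compiled right-hand side at 1e-6 / 1e-9 (the fastest
  pool turnovers are ~30/min, which makes fixed-step explicit integrators
  at practical steps unstable).
* Within windows, the smoothed activity curves are pre-evaluated on a
  0.01-minute grid and interpolated linearly inside the right-hand side.
* Steady-state balancing uses a minimum-norm pseudoinverse solve with an
  active-set nonnegativity polish (no dedicated QP solver is required).
* Flux solves: L-BFGS-B on the precomputed quadratic form; a restart
  counts as converged when the optimizer reports success, the free
  (projected) gradient is below 1e-8, or a polishing restart improves the
  objective by less than 1e-12.
* Coefficient solves: L-BFGS-B in log-coefficient space with exact
  gradients computed by forward sensitivity equations — the window system
  is linear in the states, so the sensitivities obey the same linear ODE
  and integrate alongside the states in one compiled solve. Windows where
  a substrate is pinned at zero propagate zero sensitivity through the
  clipped flux.
* Concentrations are validated nonnegative; trajectories that undershoot
  zero within solver tolerance are clipped at zero with a warning.

## Problem sizes used in the shipped checks

The validation suite runs the estimator at 100 random restarts per minute
and the refinement at a handful of random starts per window; full-scale
runs (1,000 restarts, many shooting starts) change the tightness of the
ensemble bands but not the aggregates in any qualitative way, and remain
entirely practical on a single desktop machine.

## Known limitations

* Activities are identified only up to fold change of baseline; absolute
  magnitudes carry no meaning (the proxy conflates rate constant, enzyme
  amount and, for synthases, acyl-CoA availability).
* Boundary-flux group totals must be supplied for real data; they come
  from a prior, larger pathway model and are inputs here, not estimates.
* The per-minute flux estimates inherit the null-space ambiguity of the
  stoichiometry; the smoothness anchor and ensemble averaging select a
  representative, not a proof of uniqueness.
* C20/C22 ceramides, measured in the original design but excluded from
  the chain-class set, are not represented; whether they fold into the
  C24/C24:1 class is unknown.
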