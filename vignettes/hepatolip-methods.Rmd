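---
title: "hepatolip: model, parameters and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hepatolip: model, parameters and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hepatolip` simulates cholesterol and lipoprotein handling by hepatocytes
in culture as a deterministic mass-action ODE system with 21 states in a
fixed canonical order (`hl_state_names()`). Three compartments are
represented implicitly through scaling constants: the nucleus (`J`), the
cell (reference volume), and the medium (`W`, the medium-to-cell volume
ratio; extracellular balance equations carry a `1/W` dilution).

The mechanistic blocks are:

1. **Transcription under sterol feedback.** HMGCR, LDLR and PCSK9 are
   transcribed when SREBP-2 occupies their promoters; cholesterol binds
   and inactivates SREBP-2 cooperatively. The rate is
   `mu* / (1 + [kappa (1 + (c/kc)^xc)]^x_gene)` — strictly decreasing in
   cholesterol `c`, maximal `mu*/(1 + kappa^x_gene)` at `c = 0`.
2. **Translation, transport, degradation.** Linear chains
   mRNA → protein, LDLR transport to the membrane (`gamma_r`), PCSK9
   secretion (`gamma_p`). Intracellular PCSK9 degradation `delta_p` is 0
   in the default set: the intracellular pool drains only by secretion.
3. **Receptor-mediated endocytosis.** Free surface receptors `r_f` bind
   LDL/VLDL/PCSK9 (each particle covering `M` receptors). Bound particles
   internalise at rate `beta`; unbound receptors internalise through empty
   pits at `beta_0 r_f / P` (`P` receptors per pit). Internalising a bound
   particle also co-captures free receptors in the occupancy ratio
   `r_f : (rf0 - r_f)`, so the total receptor flux per internalised
   particle is `M rf0 / (rf0 - r_f)`. A fraction `f` of receptors from
   LDL/VLDL vesicles and empty pits recycles to the internal pool;
   **nothing recycles from PCSK9-containing vesicles** — that asymmetry is
   the PCSK9 degradation mechanism. The `(rf0 - r_f)` denominator is a
   genuine singularity at full surface occupancy; the right-hand side
   raises an explicit "occupancy singularity" error rather than returning
   garbage (in the default regime `r_f` stays below ~0.1 `rf0`).
4. **Lipoprotein pools and cholesterol.** Extracellular, receptor-bound
   and internalised LDL/VLDL; VLDL delipidates to LDL (`chi_v`) and enters
   from a constant source `omega_V`. Cholesterol is produced by HMGCR
   activity (`mu_c h`) and extracted from internalised particles
   (`R_chol gamma` per particle), and is cleared at `delta_c`.
5. **Therapies.** Statin enters the cell (`CL_S`), reversibly sequesters
   HMGCR (`eps_S`, `eps_minus_S`); anti-PCSK9 agents bind extracellular
   PCSK9 1:1 (`eps_p`, `eps_minus_p`). The small-molecule variant is the
   antibody with a 10x larger association and 10x smaller dissociation
   rate (both factors configurable), encoding its smaller size and higher
   diffusivity.

Two exact linear identities follow from the equations and are enforced in
tests to machine precision: the antibody mass `W*A_E + p_AB` changes only
through the antibody source, and the statin mass `W*S_E + S_i + S_ih`
only through the statin source.

## Dimensional and dimensionless forms

The package carries both the dimensional system (molec./mL, seconds) and
the non-dimensionalised system that is actually integrated. The rescaling
uses the time scale `tau = 1/delta_mh` (~6.2 h) and per-species reference
concentrations: `m0` (mRNAs), `s0` (HMGCR; also the SREBP-2 pool that
absorbs the `s0` divisor of the dimensional transcription term into
`kappa`), `rf0` (receptors — simultaneously the physical surface
capacity), `l0`/`v0` (lipoproteins), `c0 = kc` (cholesterol),
`pE0_ref` (all PCSK9 and antibody pools) and `sE0` (statin pools). The
scale ratios `nu_l, nu_v, nu_p` (lipoprotein/receptor), `rho_v`,
`sigma_l, sigma_v` (lipoprotein/cholesterol) and `zeta_S` (statin/protein)
appear only in the dimensionless system. `nondimensionalize()` /
`dimensionalize()` implement the map and its exact inverse; the defining
contract — rescaled trajectories of the two systems coincide — is tested
to 1e-6 relative (it passes at ~1e-10).

## Parameters: provenance and the calibration of assumed values

Every parameter in `inst/extdata/parameters_default.tsv` carries a
provenance tag. `table1` values are the published ones for the
PCSK9/therapy extension (e.g. `kappa_mp = 8.21e16` molec/mL,
`delta_mp = 4.48e-5` 1/s, `beta_p = 2.7e-3` 1/s, `alpha_p = 1e-17`
mL/(molec s), `delta_p = 0`). `parent_model` marks values those entries
attribute to the parent cholesterol-endocytosis model and that we
propagate to the sibling symbols (mRNA degradation, gene affinities,
internalisation rates). Everything else is `assumed`: the parent model's
full numeric table is not available here, so those values
were fixed **once**, before the acceptance suite was frozen, by a flux
balance argument plus a single forward calibration pass:

- `W = 500` — a 0.2% cell-to-medium volume fraction, typical of culture;
  it also sets the washout clearance of an external PCSK9 bolus
  (`alpha_p r_f / W`, half-life of hundreds of hours), which must be slow
  on the 500 h read-out scale for dose effects to be measurable.
- receptor economy (`mu_mr_star = 6e6`, `gamma_r = 1e-2`, `beta_0 =
  2.7e-3`, `P = 20`, `f = 0.7`, `rf0 = 5e13`) — sized so that (i) LDLR
  production comfortably exceeds PCSK9 secretion (otherwise receptors
  cannot clear secreted PCSK9 and no positive steady state exists), and
  (ii) endogenous steady extracellular PCSK9 lands near 1e12 molec/mL
  (~100 ng/mL, a physiological circulating level).
- `M_v = 4` (receptors per VLDL, vs `M_l = 1`) — with the initial guess
  of 10, VLDL-borne receptor co-internalisation dominated baseline
  receptor turnover and pushed the PCSK9 LDL-elevation threshold a decade
  high; 4 puts the threshold at 1e13 molec/mL, inside the published
  1e12–1e13 onset bracket (elevations: 2.8% at 1e12, 22% at 1e13).
- sterol feedback (`s0 = 8.21e15` so the dimensionless gene affinity is
  10; `kc = 1e17`, `xc = 4`, `delta_c = 5e-5`, `mu_c = 1.4`) — places
  steady cholesterol near `0.8 kc` where the cooperative feedback is
  active, giving the damped oscillatory approach of the mRNAs and roughly
  equal endogenous-synthesis and lipoprotein-derived cholesterol fluxes.
- lipoprotein load (`omega_V = 2.5e6` molec/(mL s), `alpha_l = 1e-16`,
  `alpha_v = 5e-16`, `chi_v = 1e-5`) — VLDL binds faster than LDL (as the
  original model description notes) and extracellular LDL/VLDL settle over ~100 h,
  reproducing the slow lipoprotein kinetics.

These choices were not revisited after the tests were written. They are a
*reconstruction* of a plausible parent parameter set, not the published
one: quantitative agreement with the original figures is therefore not
claimed anywhere — the tests assert the stated qualitative orderings and
the two printed quantitative anchors (the threshold bracket and the
ng/mL equivalence).

## What the scenarios emulate — and what a green test does not establish

Scenario presets reproduce the in-silico protocol of adding components to
the medium at chosen times: boluses are state jumps, influxes are
piecewise-constant sources over half-open windows `[start, end)` (so
abutting windows never double-count). All dose-response metrics
(threshold scan, therapy metrics, sensitivities) are read at the **500 h
plateau** of the experiment, not at the true fixed point: a dosed bolus
is eventually consumed by receptor-mediated uptake, so the infinite-time
fixed point is dose-independent and every dose-dependent "steady state" in
this model class is necessarily a finite-horizon plateau. (At the true
fixed point, PCSK9 receptor consumption exactly balances PCSK9 secretion,
which would make sensitivities to the binding kinetics structurally zero;
`local_sensitivity(at = "fixed_point")` exposes that reading.)

A green suite establishes internal consistency (conservation,
dimensional/dimensionless equivalence, integrator cross-checks), the
qualitative pharmacology (statin and anti-PCSK9 dose responses, small
molecule > antibody, combined > monotherapies) and the two printed
quantitative anchors. It does not establish agreement with wet-lab data,
nor with the original figures' numeric axes, and real hepatocyte cultures
feature medium exchange, cell growth and death, and statin metabolism that
the model omits.

## Numerical choices

- **Integrator.** No stiff ODE solver package is available in the target
  environment, so the package ships its own: an L-stable adaptive
  Rosenbrock 2(3) pair (the classic `ode23s` scheme) in C++ with a
  forward-difference Jacobian per step, cubic-Hermite dense output, and
  integrator restarts at every event boundary so discontinuities never
  cross a step. Defaults: `rtol = 1e-8`, `atol = 1e-12` (dimensionless).
  A fixed-step classical RK4 and a pure-R Rosenbrock twin provide
  independent routes; adaptive-vs-fixed agreement is tested at 1e-4 over
  50 h (observed ~1e-7).
- **Negative values.** Integration undershoots more negative than
  `neg_tol` (default 1e-9 dimensionless) abort with the component named;
  smaller undershoots are clipped to zero. The clip threshold is
  deliberately larger than `atol`: an interpolation undershoot of order
  `rtol * |y|` on an O(1) component is roundoff, not a model bug.
- **Steady states.** `method = "root"` integrates to a 1e-6 residual and
  polishes with a damped Newton using a truncated-SVD pseudo-inverse;
  `method = "long_run"` integrates until the residual stalls on the
  adaptive-step noise floor (~`rtol * ||J||`) and finishes with an
  implicit-Euler pseudo-transient continuation — the h→∞ limit of the
  same implicit scheme — down to the 1e-10 tolerance. Handing over to
  Newton too early fails: the slow PCSK9-washout mode leaves the state
  tens of units from the fixed point, outside the full-step basin.
- **Neutral directions.** The two conservation laws make the Jacobian
  exactly singular at every fixed point. The `stable` flag therefore
  ignores up to two eigenvalues below 1e-8 of the spectral radius and
  requires all remaining real parts negative.
- **Time units.** Hours at every interface (axes of the figures),
  seconds/dimensionless internally; the conversion lives in one place.

## Known limitations and open-ended choices

- The statin dose magnitude for the single-dose experiment is not
  published; the preset defaults to a 1e12 molec/mL bolus at t = 10 h
  (micromolar-range medium concentration), exposed as an argument, and a
  brief-influx variant is available (`mode = "influx"`).
- At `W = 500` and the published uptake clearance, statin equilibration
  into the cell takes ~10 h, slower than the "minutes-scale" delay the
  original model description suggests; the volume ratio was prioritised for the
  quantitatively printed PCSK9 bracket instead.
- Combined statin + anti-PCSK9 therapy is mildly super-additive here
  (the agent protects statin-induced receptors), so only the lower
  additivity bound (combined ≥ each monotherapy) is asserted.
- Statin pleiotropic (LDL-independent) effects, chylomicrons, IDL/HDL
  fractions, enterohepatic circulation and any whole-body coupling are
  out of scope by design.
- The sensitivity module is a central-finite-difference stand-in
  (`h_frac = 0.01`, Richardson-checked); zero-valued parameters are
  perturbed additively against a documented reference scale because a
  multiplicative perturbation of zero is degenerate.
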