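---
title: "Methods: hidden-state SSE simulation, incomplete sampling, and model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hidden-state SSE simulation, incomplete sampling, and model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

State-dependent speciation–extinction (SSE) models ask whether an observed
("examined") trait drives lineage diversification. Because an unmeasured
trait may be the real driver, modern practice compares an examined-trait
dependent model (ETD) against a concealed-trait dependent model (CTD, the
character-independent alternative) and a constant-rate model (CR). Real
phylogenies are incompletely and often non-randomly sampled, and the
sampling fraction (SF) supplied to the likelihood may itself be wrong.
`ssesim` provides every ingredient needed to study how tree completeness,
taxonomically biased sampling, and SF mis-specification affect this model
comparison: a trait–tree simulator, trimming routines, a hidden-state SSE
likelihood with per-state sampling fractions, ML fitting with AICc model
selection, study-level error metrics, a config-driven experiment driver, and
a reduced Bayesian arm that places a prior on the SF.

## The generating model

Two independent ternary traits evolve on a clade: an examined trait with
states 1, 2, 3 and a concealed trait with states A, B, C. Their combination
yields nine states (1A, ..., 3C). Transitions are symmetric, one state at a
time at a single rate *q* = 0.4 events/lineage/MY; double transitions (1A to
2C) are impossible, so each combined state has four one-step neighbours.
Speciation is trait-dependent according to the generating mode:

* **ETD**: lambda depends on the examined state only (0.1, 0.3, 0.5 by state);
* **CTD**: lambda depends on the concealed state only (same three values);
* **CR**: all nine states share lambda = 0.3.

Extinction is shared across states, either "low" (0.001) or "regular"
(0.05). Simulation is an exact Gillespie algorithm from the crown: waiting
times are exponential in the summed per-lineage event rates, a
lineage-and-event is chosen proportionally to its rate, and every trait
transition is logged with its lineage and time. Extinct lineages are pruned,
leaving an ultrametric tree whose depth is the crown age. Size classes
follow the study design: large (1000–5000 tips, 23 MY), medium (450–650,
19 MY), small (100–250, 13.4 MY); tip-count bands are met by rejection
sampling, with acceptance counts logged.

Decisions where the design was open:

* **Root state** is drawn uniformly from the nine combined states and given
  to both crown lineages; with symmetric transition rates the uniform
  distribution is stationary, so nothing else would be self-consistent.
* **Small-tree band**: the source study states both 100–250 and 150–250 in
  different places; the default is 100–250 and the band is a parameter.
* **Extinct clades** (including loss of all descendants of either crown
  lineage) signal a typed condition and are resampled with a fresh derived
  seed; attempts are counted, mirroring a retained-trees-only design.
* **Seeding**: every tree, trim and fit derives its own 32-bit seed from
  `(master seed, index)` so downstream steps never perturb the simulation
  stream and any subset of the pipeline is reproducible in isolation.

## Trimming

`random_trim()` removes tips uniformly to `round(SF * N)` tips.
`biased_trim()` emulates taxonomic bias: one or two sub-clades containing
20–30% of tips are chosen (non-nested, uniformly among eligible nodes) and
80–90% of their tips removed, then background tips are removed until the
achieved SF is within ±2% of the target. If the heavy trim alone overshoots
below the tolerance band the removal fraction is redrawn once before an
infeasible-target condition is raised — the tolerance band, not hard
determinism, is the contract. Trees whose sub-clade shares never enter the
eligibility window raise an ineligible-tree condition and are resampled by
the experiment driver. Tip removal never consults trait states. Trimmed
trees stay ultrametric; if a deepest lineage is lost the crown age shrinks
and is *not* re-dated, matching how such trees would be analysed in
practice.

`transition_loss_summary()` counts recorded transitions that are visible on
the complete extant tree but have no surviving descendant among the trimmed
tips, per ordered state pair and per trait — the diagnostic used to ask
whether trimming removes examined- and concealed-trait history
asymmetrically.

## Likelihood

The hidden-state SSE likelihood integrates, along each branch toward the
root, extinction probabilities `E_i(t)` and partial likelihoods `D_i(t)`
for each combined state *i*:

```
dE_i/dt = mu_i - (lambda_i + mu_i + sum_j q_ij) E_i + lambda_i E_i^2 + sum_j q_ij E_j
dD_i/dt = -(lambda_i + mu_i + sum_j q_ij) D_i + 2 lambda_i E_i D_i + sum_j q_ij D_j
```

with `q_ij = q` on one-step neighbours and 0 elsewhere. Sampling fractions
enter only the tip conditions: `E_i(0) = 1 - rho(examined(i))` and
`D_i(0) = rho(observed)` on the states compatible with the observed examined
state. At a node `D_i = lambda_i D_i(left) D_i(right)`. At the root, with
weights `w_i`, the likelihood is `sum_i w_i D_i / (lambda_i (1 - E_i)^2)`
under survival conditioning.

Numerical choices:

* **Integrator**: adaptive Dormand–Prince 5(4) in compiled code, default
  relative tolerance 1e-8 and absolute 1e-10; the accepted step size is
  carried across branches as a warm start. No matrix-exponential shortcut is
  used on the nonlinear system.
* **Underflow**: `D` is rescaled to unit sum after every branch and the log
  factors accumulate into the log-likelihood.
* **Root weighting** defaults to likelihood-proportional (FitzJohn) weights
  computed before conditioning; equal weights and a fixed vector are
  available because the conventions differ across SSE implementations and
  the source study does not pin them down. Survival conditioning defaults
  on, and is a flag.
* **E monotonicity**: from `E(0) = 0` (complete sampling) `E` rises
  monotonically to its fixed point. With `rho < 1` the initial value
  `1 - rho` may exceed the fixed point `mu/lambda` and `E` then *decreases*
  toward it; this is correct behaviour of the Riccati flow, so the test
  suite asserts monotonicity only under complete sampling and boundedness
  everywhere.

The model parameterizations map free vectors to the nine-state rate set:
ETD and CTD have 5 free parameters (three lambdas + mu + q), CR has 3, and
the combined ECTD frees all nine lambdas (11 parameters). The same machinery
instantiates the 2x2-state system of the Bayesian arm.

## Fitting and model selection

Rates are optimized on the log scale (box 1e-6..10) by Nelder–Mead with up
to 10 restart cycles; each restart jitters the incumbent optimum (sd 0.5 on
the log scale) and convergence is declared when a cycle improves the
log-likelihood by less than 1e-6. Starts use a Yule-magnitude heuristic
(`lambda0 = log(N/2)/T`, `mu0 = lambda0/10`, `q0 = 0.1`). AICc uses the
tip count of the *fitted* (trimmed) tree as the sample size — the external
tools the study relied on do not document their convention, so it is
explicit and configurable here. Lowest AICc wins; exact ties break to the
smaller parameter count and then the fixed order CR < CTD < ETD < ECTD,
conservative against false detection of trait dependence. Non-converged
fits are excluded from selection with a warning.

False positives are ETD selections on CTD- or CR-generated data over all
CTD+CR datasets; false negatives are non-ETD selections on ETD data.
Parameter summaries are computed over all trees regardless of which model
won selection, and net diversification per examined state
(`lambda_s - mu`) always comes from the ETD fit. The Sackin imbalance index
is reported primarily as the mean root-to-tip node-count path (with the
classical summed form alongside).

## Experiment driver

`run_experiment()` executes one arm of the design — size class x extinction
level x SF levels x regime x (correct + mis-specified) SF settings — writing
fits, selections and rate summaries to CSV plus a JSON-lines run log, with
per-replicate task fragments making a rerun resumable and byte-identical.
The mis-specification grid is validated against the study design (true SF
1.0 may be specified as 0.8; 0.8 as 1.0/0.6; 0.6 as 1.0/0.8/0.4; 0.4 as
1.0/0.8; 0.2 admits none). Mis-specified runs use the *nominal* SF as truth
and record the achieved one. For biased-trimmed trees the specified rho is
still the global SF — SSE likelihoods assume missing tips are random, and
that mismatch is precisely the object of study. Configs are JSON (the
environment provides no YAML parser; the schema is one flat object, see
`inst/extdata/demo_config.json`). `cli()` exposes `simulate`, `trim`,
`fit`, `experiment` and `summarize` subcommands.

## Bayesian arm

The reduced arm uses 2 examined x 2 concealed states on 100–250-tip trees
(crown age 13.4 MY, ETD rates 0.1/0.5, mu = 0.001, q = 0.4 — the source
study does not restate its two-state rates, so these keep the 3-state
magnitudes and contrast). A single global sampling fraction rho applies to
both observed states and carries a uniform prior: wide U(0.3, 0.9) or
narrow U(0.5, 0.7). Rate priors are exponential with mean 1 on speciation
and extinction and mean 0.5 on the transition rate (not stated by the
study; chosen weakly informative at the rates' magnitude, and
configurable). Sampling is adaptive Metropolis-within-Gibbs on log-rates
and logit-rho; marginal likelihoods come from stepping-stone sampling with
powers at Beta(0.3, 1) quantiles, default 50 stones, warm-started along the
ladder, with a delta-method standard error. The dependent/independent
choice is by Bayes factor, ties conservatively to independent.

## What the synthetic data does and does not establish

The generator *is* the stated world of the study design: rates, crown ages,
size bands and SF levels above. It does not emulate topology or
branch-length estimation error, trait measurement error, diversified or
clade-specific sampling, asymmetric transition rates, or state-dependent
extinction — all outside scope. A green test therefore certifies the
behaviour of the inference machinery under the generating model, not
robustness to those additional real-data pathologies.

The test suite's replication study is scaled down to fit a CI budget:
8–16 replicates per condition instead of 100, likelihood tolerances 1e-6 /
1e-8 in the fitting loops, and the false-positive-inflation contrast is run
on medium trees at SF 0.8 vs {0.4, 0.2} pooled — the size class where the
source study reports that inflation most clearly (its small-tree false
positive rate actually *falls* slightly from SF 100 to SF 40 while false
negatives explode, and the small-tree arm here asserts exactly that
pattern). At these replicate counts the rate comparisons are directional
checks with sampling noise of several percentage points; the
`inst/extdata/full_scale_config.json` arm reproduces the quantitative rates
but needs cluster-scale compute.

## Known limitations

* The likelihood supports neither ambiguous tip states nor clade-specific
  sampling fractions.
* Nelder–Mead with jittered restarts is robust but not fast; the
  11-parameter ECTD surface in particular can exhaust its cycles without
  converging, which is reported honestly in `fit_result$converged` (and
  matches the behaviour the study describes for that model).
* Stepping-stone standard errors ignore residual autocorrelation within
  rungs and are mildly optimistic; ladder-refinement self-consistency is
  tested instead.
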