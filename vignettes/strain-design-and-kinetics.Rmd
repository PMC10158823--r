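---
title: "Constraint-based strain design and batch kinetics with kivflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based strain design and batch kinetics with kivflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kivflux)
```

`kivflux` supports the two computational halves of engineering a
2-ketoisovalerate (2-KIV) overproducing *E. coli* strain: deciding *in
silico* which gene deletions reroute carbon towards the branched-chain
keto acid pathway, and quantifying the resulting batch cultures.  This
vignette explains the models behind each function, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The steady-state flux model

A constraint-based metabolic model is a stoichiometric matrix **S**
(metabolites x reactions) with per-reaction flux bounds and
gene-protein-reaction (GPR) boolean rules.  Flux balance analysis (FBA)
assumes the metabolite pools are at steady state and solves

$$\max_v c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

with fluxes in mmol gDCW⁻¹ h⁻¹ (the biomass pseudo-reaction in h⁻¹) and
the convention that a negative exchange flux is uptake.  The LP is
solved by a bounded-variable two-phase primal simplex using Bland's
smallest-index rule, which terminates on the heavily degenerate vertices
flux cones produce.  Tolerances: pivot/feasibility 1e-9 at the solver,
1e-6 at reporting; fluxes below 1e-9 in magnitude are reported as exact
zeros.  Alternate optima are *not* resolved — `solve_fba()` returns
whichever optimal vertex the pivot path reaches, and any uniqueness
question should go through `run_fva()`, which brackets each reaction's
flux at a stated fraction of the optimum (two LP solves per reaction).

Models arrive either through `read_sbml_fbc()` — the SBML Level 3 + FBC
subset that genome-scale reconstructions actually use: species,
reactions, parameter-referenced flux bounds, the active objective, and
gene-product association trees; any *other* required SBML Level 3
package is rejected outright — or through a line-oriented native
dialect (`read_native_model()` / `write_native_model()`) whose write/read
round trip is exact.  Explicitly infinite SBML bounds are replaced by
±1000, the community convention that keeps the LP bounded; reaction and
metabolite order is file order, and all matrix indices derive from it,
so S construction is deterministic.

### Knockouts and the secretion route

`apply_gene_knockouts()` evaluates each reaction's GPR rule with the
deleted genes set to false (empty rule = unconditionally present,
case-insensitive `and`/`or`, parentheses) and sets the bounds of every
disabled reaction to `[0, 0]`.  Knocked-out reactions are *not* removed:
keeping the matrix shape identical across scenarios makes sampled flux
matrices directly comparable column-by-column.  Unknown gene ids are an
error rather than a silent no-op, since a typo would otherwise
masquerade as a neutral deletion.

Wild-type genome-scale models typically cannot excrete 2-KIV.
`add_secretion_pathway()` grafts a secretion route onto the model: one
transport reaction per compartment hop along the chain (cytosol →
periplasm → extracellular on a three-compartment model, hence exactly
three added reactions there) plus a terminal irreversible exchange, all
with bounds `[0, 1000]` — outward only, because only secretion is being
granted.  Pre-existing reactions are untouched, and an existing route is
an error rather than a duplicate.

### The growth medium

Genome-scale models carry no intrinsic medium, and the uptake rates
behind a published simulation are rarely stated.  `apply_medium()`
implements the common single-carbon-source convention: the designated
carbon exchange gets lower bound −10 mmol gDCW⁻¹ h⁻¹ (overridable) and
every other exchange keeps uptake closed (lower bound raised to 0,
secretion open).  Likewise, whether a sampling study optimised biomass
or product is usually unstated, so the evaluation reports *both* FBA
optima and leaves the ranking statistic as an explicit parameter rather
than guessing intent.

## Monte Carlo sampling of the flux polytope

FBA returns one optimal vertex; the *distribution* of feasible fluxes is
what distinguishes knockout designs whose optima tie.  `sample_achr()`
samples the polytope `{v : Sv = 0, lb ≤ v ≤ ub}` with
artificially-centered hit-and-run (ACHR), the sampler family standard in
the constraint-based modelling toolboxes: directions are differences
between a randomly chosen stored point and the running center (so the
chain stretches along the polytope's long axes without an explicit
rounding transform), the step is uniform on the feasible segment, and
the center updates incrementally.  Warmup is the classical 2n FVA
extreme-point set.

Numerical choices: chain states are re-projected onto the null space of
S (orthonormal basis from an SVD) whenever the steady-state residual
exceeds 1e-9, so every recorded point satisfies `|Sv| ≤ 1e-6` and bounds
to 1e-8; reactions fixed by their bounds (knockouts) are pinned to that
value *exactly* at every step; a polytope that collapses to a single
point is returned as that point replicated.  Seeds are mandatory — there
is no wall-clock entropy anywhere — and identical seeds give
bit-identical sample matrices.  The production-scale default is 35,000
recorded points with thinning 100; the test suite and the examples use
a few thousand points with thinning 5–10, which already separate the
knockout scenarios on the desk-scale network.  Histograms default to 50
equal-width bins over the observed range.

`evaluate_scenario()` composes the pieces — augment, knock out, two FBA
solves (biomass and product), sample, summarise the target reactions —
and `rank_scenarios()` orders designs by a chosen statistic (mean,
median or 95th percentile) of a target reaction's sampled flux, minus an
optional penalty weight times the same statistic of a byproduct reaction
(acetate secretion being the canonical penalty).  The default penalty
weight is 0, i.e. a pure flux-frequency comparison; ties break
alphabetically by scenario name so reports are permutation-invariant.

## Batch kinetics

The estimators operationalise the textbook batch model.  The maximum
specific growth rate is defined by $\mu_{max} = \frac{1}{X}\frac{dX}{dt}$
during exponential growth, which integrates to linearity of ln *X* in
*t*; `fit_mu_max()` is therefore an ordinary least-squares slope over an
exponential-phase window, making the estimate invariant to any positive
rescaling of the biomass signal.  `detect_exponential_phase()` picks the
window by scanning every contiguous window of at least `min_points`
observations (default 4, the smallest window where an R² is meaningful)
and maximising the R² of ln *X* vs *t*.  Ties within 1e-9 go to the
*longest* window, then the earliest — a pure exponential curve thus
reports its full range, while a window ending in stationary phase loses
to the clean exponential stretch.  A zero-variance (flat) stretch scores
R² = 0 rather than a vacuous 1, which is what keeps plateaus from
winning; a fully constant curve still yields µmax = 0 as the slope.

Yield coefficients are endpoint-delta ratios over the whole batch
(Yx/s = ΔX/ΔS, Yp/s = ΔP/ΔS, Yp/x = ΔP/ΔX, all g/g), matching how batch
tables report "total substrate uptake"; `estimate_kinetics()` applies
them per replicate after the optional OD600 → dry-cell-weight conversion
(`od_to_dcw()`, factor 0.452 g DCW/L per OD unit, the strain's
calibration; `linear_calibration()` provides the generic linear fit for
other standard curves).

### Duncan's multiple range test

Conditions are compared with Duncan's multiple range test
(`duncan_mrt()`), the protected step-down range procedure: after a
one-way ANOVA, the sorted means are tested span-by-span against the
least significant range
$LSR_p = q_{1-\alpha_p}(p, df)\sqrt{MSE/n_h}$ with protection level
$\alpha_p = 1-(1-\alpha)^{p-1}$, where $q$ is the studentized-range
quantile (base R's `qtukey`, i.e. the distribution's CDF inverted
numerically — no 1955 table lookups) and $n_h$ the harmonic mean group
size, the standard approximation under unequal replication.  A
non-significant range freezes all its sub-ranges untested, which is what
makes the family error under a complete null exactly the protection
level of the full span — the property the test suite verifies by
simulation.  With two groups the procedure provably collapses to
Fisher's LSD.  Homoscedasticity is assumed (the pooled MSE is used
throughout); zero pooled variance is handled exactly (unequal means are
then always significant).  The letter display is built from maximal
non-significant stretches of the sorted means, so it is transitive by
construction.

## The synthetic-data generator

`make_toy_network()` builds a 15-reaction, single-compartment (+
extracellular) mirror of the decision problem at desk scale: lumped
glycolysis to pyruvate, the pyruvate dehydrogenase → TCA branch, the
ACLS → KARA → DHAD → export branch to 2-KIV, an acetate overflow drain
from acetyl-CoA, a transhydrogenase, an NADH-oxidising respiration lump,
a biomass drain and ATP maintenance.  Cofactors are explicitly balanced
so the NADPH demand of the reductoisomerase is a real constraint — the
same cofactor argument that favours malate-dehydrogenase co-deletion in
the full-scale design — and the key reactions carry gene labels (PDH:
aceF, ACLS: alsS, KARA: ilvC, DHAD: ilvD, TCA: gltA) so knockout logic
is exercised end to end.  Its optima are hand-derivable: each glucose
gives two pyruvate, biomass consumes one pyruvate-equivalent per unit
and 2-KIV condenses two, so max biomass = 2u and max 2-KIV export = u at
uptake cap u, linearly in u.  These closed forms are what the test suite
asserts against the LP.

`simulate_batch_culture()` generates growth curves from the same model
the estimators assume: exponential biomass until yield-coupled substrate
exhaustion, then a plateau, with product formation proportional to
substrate consumed.  Defaults reflect a realistic production batch for
this organism: inoculum 0.452 g DCW/L (an OD of 1.0), µ = 0.5 1/h,
Yx/s = 0.4, Yp/s = 0.2, 10 g/L substrate, hourly sampling over 24 h,
2% multiplicative lognormal measurement noise (concentrations are
positive, so noise is multiplicative and its sd is read on the log
scale), duplicate cultures.  What it deliberately does **not** emulate:
lag phases, diauxie or multi-substrate kinetics, substrate inhibition,
death phase, pH drift, or correlated instrument error.  Passing the
recovery tests therefore shows the estimators are correct *under the
stated batch model*, not that real shake-flask data will be this clean —
on real curves the exponential-window detection is doing the work the
noise model here does not probe.

`make_table2_fixture()` returns the published 24 h endpoint records of
the engineered producer strain on glucose, lactose and whey lactose
(substrate uptake, 2-KIV titer, the whey L-valine titer, and the printed
yields for cross-checking).  Two published quirks are taken at face
value and flagged rather than "fixed": the printed Yp/x values are not
reproducible from the printed Yx/s and substrate columns (they
presumably used unrounded biomass, so Yp/x is excluded from the checks),
and the whey Yp/s of 0.81 g/g is treated as a lower bound since the
printed inputs give 3.22/3.9 = 0.826 (likely a consumed-vs-total lactose
distinction).

## Pipelines, determinism, and problem sizes

`run_design_pipeline()` and `run_kinetics_pipeline()` drive the two
workflows from a YAML config (see `default_design_config()` /
`default_kinetics_config()` for every recognised field and default).
Both write CSV/text reports plus a log carrying the seed, config hash
and model hash — enough metadata to reproduce any output file — and both
are byte-deterministic under a fixed config and seed.  Stage failures
abort with the stage name and cause.

The validation suite runs at desk scale by design: LP agreement with an
independent HiGHS oracle on 100 random networks of up to 20 reactions,
sampler feasibility at 5,000 points on the toy network, knockout
ordering cross-checked against a uniform rejection sampler, Duncan
calibration with 1,000 null replicates.  These sizes were chosen as the
smallest that make the statistical assertions sharp; all scale knobs
(points, thinning, bins, replicates) are function arguments.

## Known limitations

* The simplex is dense and single-threaded: fine for networks up to a
  few thousand reactions (one genome-scale FBA solve), but FVA or
  warmup generation on a full reconstruction costs 2n solves and is
  better run once and cached via the native dialect.
* ACHR provides no rounding transform; on extremely elongated polytopes
  mixing can be slow and thinning should be raised.
* Only the FBC subset of SBML is read; kinetic (ODE) SBML semantics are
  out of scope, as are MILP-style design methods (OptKnock and
  relatives) and dynamic FBA.
* Duncan's test assumes homoscedastic groups; with strong variance
  heterogeneity the letter display inherits the pooled-MSE bias.
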