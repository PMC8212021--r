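---
title: "Modeling MSC lineage metabolism: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling MSC lineage metabolism: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemkit)
```

This vignette documents the models and numerical procedures behind
`gemkit`, the assumptions they rest on, and the design decisions taken
where several defensible choices existed. It is the reference companion
to the function documentation: nothing here states an empirical result
that the package's tests do not themselves compute.

## 1. The modeling frame

All analyses operate on a constraint-based metabolic model: a
stoichiometric matrix $S$ (metabolites $\times$ reactions), flux bounds
$\ell \le v \le u$ in mmol gDW$^{-1}$ h$^{-1}$, and the steady-state
assumption $S v = 0$. Boundary (exchange) reactions follow the
community sign convention: negative flux is uptake, positive flux is
secretion. Bounds absent from an input file default to $\pm 1000$, the
de facto "unconstrained" value in genome-scale models. Gene-protein-
reaction (GPR) rules are boolean expressions over gene ids with `and`
binding tighter than `or`; `and` nodes represent complex subunits,
`or` nodes isozymes.

Steady-state FBA deliberately ignores kinetics, regulation and
thermodynamic driving forces; reversibility is encoded only through the
bounds. Flux vectors at alternative optima are not unique - the package
treats the *objective value* as the contract and never asserts
individual fluxes of an optimal vertex.

## 2. The linear-programming layer

No dedicated LP solver package is available to depend on, so the
package ships a dense two-phase primal simplex for bounded variables
(`R/lp.R`). Design points:

* variable bounds are handled natively (no $x \ge 0$ substitution and
  no explicit bound rows), keeping the basis at the number of
  metabolites;
* Bland's smallest-index pivoting rule guarantees termination on the
  heavily degenerate bases that metabolic networks produce;
* the basis inverse is maintained by product-form updates with
  refactorization every 60 pivots (or when a pivot falls below
  $10^{-11}$);
* feasibility/optimality tolerance is $10^{-9}$; phase-1 artificial
  variables above $10^{-7}$ declare infeasibility.

The solver is deterministic, which in turn makes GIMME extraction and
the relaxation program deterministic. Its solutions are cross-checked
in development against an independent interior-point/simplex
implementation on randomized degenerate instances; the test suite
verifies $\max |S v| < 10^{-9}$ and bound feasibility on every optimal
solution it touches.

## 3. The synthetic core network

`build_core_network()` is a first-class, deterministic generator of an
84-reaction core model of human central metabolism: glycolysis, the
pentose phosphate shunt, pyruvate dehydrogenase, the full TCA cycle,
NAD-dependent malic enzyme, glutaminase + NAD-dependent glutamate
dehydrogenase, a lumped electron transport chain, lactate fermentation
with proton symport, a three-cycle octanoate $\beta$-oxidation arm,
twelve amino-acid uptake arms, exchanges for a basal medium, an ATP
hydrolysis demand and a lumped biomass reaction. Every internal
reaction is elementally and charge balanced against real formulas
(verified by `check_balance()`), which is what guarantees the leak
tests pass by construction.

**Energy calibration.** The respiratory chain pumps 10 protons per NADH
and 6 per FADH$_2$; the synthase costs 4 protons per ATP, i.e. textbook
P/O ratios of 2.5 and 1.5. Per glucose this gives
$2_{\text{glycolysis}} + 2_{\text{succinyl-CoA}} + 10 \times 2.5 +
2 \times 1.5 = 32$ ATP aerobically and 2 by lactate fermentation; full
glutamine oxidation through glutaminase, GDH, the TCA cycle and malic
enzyme yields $7$ NADH $+ 2$ FADH$_2$ $+ 2$ substrate-level $= 22.5$.
These are exact LP optima of the model, not approximations, and the
acceptance script recomputes them from scratch.

**Proton bookkeeping.** Pumped protons live in a dedicated
intermembrane compartment `i` touched only by the chain and the
synthase. Medium protons connect to the cytosol by free diffusion.
This separation is what prevents the classic artifact of running the
synthase off medium acidity.

**Growth design.** Biomass drains glucose-6-phosphate, ribose-5-
phosphate, NADPH, glutamine/glutamate, twelve amino acids and 20 ATP.
Glutamine uptake is capped at 0.3 against a 0.3 per-unit requirement,
so the wild-type optimum is exactly 1 and - deliberately - attainable
without respiration (glycolytic ATP suffices at the given glucose cap).
That choice mirrors the glycolytic phenotype of expanding MSCs and is
what allows the extraction step to drop the oxidative subsystems for
the expansion lineage while honoring the 90% growth guarantee.
Acetyl-CoA is consequently *not* a biomass precursor: in a core network
without cytosolic redox shuttles its anaerobic synthesis is
redox-blocked, and including it would covertly force respiration.

**Background arms.** The twelve amino-acid exchange/transport pairs are
lineage-neutral, biomass-coupled "background": they enlarge the
enrichment universe the way the thousands of untouched reactions of a
genome-scale model would. Without them a planted contrast that flips
half of a 60-reaction network leaves too little background for a
five-member subsystem ever to reach significance - a power property of
the statistics, not a bug in them.

**What the fixture does not emulate.** No kinetic or regulatory
constraints, no compartmentalized mitochondrion beyond the proton
pool, no thermodynamic ($\Delta G$) feasibility, and none of the size
or redundancy of a real reconstruction. Passing tests therefore
demonstrate correctness of the algorithms under known ground truth, not
biological completeness of any particular reconstruction.

## 4. Synthetic transcriptomes

`simulate_expression()` draws one lognormal gene effect per lineage
(sd 0.15 on the log scale) around a per-subsystem baseline, then emits
datasets differing by an overall scale jitter (U(0.8, 1.25)), rescaled
so each dataset's maximum sits near 1000 - the magnitude convention of
the array data the pipeline is designed for. Baselines encode a
glycolytic resting program (TCA cycle 70, oxidative phosphorylation 70,
fatty-acid oxidation 30, versus 200-400 elsewhere); lineage multipliers
plant the programs: osteogenic boosts TCA/oxidative phosphorylation
$\times 4$, adipogenic additionally boosts the fatty-acid arm
$\times 12$. The fatty-acid multiplier is set high enough that `and`
rules - which score as the *minimum* over subunits and are therefore
biased low - still clear the extraction threshold; with $\sigma = 0.15$
the planted clusters sit several standard deviations from the
threshold, making the extracted lineage structure stable across seeds.

Normalization (`normalize_and_pool()`) rescales each dataset's maximum
to a common 1000 and pools genes by the mean across datasets carrying
them - a deliberate, simple stand-in for the heterogeneous per-platform
normalizations of real array sets, which are assumed already applied
within each dataset. Probe-to-gene mapping is out of scope.

## 5. GIMME extraction and pruning

`map_expression_to_reactions()` scores each reaction by its GPR with
`and` $\to$ min and `or` $\to$ max; unmeasured genes drop out of `or`
nodes and an `and` node is unknown only if all children are. Reactions
without rules score unknown and are never penalized (missing evidence
is not evidence of absence).

`gimme_extract()` splits fluxes into nonnegative forward/backward parts
and minimizes $\sum_i \max(0, t - s_i)\,(v_i^+ + v_i^-)$ subject to
steady state, bounds, and biomass $\ge f \times$ the parent optimum.
Defaults: threshold $t$ = the 25th percentile of scored reactions
(configurable as an absolute value), $f = 0.9$. A reaction is kept if
it scores at or above threshold, is unknown, is listed as core, or
carries flux above `prune_tolerance` ($10^{-6}$) in the GIMME solution.
Core reactions are treated as maximally expressed; if one ends up
unable to carry flux, the shortest stoichiometric path through the
removed reactions (breadth-first search on the metabolite-reaction
bipartite graph) is re-added to reconnect it. `prune_model()` then
removes every reaction whose flux range at objective fraction 0 is
below tolerance, leaving a fully functional context model; pruning is
idempotent.

## 6. Exometabolomic rates and elastic constraints

Uptake/secretion rates come from an ordinary least-squares slope of
concentration against time (mM/h), pooling time points across
replicates in a single regression, converted by
$q = \text{slope} \cdot V / \bar X$ with the time-averaged exponential
biomass $\bar X = X_0 (2^{T/d}-1)\, d / (T \ln 2)$ (and $\bar X = X_0$
as $d \to \infty$). The time-average is the least-biased single-number
normalization when growth is appreciable over the sampled span; for
typical MSC parameters the residual curvature bias of the linear fit is
well under the measurement noise. Pooling replicates into one
regression (rather than averaging per-replicate slopes) weights points
rather than donors; the alternative is a one-line change and was judged
immaterial at the simulated noise levels. Points flagged as depleted
(concentration truncated at zero) are excluded.

`apply_measured_rates()` constrains each measured exchange to
rate $\pm k \cdot$ SE (default $k = 1$). If the windows are jointly
infeasible with positive growth, an elastic LP minimizes the total L1
slack on the measured bounds; L1 keeps the program linear and the
relaxation sparse-ish, and the per-constraint slack is reported so a
practitioner can see exactly which measurement the model cannot honor.
`apply_medium_constraints()` opens uptake only for medium metabolites
(detected-but-unquantified ones at the default cap) and closes all
other uptakes.

## 7. Flux sampling and differential flux

`sample_flux_space()` restricts biomass to a window (default 50-100% of
its optimum) and runs artificial-centering hit-and-run: warmup points
are the FVA vertices, directions are differences between a stored point
and the running center, and the step is uniform on the feasible
segment. Two numerical safeguards matter in practice: directions are
re-projected onto the movable subspace - the null space of $S$
augmented with indicator rows for variables pinned by equal bounds -
because normalizing a small difference vector otherwise amplifies
rounding error into systematic drift; and the state is re-projected
every 50 steps. Chains are seeded and bit-reproducible. Defaults are
`thinning = 100` with warmup $10 \times$ the polytope dimension;
the tests and the bundled analyses use `thinning` 5-10 at 300-5000
samples, sizes at which the sampled moments match analytic values on
segment and simplex polytopes to within Monte-Carlo error. Hit-and-run
is uniform only asymptotically; no convergence diagnostics beyond fixed
warmup/thinning are attempted.

`compare_reaction_fluxes()` aligns two samples on the union of their
reactions, zero-imputing reactions absent from a model (absence means
the context holds that flux at zero). Per reaction it reports the fold
change of absolute means (floored at $\varepsilon = 10^{-9}$; both
means under the floor = "both-inactive", never significant), a
two-tailed Welch $t$ (variance heterogeneity between models is the
norm), and a Wilcoxon rank-sum p recorded alongside. The significance
gate is fold $\ge 5$ *and* $t$-p $< 10^{-12}$ - intentionally brutal
thresholds appropriate to the enormous $n$ of sampled fluxes, where
trivial differences are otherwise "significant".

`flux_enrichment()` is an upper-tail hypergeometric test per subsystem
with Benjamini-Hochberg adjustment and a 0.05 flag threshold. Its power
scales with subsystem size: with a three-member subsystem and a changed
set of ~20 in a universe of ~80, even a perfect hit cannot clear 0.05
after adjustment - which is why the package's own end-to-end check
gates on the nine-member TCA cycle and the five-member fatty-acid arm.

## 8. Lineage-switch relaxation

`build_merged_model()` forms the union of a target and an initial
context model, keeping the initial bounds and closing target-exclusive
reactions to $[0, 0]$. (Such constructions are sometimes labeled
"intersect models" in the constraint-based modeling literature even
though the reaction set is a union; the function name here says what
it does.)

`relax_to_target()` is a two-stage LP. Stage one finds the minimal L1
distance to the target state over fluxes with per-reaction bound
expansions $r_L, r_U \in [0, \text{cap}]$. Stage two fixes that
distance (within $10^{-6}$) and minimizes
$\alpha \sum (r_L + r_U) + (1-\alpha) K \sum \phi(r_L + r_U)$, where
$\phi$ is a capped-L1 count surrogate handled by iteratively reweighted
L1 (weights $c/(r + c)$, $c = 10^{-3}\,$cap, four rounds) and
$K = 0.1\,$cap converts a counted reaction into flux units. Lower
$\alpha$ therefore presses harder on sparsity; when the primary
$\alpha = 0.99$ yields a list longer than `max_list_length` (100), the
fallback alphas (0.75, then 0.9) are tried and the alpha that produced
the returned list is reported. This two-term program is an
interpretation of an unpublished solver knob: it is validated by
soundness (re-applying the returned bounds makes the target reachable
at the reported distance) and by exact recovery of planted conflicts
against a subset-enumeration oracle, not by output identity to any
particular implementation. The lexicographic order - distance first,
sparsity second - reflects that reaching the target state is the
experiment's point and the shortness of the intervention list its
practicality.

`classify_relaxed()` labels relaxed reactions `transport` (metabolites
cross compartments with zero net change per base species),
`exchange/demand` (boundary), or `internal`, with a direction of change
derived from feasible flux signs: `activate` (previously pinned at
zero), `reverse` (a previously unavailable sign opens), `amplify`.

## 9. Numerical conventions and degenerate inputs

* LP tolerance $10^{-9}$; sampled mass-balance residuals $< 10^{-6}$;
  blocked-reaction and GIMME flux tolerance $10^{-6}$; energy-leak
  threshold $10^{-10}$.
* Flat concentration series regress to rate 0 with SE 0; fewer than two
  distinct time points is an error, as is an all-zero expression
  dataset.
* Zero-variance sample comparisons: equal constant means give p = 1,
  unequal give p = 0; rank-sum failures (all ties) report p = 1.
* Infeasibility is always an explicit status or error, never a silent
  zero - except `atp_yield()`, which returns 0 with a warning for a
  substrate the network genuinely cannot catabolize, because "no yield"
  is that assay's meaningful answer.
* All stochastic components (expression, time courses, sampling) take
  explicit integer seeds and are bit-reproducible; no global RNG state
  is disturbed.

## 10. Known limitations

* The simplex is dense and single-threaded: comfortable at core-network
  scale (tens of ms per solve, seconds for FVA), but a genome-scale
  reconstruction with thousands of reactions would need a sparse
  industrial solver behind the same interface.
* Flux sampling inherits hit-and-run's slow mixing in elongated
  polytopes; fixed thinning is a pragmatic, not a verified, convergence
  policy.
* The anaerobic glutamine yield of the fixture is 0, not the small
  positive value a full reconstruction with fumarate-reductase-like
  sinks would give; that benchmark is documented as outside the
  fixture's contract.
* SBML support covers Level 3 with the flux-bound conventions used by
  current model repositories (species formula/charge, parameter-backed
  bounds, gene-product associations, subsystems in notes); exotic
  SBML constructs (kinetic laws, rules, events) are ignored.
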