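---
title: "Scoring metabolic interactions in multi-organism ecosystems"
author: "ecoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring metabolic interactions in multi-organism ecosystems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoscore)
```

## The model

A genome-scale metabolic model (GEM) describes one organism as a
stoichiometric matrix $S$ over metabolites and reactions, flux bounds
$l \le v \le u$ (mmol·gDW⁻¹·h⁻¹), and a linear objective $c^\top v$ —
biomass production for a bacterium, or a maintenance pseudo-reaction
(membrane, protein and energy turnover without replication) for a
differentiated host cell. Flux balance analysis (FBA) predicts a metabolic
phenotype as the solution of

$$\max_v \; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u .$$

To model a community, `build_ecosystem()` diagonally assembles the member
matrices into one ecosystem matrix $S_\sigma$ and adds a shared *pool*
compartment. Each member's exchange reactions (detected by
`detect_exchanges()`; negative flux = uptake, the BiGG convention) become
*transport reactions* (TR) between that organism and the pool, and every
metabolite exchanged by at least one member receives a single *pool
exchange reaction* (ER) connecting the pool to the environment. TR are
unconstrained so that metabolites transit freely; the growth medium (the
"diet", `apply_diet()`) acts only on the ER. Pool metabolites are matched
by identifier, so reconciling namespaces across model collections
(`apply_namespace()`) is a precondition for sharing, not an afterthought.
Host models carry a second, blood-side external compartment whose
reactions are deliberately *not* treated as exchanges: the blood is not
part of the shared lumen environment, and blood bounds are applied
per-reaction from the diet's blood table.

A community has one objective per member. Rather than maximizing a fixed
weighted combination (which rewards the best-yield organism) or calibrating
weights to observed abundances, the package treats the ecosystem as a
multi-objective linear program

$$\max_{v \in \mathbb{R}^{\bar n}} \; (f_1, \dots, f_k)
  \quad \text{s.t.}\quad S_\sigma v = 0,\; l \le v \le u,$$

whose solution set is a Pareto front: the polyhedral surface of phenotypes
where no organism can grow faster without another growing slower. The
front's *shape* is the object of interest — it encodes competition,
independence, and cross-feeding simultaneously.

## Front enumeration

`compute_pareto_front()` returns the front's extreme points. For $k = 2$
the package uses non-inferior set estimation (NISE): solve the two
lexicographic endpoint problems, then recursively probe each chord with its
normal vector as weights until no probe improves beyond tolerance. For
linear problems this terminates with the exact vertex set; the test suite
verifies it against an independent ε-constraint sweep. For $k \ge 3$ a
facet-driven generalization is used: the convex hull of the current point
set (plus a dominated anchor) is computed, every hull facet with a
nonnegative outward normal is probed as a weight vector, and improving
points are added until the hull is supported everywhere. When the front is
degenerate in objective space (lower-dimensional, e.g. a single fully
coupled vertex) the hull does not exist; the package then falls back to a
deterministic weight-grid scan, which recovers every vertex supported by a
scanned weight and is labeled approximate. The reference community
conditions used in the tests have single-vertex coupled fronts, for which
both routes are exact.

All linear programs are solved by a dense bounded-variable two-phase
primal simplex implemented in the package (`lp_solve()`). Every reaction
carries finite bounds — absent bounds default to ±1000 mmol·gDW⁻¹·h⁻¹, the
community convention — so LPs are always bounded and "unconstrained" TR
are honored up to that numerical cap (configurable via `default_bound`).
The solver is deterministic (Dantzig pricing, smallest-index tie-breaks,
Bland's rule under prolonged degeneracy), uses feasibility/optimality
tolerances of 1e-9, and is cross-checked in the tests against exhaustive
vertex enumeration and `boot::simplex`. Degenerate alternate optima at a
vertex are accepted as-is: the front in *objective space* is unique
regardless of which optimal basis realizes it, and downstream scoring
consumes only objective space.

## The interaction score

Axes are normalized by each member's *alone* optimum under the same diet
(`normalize_front()`): the member is rebuilt as a one-member ecosystem with
its own pool, the diet is re-applied, and a standalone FBA is solved. A
normalized coordinate of 1 means "exactly as well as alone"; above 1 means
the partners improve it. The "original growth points" — the $k$ unit
vectors — are appended to the front. Normalization fails loudly when a
member cannot grow alone (the score is undefined there), which is why the
one-way cross-feeding generator gives the beneficiary a small private
substrate rather than making the byproduct its sole food.

For $k = 2$ the score is

$$S = \mathrm{AUC}_P - \mathrm{AUC}_{NI},$$

the trapezoidal area under the augmented normalized front minus the area
under the *non-interaction front* — the front of a perfectly neutral pair,
the unit square through $(0,1), (1,1), (1,0)$, whose area is 1. Neutral
fixtures give $S = 0$, pure competition over one substrate gives the
triangle area $0.5 - 1 = -0.5$, and cross-feeding gives $S > 0$. Ordered
along increasing first coordinate, an augmented front can violate
monotonicity only at its final point (when the first member's ecosystem
optimum exceeds 1, the appended $(1,0)$ steps backwards); `auc_2d()` then
subtracts the final segment's area from the monotone prefix's area, and
treats an interior break as an input error.

For $k \ge 3$ the same construction uses convex-hull hypervolumes
(`hypervolume()`): the hull of the augmented points plus the origin, minus
the non-interaction hypervolume, defined here as the hull of the origin,
the $k$ unit vectors and the all-ones point. That choice is the same
augmentation rule applied to a neutral ecosystem's single-point front at
all-ones; it reproduces $\mathrm{AUC}_{NI} = 1$ at $k = 2$ (where the
construction is the unit square) and is stated prominently because it
controls comparability: scores are comparable within a dimension only,
never across dimensions. Hull volumes are computed exactly by brute-force
facet enumeration over point subsets with recursive facet-area evaluation —
adequate and exact for the small point sets of objective space (tens of
points, $k \le 6$), degenerate hulls returning 0.

## Interaction types

For two members the front shape is summarized by four conditions: the sign
of $S$ (values within tolerance of zero count as "+", so exact neutrality
is Neutralism, not Unclassified); E+ — some front point puts the first
member (the host, by convention the first member of the ecosystem) above
its alone optimum; B+ — the same for the second member; and E+B+ — both
hold *and* one single front point attains both members' front maxima
simultaneously. The additional "both hold" guard is a deliberate design
choice: without it, any single-vertex commensal front would trigger the
joint-attainment test and fall outside the type table, although its shape
is exactly the one the table calls FavorsBacteria. The table:

| Sign | E+ | B+ | E+B+ | Type |
|------|----|----|------|------|
| + | F | F | F | Neutralism |
| − | F | F | F | Competition |
| + | T | F | F | FavorsHost |
| + | F | T | F | FavorsBacteria |
| + | T | T | F | LimitedMutualism |
| + | T | T | T | Mutualism |

Any other combination is `Unclassified`. Types are defined for $k = 2$
only; higher dimensions use the score and the removal decomposition.

`removal_analysis()` rebuilds and re-scores every $(k-1)$-member
sub-ecosystem under the same diet. Removing a cross-feeder collapses the
interaction it sustains (low residual score), removing a bystander leaves
it intact — a ranking of each member's contribution, reported with the
explicit caveat that $(k-1)$-dimensional scores are not comparable to the
$k$-dimensional one.

## Sampling the front for mechanisms

`sample_front()` explains *why* an interaction is favorable. It places `n`
points uniformly by arc length along the bi-objective front polyline
(endpoints included) and solves one FBA per point with both member
objectives pinned by equality rows. Pinning two objectives leaves fluxes
under-determined; since the choice of representative is not dictated by the
front itself, the default secondary criterion minimizes total absolute flux
(a parsimonious, deterministic representative), with `secondary = "none"`
available to mimic arbitrary-basis behavior. The driver tests use a
fixture whose exchange fluxes are fully determined at every front point,
so the reported correlations cannot depend on this choice.

Each TR and host-blood flux is then rank-correlated (Spearman, average
ranks on ties) with the *ecosystem biomass* — the sum of the pinned
objective values. Fluxes with $|\rho| \ge 0.95$ are reported as drivers
(secreted for positive, uptaken for negative correlation, under the
negative-flux-is-uptake convention); `find_exchanged()` pairs one member's
secretion with another's uptake of the same pool metabolite at
$\rho > 0.5$, naming producer and consumer. Both thresholds are the
field's reference values and are exposed as arguments. Finally
`find_obligatory()` pins the objectives at a chosen front point and runs
flux variability analysis: reactions whose flux interval excludes zero
(at 1e-6) cannot be inactive in any realization of that community
phenotype.

## The synthetic generator as study conditions

`generate_pair()`, `generate_host_like()` and `generate_community()`
produce models of at most 8 reactions with integer-friendly stoichiometry,
so every expected value in the tests is exact arithmetic. Defaults are the
package's reference conditions: yields 1, substrate supply 10 (5 and 7 for
the neutral pair), byproduct stoichiometry 0.5, obligate coupling 0.1,
flux cap 1000.

* *competition*: both members consume one pooled substrate; the front is
  the $(0,1)$–$(1,0)$ segment after normalization and $S = -0.5$
  identically.
* *neutralism*: disjoint substrates; single-vertex front, $S = 0$.
* *crossfeed_oneway*: member A secretes a byproduct both obligately
  (stoichiometrically coupled into biomass, so secretion is strictly
  positive whenever A grows) and facultatively (a conversion reaction that
  competes with A's own growth). The facultative route creates a genuine
  A-versus-B trade-off, giving the front two vertices and giving the
  sampling analyses real variance; the beneficiary holds a small private
  substrate so its alone-growth is positive and the score is defined.
  Expected: $S > 0$, FavorsBacteria.
* *crossfeed_mutual*: reciprocal obligate byproducts with each member
  substrate-limited alone; the coupled optimum $(2, 2)$ in normalized
  coordinates under the defaults. Expected: $S > 0$, Mutualism.
* *communities* place one mutual pair among neutral bystanders and ship a
  machine-readable matrix of expected pairwise signs.

What the toys emulate is the *interaction topology* — shared resources,
directed byproduct flows, obligate coupling — under exactly known
arithmetic. What they do not emulate is everything that makes real GEMs
hard: thousands of reactions, redundant pathways, gap-filled reactions of
uncertain provenance, namespace noise between reconstructions, and diets
whose unlisted nutrients must be guessed. A green test suite certifies the
machinery (assembly, LP solving, enumeration, geometry, statistics), not
the biology of any particular reconstruction.

## Numerical choices and degenerate inputs

* LP feasibility/optimality: 1e-9; front vertex deduplication:
  $\|p-q\|_\infty < 10^{-6}(1 + \|p\|_\infty)$; type flags: relative 1e-6;
  obligatory-call activity: 1e-6.
* Diet policy: ER not listed in a diet default to *unconstrained* —
  blocking every unlisted nutrient abolishes growth outright, so unknown
  concentrations are modeled as freely available; `"blocked"` is available
  to reproduce that collapse deliberately. Diet ids matching nothing are
  reported and skipped, never fatal.
* Infeasible sampling pins are retried once after a 1e-9 inward
  perturbation, then dropped with a warning.
* Constant flux columns (undefined correlation) are skipped, which also
  makes the neutral fixture's driver report empty rather than spurious.
* One-member ecosystems reproduce standalone optima; mass balance
  $|S_\sigma v| \le 10^{-6}$ is asserted on returned solutions.

Problem sizes used in the shipped tests and acceptance script: pair
fixtures of 7–18 ecosystem reactions, communities of up to 5 members
(30 reactions), fronts sampled at up to 1000 points, 100 randomized
parameterizations for the sign-recovery property, ε-constraint grids of
100 points against 20 randomized fronts, and a $10^6$-point Monte-Carlo
membership check of the hypervolume routine. These sizes make the whole
suite run in well under a minute while exercising every code path; all of
them are choices of the package, scalable upward through the same API.

## Worked example

```{r example}
pair <- generate_pair(toy_spec("crossfeed_mutual"))
eco <- apply_diet(build_ecosystem(pair$models), pair$diet)
front <- compute_pareto_front(eco)
front$points
nf <- normalize_front(front, eco)
interaction_score(nf)
```

## Known limitations

Interaction types are undefined for more than two members, mirroring the
method's own scope. The $k$-dimensional non-interaction hull is one
defensible convention among several; absolute $k \ge 3$ score values
depend on it even though rankings (as in the removal analysis) are robust.
The grid fallback for degenerate $k \ge 3$ fronts can miss vertices that
no scanned weight supports. The SBML layer covers Level 3 core plus fbc
bounds/objectives — the subset community GEM collections actually use —
not the full standard (no groups, gene-product associations, or notes).
Brute-force hull enumeration scales as $\binom{n}{k}$ and is intended for
objective-space point sets, not for general computational geometry. And,
as always in constraint-based modeling, predictions inherit the quality of
the input reconstructions and diet bounds.
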