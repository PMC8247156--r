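---
title: "Enzyme-constrained metabolic models: method, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme-constrained metabolic models: method, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgem)
```

## The model

A genome-scale metabolic model is a stoichiometric matrix $S$ (metabolites ×
reactions) with flux bounds $l \le v \le u$ and a biomass objective. Flux
balance analysis maximizes the objective over the steady-state polytope
$S v = 0$. The enzyme-constrained extension adds, for every reaction $j$ with
kinetic evidence, the capacity law

$$v_j \;\le\; k_{cat}^{j}\,[E_j],$$

and encodes it *stoichiometrically* rather than as extra inequality rows:
the enzyme becomes a pseudo-metabolite consumed with coefficient
$1/k_{cat}^{j}$, supplied by a usage (enzyme-exchange) reaction whose upper
bound is the measured abundance $[E_j]$ (mmol/gDW). Steady state of the
enzyme species then enforces $\sum_j v_j / k_{cat}^{j} \le [E_j]$, which for
a single reaction is exactly the capacity law and for a multifunctional
enzyme couples all reactions it catalyzes through one shared budget. The
construction keeps the problem a plain LP over $S v = 0$, which is why
`expand_ec()` can promise *neutrality*: with every usage bound lifted to
$+\infty$ the optimum of the base model is recovered exactly (this is a
tested invariant, tolerance $10^{-8}$).

Isozymes (OR in the gene–protein–reaction rule) would otherwise share one
row; instead the reaction is split through an *arm* pseudo-metabolite:
substrates feed the arm, and one branch per isozyme converts arm to products
while paying its own $1/k_{cat}$ enzyme cost. Total capacity is therefore the
*sum* of branch capacities. Complexes (AND) charge every subunit in the same
branch; lacking subunit stoichiometries we charge each subunit coefficient
$1/k_{cat}$ of the whole reaction, with the reaction's $k_{cat}$ taken as the
minimum over subunit records — the conservative reading when records
disagree. A reversible enzymatic reaction is first split into `_fwd`/`_rev`
columns that may carry different $k_{cat}$ values but always share one usage
bound, since forward and backward flux draw on the same protein.

Two deliberate non-imputations: a reaction whose GPR cannot be fully matched
to kinetic records is left *unconstrained* (no default $k_{cat}$), and a
protein without abundance evidence gets an infinite usage bound. Both follow
the principle that a missing measurement should not invent a constraint.
Consequently an arm split is only made when at least two branches survive
kinetic matching; with a single matched branch the free branch would void the
constraint anyway, so the reaction is left untouched and the case is recorded
in the build report.

## Evidence selection

*kcat*: among direct measurements for a (protein, reaction) pair the maximum
is used; only when none exists is specific activity converted,
$k_{cat}\,[\mathrm{h}^{-1}] = SA \cdot MW \cdot 60 \cdot 10^{3} \cdot
10^{-6}$ (net factor $0.06\,SA\,MW$), again taking the maximum.
Reaction-specific records beat wildcard records, which is how multifunctional
enzymes get per-reaction turnover numbers.

*Abundance*: entries carry the taxon and rank they come from. Matching is
greedy by rank — species first, then genus, family, order, class — returning
the maximum at the **first** rank holding any entry. The alternative reading
(maximum across all ranks) was rejected because the rank order would then be
meaningless; the greedy rule is what makes "closer taxon wins" true. When
inputs are ppm (PAXdb-style), conversion to mmol/gDW uses
$ppm \cdot 10^{-6} \cdot P_{tot}/MW \cdot 10^{3}$ with total protein content
$P_{tot}$ defaulting to 0.5 g/gDW — the standard assumption for fungal
biomass; it is a parameter of `read_abundance_table()`, not a constant.

## kapp correction

Database turnover numbers are frequently orders of magnitude too small for a
working model; with them in place the LP may admit essentially no growth.
The repair sweeps a condition grid (by default 20×20 combinations of
substrate and oxygen uptake over (0.25, 5] mmol/gDW/h — 400 conditions; the
spacing is configurable because only the count and range matter), records
the apparent catalytic rate $k_{app,j}(C) = v_j(C)/E_j$ with the abundance
held fixed, and replaces $k_{cat} := \max(k_{cat}^{db}, k_{app,max})$.

Two design points deserve note. First, the fluxes feeding $k_{app}$ come by
default from the *relaxed* model (usage bounds lifted, $1/k_{cat}$
coefficients still present): estimates far above the database value are only
possible if the fluxes are not themselves capped by it. A `constrained` mode
is provided, under which $k_{app} \le k_{cat}$ holds by construction and a
saturating condition recovers the true $k_{cat}$ exactly — that is the
parameter-recovery test. Second, FBA flux vectors are not unique, so the
sweep uses parsimonious FBA (total absolute flux minimized at the fixed
optimum) to make the estimates reproducible; plain FBA would make them
solver-path-dependent. The default policy `replace_if_larger` makes the
correction monotone (an LP relaxation can only raise the optimum) and
idempotent (a second pass changes nothing); `always_replace` is available
for the unconditional reading.

The relaxed sweep can legitimately raise a *correct* $k_{cat}$ too: if the
grid admits more flux through a reaction than its true capacity, the new
coefficient reflects the grid, not the enzyme. Restoration of the analytic
optimum after repair is therefore exact only when the surviving constraints
(uptake bound inside the grid range, generous database kcats elsewhere) are
the binding ones — the over-constrained fixture is built that way on
purpose, and the limitation is inherent to the method, not the
implementation.

## Simulation suite

FVA constrains the objective to a fraction of its optimum — the "99.9%
confidence level" is read as $\mu \ge 0.999\,\mu^*$, a fraction-of-optimum,
not a statistical interval — and solves a min and max LP per reaction; the
flux variability is $FV_j = \max - \min$. Comparing base and
enzyme-constrained variability requires pairing reactions: expanded
reactions map to their pre-expansion parent, an arm reaction carries the
comparable total flux of its split reaction, and usage reactions are
excluded. Reactions with $FV^{base}_j = 0$ get reduction 0 (the defining
ratio is undefined there); both the mean per-reaction reduction and the
total-FV ratio are reported because the two summaries answer the same
question differently and neither dominates.

Knockouts evaluate each reaction's GPR with the gene deleted; blocked
reactions get bounds $[0,0]$ and, in the enzyme-constrained model, a protein
left without a supporting gene has its usage bound zeroed rather than its
column deleted — the matrix keeps its shape and isozyme branches reroute,
which is what produces partial (grRatio between 0 and 1) rather than
all-or-nothing knockout phenotypes. Classification uses
$\varepsilon = 10^{-6}$: lethal below, neutral within $\varepsilon$ of 1.

Differential usage runs max-growth parsimonious FBA per carbon source with
the oxygen limit lifted, reads the usage-reaction fluxes, and reports fold
changes against the reference with the denominator floored at $10^{-8}$;
usages induced from a zero baseline are flagged as such instead of being
divided by zero. Carbon-source uptakes are chosen carbon-mole-matched (1.0
mmol/gDW/h of a 6-carbon source against 1.2 of a 5-carbon source, both 6
C-mmol/gDW/h) so that usage changes reflect rerouting, not supply.

## Network indices

The metabolite graph joins two metabolites iff they co-occur in a reaction;
enzyme and arm pseudo-metabolites are nodes like any other, which is what
makes enzyme-connectivity rankings possible. Currency metabolites (ATP,
NAD(P)H, H2O, ... — a configurable list, matched by name across
compartments, since compartmentalized copies are distinct nodes) may be
dropped before edge construction. Degree-based indices follow their defining
formulas: density $\bar k/(n-1)$, heterogeneity
$\sqrt{\mathrm{var}(k)}/\bar k$ with population variance, centralization
$\max(k)/n$ — the latter kept verbatim even though it differs from the
Freeman index, because comparability with the published convention wins.
Average local clustering counts degree-$\le 1$ nodes as 0. Path metrics
(diameter, radius, characteristic path length) are computed on the largest
connected component; a disconnected graph would otherwise have infinite
diameter, and the largest-component convention is what network tools
typically report. All indices are checked against an independent BFS-based
oracle on exhaustively enumerated 4-node graphs and sampled graphs up to 12
nodes.

## The toy generator, and what passing means

`make_toy()` builds substrate → linear chain → biomass models whose
max-growth optimum is the closed form $\min(\text{uptake},
\min_i \text{cap}_i)$ with step capacities $k_{cat}E$ (single),
$\sum k_{cat,i}E_i$ (isozymes), $k_{cat}\min_s E_s$ (complex) and
$E/(1/k_1 + 1/k_2)$ (one enzyme shared by two steps). Topology is
deterministic from the counts; only kinetic/abundance draws and
reversibility choices consume the seed, so analytic answers stay derivable.
Units are fixed (mmol/gDW, 1/h, mmol/gDW/h) so the fixtures double as
unit-consistency checks. Default draw ranges — kcat 50–500 1/h, abundance
0.001–0.05 mmol/gDW, uptake 10 mmol/gDW/h — put capacities in the 0.05–25
range, i.e. both enzyme-limited and supply-limited regimes occur across
seeds, which is the interesting regime for the suite.

What the toys deliberately do **not** emulate: branched topologies with
alternative routes (beyond isozyme branches and the two-pathway carbon
switch), cofactor coupling, compartment transport chains, biomass equations
with many precursors, and genome-scale dimensions. Passing the suite
therefore certifies the algebra and the algorithms — expansion correctness,
LP laws, estimator behaviour — on networks where the truth is computable by
hand; it does not certify biological predictions on a real reconstruction,
where evidence quality dominates.

## Numerical choices

The LP core is a dense bounded-variable two-phase primal simplex
(`solve_lp()`) with Bland's smallest-index rule throughout, which guarantees
termination under degeneracy at some cost in pivots — an easy trade at these
problem sizes (toys are tens of columns; the design target is a few thousand).
Tolerances: $10^{-9}$ on reduced costs and basic feasibility, $10^{-7}$ on
phase-1 infeasibility; every returned flux vector satisfies
$\|S v\|_\infty \le 10^{-6}$ (tested). Infinite bounds are handled by
substitution, free variables by column splitting. Degenerate inputs are
answered explicitly: infeasible and unbounded statuses are first-class
results, an unbounded FVA direction yields an infinite $FV$ that is excluded
from averages and counted, infeasible robustness grid points carry growth 0
with a flag, and ties in degree rankings break lexicographically so reports
are stable under relabeling.

Model identity across formats: JSON is the canonical archive (doubles
serialized at 17 significant digits round-trip exactly, including kind tags,
parent maps and infinite bounds); SBML export sanitizes ids deterministically
(non-alphanumerics to `_`, digit-initial ids prefixed) and keeps the original
ids and kind tags in per-element annotations, so a round trip restores them.

## Known limitations

* Subunit stoichiometries in complexes are not modeled (all coefficients
  $1/k_{cat}$); GECKO-style per-subunit weighting would need data the
  evidence tables do not carry.
* The kapp sweep inherits the method's identifiability limit described
  above: it bounds $k_{cat}$ from below by observed-at-some-condition flux
  per enzyme, nothing more.
* The protein pool is a single global budget; compartment-specific pools are
  out of scope.
* The simplex is dense; truly genome-scale models (tens of thousands of
  columns) would want a sparse revised implementation or an external solver
  behind the same `solve_lp()` interface.
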