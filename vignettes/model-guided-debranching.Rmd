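---
title: "Model-guided debranching of metabolic flux: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided debranching of metabolic flux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debranch)
```

## The problem

Engineering *E. coli* to make an irregular monoterpenoid (here: the
chrysanthemol → chrysanthemal → chrysanthemic acid tail of pyrethrins) runs
into a classic flux-partitioning problem. The C5 prenyl precursor DMAPP sits
at a metabolic crossroads: the native prenyltransferase (an ispA-type enzyme
catalyzing the GPP- and FPP-forming condensations) is both essential for
growth and the dominant drain on the pool, while phosphatase shunts
(DMAP, geraniol, farnesol) siphon off more. "Debranching" — partially
silencing competing consumers rather than deleting them — redirects flux to
the product without killing the cell. This package implements the
constraint-based modeling workflow that identifies the dominant branch,
quantifies its capacity, and simulates graded knockdown and downstream
overexpression before any strain is built.

## The constraint-based core

All simulations are linear programs over the steady-state flux polytope

$$\max\; c^\top v \quad \text{s.t.}\quad S v = 0,\; lb \le v \le ub,$$

with $S$ the stoichiometric matrix (one row per metabolite, one column per
reaction) and $v$ in mmol gDW⁻¹ hr⁻¹. The solver is a bounded-variable
primal simplex written for this package: Bland's smallest-index rule makes
it deterministic and immune to cycling, two phases handle feasibility, and
free variables are supported. Networks in this workflow are small (tens of
reactions), so the dense O(m³) refactorization per iteration is irrelevant;
correctness is what matters, and the test-suite checks every optimum against
exhaustive vertex enumeration on randomized instances, against
`pracma::linprog` on inequality-form programs, and against COBRApy/GLPK on
the bundled network.

**Baseline flux** (`baseline_flux()`) is the parsimonious solution: the
objective is fixed at its optimum and total absolute flux is minimized
(L1 splitting with one auxiliary variable per reaction). Raw FBA optima are
degenerate; recording a *single* baseline value per reaction — which the
knockdown procedure needs — requires a uniqueness rule, and minimal total
flux is the standard one.

**FVA** (`fva()`) minimizes and maximizes each reaction subject to the
objective staying at a stated fraction of its optimum; `fraction = 0` drops
the objective row and describes the pure feasibility polytope.

**Sampling** (`sample_fluxes()`) runs coordinate hit-and-run in an
orthonormal null-space parameterization of the equality constraints, so
every point satisfies mass balance by construction. Warmup points are the
FVA extreme solutions, whose average is the start point; default thinning is
100 steps per kept sample and the chain re-projects onto the affine subspace
every 100 kept samples to cancel numerical drift. Everything is driven by a
single integer seed and restores the caller's RNG state.

**Multi-objective solves** (`optimize_multi()`): the workflow's intervention
simulations "simultaneously maximize" growth and product secretion, which a
single LP cannot express. Two standard readings are implemented and the
choice is recorded in every report: *lexicographic* (default) maximizes
biomass, constrains it to ≥ 99.9% of that optimum (`slack = 0.999`), then
maximizes the product — the "stay viable, then produce" reading; *weighted*
maximizes $\sum_i w_i\, v_i / \mathrm{opt}_i$ with per-term normalization by
the standalone optima. Neither reading is asserted as canonical; on the bundled network both
produce the same qualitative sweeps.

## Expression-scaled capacity bounds

Enzyme capacity enters as upper bounds derived from kinetics and transcript
abundance:

$$V_{max} = k_{cat} \cdot 3600 \cdot E_{total}, \qquad
  E_{total} = \theta \cdot \mathrm{TPM}.$$

Units: $k_{cat}$ in s⁻¹ (the factor 3600 converts to hr⁻¹ exactly once),
TPM dimensionless, and $\theta$ in mmol gDW⁻¹ per TPM unit so that
$V_{max}$ lands in mmol gDW⁻¹ hr⁻¹. $\theta$ is a free scaling factor —
the linearity of active enzyme in transcript abundance is an assumption,
not a measurement — and defaults to $10^{-5}$, which places the capacities
of well-expressed enzymes in the usual single-digit mmol gDW⁻¹ hr⁻¹ range.
`calibrate_theta()` fits the single global $\theta$ that makes one named
reference reaction's $V_{max}$ equal a trusted flux, exploiting the exact
degree-1 homogeneity of the formula.

## Branch-point screening

Two complementary rankings of the competing consumers of a substrate:

* **Capacity**: $V_{max}$ per consumer reaction, aggregated per gene for
  multi-reaction enzymes (the ispA-type gene catalyzes both condensation
  steps). Rank 1 is the largest; ties break lexicographically by reaction
  id so reports are reproducible.
* **Kinetic share** at substrate concentration $[s]$ (mM):

$$\mathrm{PRate}_i = \frac{k_{cat,i}/(K_{m,i}+[s])}
  {\sum_j k_{cat,j}/(K_{m,j}+[s])},$$

evaluated on a logarithmic grid (default $10^{-3}$–$10^{2}$ mM, 6 points —
the intracellular concentration is unknown, so the share is reported across
orders of magnitude; the grid is recorded in the output). The shares sum to
one by construction, converge to $k_{cat}/K_m$-proportional shares as
$[s]\to 0$ and to $k_{cat}$-proportional shares as $[s]\to\infty$; both
limits are verified numerically in the tests.

## The production-strain constraint preset

`cs5_preset()` reproduces the five constraints the engineered production
strain is simulated under: glucose uptake capacity 20 mmol gDW⁻¹ hr⁻¹
(lower exchange bound −20), biomass flux fixed at 1.706, product secretion
floor 0.0023, a mevalonate:MEP route flux ratio of 6461:1 pinned as
$b\,v_A - a\,v_B = 0$ on the terminal route reactions, and a grouped DMAPP
consumption cap with correction factor $\Delta = 0.4$:

$$\sum_{i \in \text{consumers}} F_{out,i} \;\le\; \Delta \sum_{j \in \text{producers}} F_{in,j}.$$

Two points here were genuinely open and are worth recording:

* **The cap's right-hand side must be a reference value, not the concurrent
  producer flux.** At steady state, total consumption of any metabolite
  *equals* its total concurrent production, so a fractional cap with
  complete consumer/producer sets would force the pool to zero; and even
  with the producer side taken as the upstream route reactions, the route's
  output is itself consumed by the growth-essential branch, so the cap would
  shrink as that branch is silenced — the opposite of the debranching
  effect. The preset therefore freezes the right-hand side at the
  producers' output in a parsimonious *reference* solve (the uninhibited
  state under the other preset constraints), matching the reading
  "consumption must not exceed the precursor's initial production rate".
  The variable-flux form remains available (`group_cap()` and
  `cap_rhs = "flux"`), and with $\Delta = 1$ and complete sets it is
  verifiably redundant, as steady state implies.
* **The biomass value 1.706 is applied verbatim** as a flux on the model's
  biomass reaction, in the flux unit the rest of the model uses, although a
  growth rate would conventionally carry hr⁻¹. Nothing in the workflow
  depends on the unit label.

Consumption and production are measured as the metabolite-directed positive
part of each reaction's flux (coefficient-weighted). Irreversible
participants contribute exactly; a reversible consumer gets an auxiliary
overestimating variable that the binding cap drives to the exact positive
part, and a reversible producer a split-variable relaxation — both noted in
the function documentation.

## Intervention simulations

**Graded knockdown** (`simulate_knockdown()`): a parsimonious baseline
fixes per-target reference fluxes; for each inhibition factor
$k \in \{1, 2, 4, \dots, 256\}$ the targets' bounds are set to baseline/$k$
(both directions for reversible targets — silencing reduces enzyme amount,
hence capacity in both directions), and the multi-objective program is
re-solved. Fold-changes are reported relative to the factor-1 row, which by
construction makes the uninhibited fold-change exactly 1. During sweeps the
preset's biomass equality is dropped (`fix_biomass = FALSE`) and biomass is
maximized lexicographically instead: a fixed growth rate would contradict
the tightening bounds at high inhibition and make "maximizing biomass"
vacuous. Full knockout (bounds 0) of the growth-essential pair abolishes
growth — the toy network plants this essentiality via a biomass quota on
the FPP-analogue. Rows that become infeasible are flagged and the sweep
continues. Because "total product flux" is ambiguous between the secretion
flux and a pathway flux-sum, the simulator extracts the secretion exchange
by default and can additionally record the metabolite flux-sum
(`flux_sum_of`), clearly labeled.

**Overexpression sweep** (`sweep_overexpression()`): the two dehydrogenase
steps get base upper bounds $f_1, f_2$ from their expression-scaled
$V_{max}$ (their ratio is the reported
$RV_{max} = k_{cat,1}\mathrm{EXP}_1 / k_{cat,2}\mathrm{EXP}_2$); the sweep
then scales each bound by $n \in \{1, 2, 4, 8, 16, 32\}$ (powers of two,
matching the knockdown convention) and records the product flux per cell,
with the ratio constraint released during the sweep. Since relaxing an
upper bound can never lower an LP maximum, the surface is monotone
non-decreasing in each axis — asserted cell-by-cell in the tests. On the
bundled network the aldehyde step is limiting: scaling the alcohol step
alone leaves the product flat, scaling the aldehyde step raises it strictly
until the upstream precursor cap binds.

## Comparative analytics

* **FVA Jaccard** (`fva_jaccard()`): per shared reaction,
  interval-length-measure Jaccard of the two FVA intervals, sorted
  most-changed first. Degenerate conventions are fixed so outputs are
  reproducible: two identical single points give 1; a single point against
  anything else has measure-zero intersection, hence 0.
* **Sampling volcano** (`sampling_volcano()`): per reaction,
  $\log_2\mathrm{FC} = \log_2\!\big((|\bar v_B|+\varepsilon)/(|\bar v_A|+\varepsilon)\big)$
  with $\varepsilon = 10^{-9}$ guarding zeros, and a two-sided rank-based
  (Mann–Whitney) p-value — the sampling distributions are non-normal, and
  the test choice is recorded in the output metadata. Reactions whose mean
  flux changes sign are flagged `sign_flip` and excluded from the gate
  (a ratio of signed means is meaningless). Default thresholds are
  $p < 10^{-8}$ and $|\log_2\mathrm{FC}| > 1$. These p-values are
  descriptive: they scale with the sample count, which is recorded in the
  report header. Two independent ensembles of the *same* model pass the
  default gate essentially never — the null calibration is part of the
  test-suite.
* **Flux-sum** (`flux_sum()`):
  $\Phi_m = \sum_j \max(S_{mj} v_j, 0)$, per sample for ensembles; at
  steady state production and consumption flux-sums agree, which is checked
  per sampled point.

## The synthetic network

`make_toy_model()` builds a 27-reaction, 20-metabolite network emulating the
engineered strain: glucose uptake, lumped glycolysis, parallel MEP and MVA
routes into the C5 pool, an isomerase, the three competing DMAPP consumers
(prenyltransferase condensations, phosphatase shunt, chrysanthemol route),
the two-step dehydrogenase tail, shunt products (geraniol, farnesol, DMAP)
with exchanges, and a biomass pseudo-reaction consuming acetyl-CoA plus a
0.1 quota of the FPP-analogue. Ground truth plants the dominant consumer at
8× the competitors' $k_{cat}\cdot$TPM capacity, with noise generators
(log-normal, multiplicative, seeded) for kinetics and expression. An
"sRNA-silenced" condition multiplies the ispA-analogue's TPM by 0.1223,
emulating an ~88% knockdown.

What the toy deliberately does *not* emulate — and hence what passing tests
do not show about real data: cofactor balancing (no ATP/NADPH, so yields are
carbon-limited only; this keeps the mass-balance check trivially auditable
and the polytope small enough for the vertex-enumeration oracle), elemental
formulas beyond carbon, transcriptional regulation, and any mapping from
flux to titers in mg L⁻¹ (no genome-scale model predicts fermentation
titers without additional kinetics). The chassis/extension split
(`core` + mevalonate + chrysanthemate tables) exists so the extension
machinery is exercised on exactly the structure it was built for.

Problem sizes used throughout the test-suite and the acceptance script —
50 randomized oracle instances, 200 noisy recovery seeds, 500-sample
ensembles at thinning 100 — were chosen as the smallest sizes at which the
checked properties are stable across seeds.

## Numerical choices

* LP feasibility tolerance $10^{-9}$; reported-value comparisons $10^{-6}$;
  mass-balance residuals $10^{-6}$.
* Bland's rule everywhere: deterministic pivoting, identical results across
  repeated runs; the ratio test collects all blocking candidates and breaks
  ties by smallest variable index.
* Bounds are kept finite in the bundled models (±1000, the community
  convention); genuinely unbounded directions are detected and reported as
  such rather than truncated.
* Ties in $V_{max}$ rankings break lexicographically; grid values and seeds
  are echoed into every report so a run can be reproduced bit-identically.

## Known limitations

* The simplex is dense and refactorizes per iteration — appropriate for
  networks up to a few hundred reactions, not for genome-scale models with
  thousands; swapping in a sparse LP backend behind `solve_lp()` would be
  the natural extension.
* The cap relaxation for reversible *producers* can be inflated by the
  solver in contrived models; the preset's producer sets are irreversible,
  where the term is exact.
* Hit-and-run mixing is not diagnosed; thinning 100 is generous for these
  small polytopes but is a parameter, not a guarantee.
* Gene rules are carried as strings and substituted, never evaluated:
  knockouts here are reaction-bound operations, not GPR logic.
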