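---
title: "Eco-efficiency scoring and spatial association networks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-efficiency scoring and spatial association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoefnet)
```

`ecoefnet` chains four models: slacks-based efficiency measurement with an
undesirable output, gravity-model network construction, social-network
structure analysis with CONCOR blockmodelling, and QAP permutation inference.
This vignette records what each model assumes, the parameters that matter,
the numerical choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish about real yearbook data.

## The panel and the carbon account

A panel is a complete rectangle of city-year records: four inputs (crop sown
area, 10³ ha; primary-industry labor, 10⁴ persons; machinery power, 10⁴ kW;
fertilizer applied, 10⁴ t), two desirable outputs (grain output, 10⁴ t; gross
agricultural output value, 10⁸ yuan), and carbon-source quantities. Carbon
emissions — the sole undesirable output — are a coefficient-weighted sum over
sources, `E = Σ c_k q_k`, reported in 10⁴ t. The shipped coefficient table
covers the six-source convention of the agricultural-carbon literature
(fertilizer 0.8956 kg C/kg, pesticide 4.9341, plastic film 5.18, diesel
0.5927, plowing 312.6 kg C/km², irrigation 20.476 kg C/ha), with unit
conversions as explicit table columns. These are literature conventions, not
measurements; any study with its own factors should replace the table
(`read_carbon_coefficients()` takes a path), and the source set itself is
whatever `cs_*` columns the panel carries.

Validation is strict by design: a missing (city, year) cell, a negative
value, or a zero in any DEA input/output is an error naming the offender.
Ratio-form efficiency is undefined at zero, and silently imputing values
would corrupt scores downstream, so nothing is imputed.

## SBM efficiency with an undesirable output

`solve_sbm()` minimizes the ratio of average input slack reduction to average
output slack expansion, with carbon entering the constraints in the input
direction. The fractional program is linearized by the standard
variable-substitution (Charnes–Cooper) transformation — every variable scaled
by t, the denominator pinned to 1 — and solved exactly as an LP. ρ ∈ (0, 1],
with ρ = 1 iff all optimal slacks vanish.

Frontier units (ρ within 1e-7 of 1) are re-scored by `solve_super_sbm()`
against the frontier formed without them: the point may be worsened (inputs
and bads expanded, goods retained) until it reaches the residual frontier,

δ = min [ (1/(m+s₂)) (Σ x̄ᵢ/xᵢₒ + Σ ȳᵗᵇ/yᵗᵇₒ) ] / [ (1/s₁) Σ ȳᵣᵍ/yᵣᵍₒ ],

subject to x̄ ≥ X₋ₒλ, ȳᵍ ≤ Y^g₋ₒλ, ȳᵇ ≥ Y^b₋ₒλ, x̄ ≥ xₒ, 0 ≤ ȳᵍ ≤ yᵍₒ,
ȳᵇ ≥ yᵇₒ. Treating bads direction-wise as inputs (they may be *increased* to
reach the residual frontier, and their proportional expansion joins the
numerator average) is one of several published variants; it keeps δ = 1 for
an exactly reproducible point and δ > 1 for strictly dominating units, which
is all the final score P = ρ-or-δ requires.

Open design choices, and what was chosen:

* **Returns to scale**: constant (CRS) by default — the common default of the
  DEA software lineage used in this literature; `rts = "vrs"` adds Σλ = 1.
  VRS super-efficiency can be genuinely infeasible; that surfaces as an
  error, never a patched score.
* **Frontier scope**: per-year frontiers by default (annual cross-sections
  are what gets reported); `scope = "pooled"` gives one intertemporal
  frontier when scores must be comparable across years.
* **Tie rule**: ρ ≥ 1 − 1e-7 counts as efficient and triggers super-SBM.
* **Degeneracy**: alternate optima in λ are accepted; only the optimal
  objective and slacks are contractual.

### The LP layer

The linearized programs are small (≈ n + m + s₁ + s₂ variables, under twenty
rows) but heavily degenerate: the evaluated DMU sits in its own reference
set, and panel magnitudes span orders of magnitude. The package carries a
dense two-phase simplex tuned for exactly this shape: rows and columns are
equilibrated before solving, pivoting prefers large elements (Dantzig
entering, largest-pivot ratio ties) and falls back to Bland's least-index
rule after a degenerate stall so termination is guaranteed, and every
solution is verified against the original constraints before it is accepted.
Feasibility/optimality tolerances are 1e-9 on the equilibrated tableau.

The tests check this layer two independent ways: against hand-derived LP
optima, and — for the DEA programs themselves — against an LP-free oracle
that minimizes the original fractional objective by enumerating all basic
feasible points of the untransformed polyhedron (valid because a
linear-fractional objective with positive denominator attains its minimum at
a vertex). On random five-DMU instances the two routes agree to better than
1e-4; units invariance (rescaling any input/output column for all DMUs)
holds to 1e-9.

## Gravity network

Masses are the final scores P; strengths are Sᵢⱼ = Kᵢⱼ MᵢMⱼ / Dᵢⱼᵇ with the
asymmetric contribution rate Kᵢⱼ = Mᵢ/(Mᵢ+Mⱼ), so Kᵢⱼ + Kⱼᵢ = 1 and
Sᵢⱼ/Sⱼᵢ = Mᵢ/Mⱼ — the network is directed because the larger mass
contributes more of the pair's interaction. b = 2 is the conventional
distance attenuation. Distances are great-circle (haversine, sphere radius
6371.0088 km) from city coordinates; a user-supplied distance matrix
overrides them when a projected distance is preferred, since projected
distances are not reproducible without the projection.

Binarization takes the *global off-diagonal mean* as the threshold — the
natural reading of "the average value of the matrix" — with a strict
inequality, so ties at exactly the mean are 0; a row-mean variant is provided
because it is common in this literature. Per-year networks are built from
that year's scores, and the final study year is the default for downstream
structure analysis. Both threshold rules are invariant to common rescalings
of all masses or all distances (threshold and strengths co-scale), which the
tests assert exactly.

## Network structure

Density is m/(n(n−1)) over directed ties. Centralities are the standard
Freeman definitions — normalized degree deg/(n−1), closeness (n−1)/farness,
betweenness as summed geodesic fractions normalized by (n−1)(n−2)/2 — on the
symmetrized network by default (a tie in either direction connects;
directional variants are exposed for degree). Two conventions the literature
rarely states are made explicit and configurable:

* unreachable pairs contribute distance n (the node count) to farness, so
  closeness is defined on disconnected networks;
* report rankings break ties by value descending, then city id ascending, so
  ranked tables are deterministic.

Both fraction and percent scales are emitted, since published centrality
tables mix normalization scales. Correctness is checked against igraph (an
independent implementation) to 1e-10 on random graphs, and betweenness
additionally against walk-count path enumeration on tiny graphs.

## CONCOR subgroups

`concor_split()` builds each node's profile from its full row and column of
the tie matrix — structural equivalence with respect to the whole network,
also when a block is re-split at depth 2, the convention of the established
blockmodelling software lineage. Pairwise profile correlations exclude the
positions referring to the two nodes themselves (diagonal and mutual-pair
entries). The correlation matrix is then repeatedly replaced by the
correlation matrix of its own columns until every off-diagonal entry is
within 1e-6 of ±1 (cap 200 iterations), and the sign pattern of the first
row gives the bipartition; depth 2 yields four cohesive subgroups. Subgroup
density divides realized by possible ties per block pair; the image matrix
applies the α-density criterion with α defaulting to the overall network
density. Weighted by block sizes, subgroup densities re-aggregate *exactly*
to the overall density — an identity the tests assert to machine precision.

Degenerate cases are handled explicitly rather than silently: a
zero-variance profile (e.g. an isolate) is assigned to its most-correlated
non-degenerate neighbor's block, else to the larger block, with a warning; a
pair whose correlation is undefined only after the exclusions is treated as
uncorrelated; singleton diagonal density cells are 0 and flagged.

A limitation worth knowing: on planted 4-block networks (48 nodes, within-
block tie probability 0.6, between 0.05) the iterated-correlation sign split
recovers the exact planted partition in roughly 90–94% of runs. The misses
are near-misses — typically one weakly-attached node whose initial profile
correlations favor its planted block but whose sign flips during the
iteration, occasionally a first split that does not separate the four blocks
two-and-two. This greediness is intrinsic to iterated-correlation
blockmodelling (every canonical variant we measured — restricted vs full
profiles, with or without the exclusions, symmetrized input — performs the
same or worse), so exact recovery on every realization should not be
expected from CONCOR on data this noisy.

## QAP inference

Predictors are symmetric absolute-difference matrices of city attributes
(agricultural-economy share of GDP, urbanization rate, rural per-capita
income, fertilizer intensity, mechanization intensity, population) plus
binary spatial adjacency; the dependent matrix is the directed tie network.
All statistics use the vectorized off-diagonal entries only.

QAP correlation permutes rows and columns of the predictor jointly
(relabeling nodes, which preserves the dyadic dependence structure);
p-values follow the add-one convention p = (1 + #extreme)/(1 + n_perm), so
they are never exactly zero, and both two-tailed (on |r|) and directional
one-tailed values are reported because published tables mix signs. MRQAP is
OLS — a linear probability model for a binary network — with coefficient
nulls from either Y-permutation (default: the dependent matrix is relabeled,
matching "random row and column replacement"; with 999 permutations the
achieved size at α = 0.05 is exactly 50/1000) or Dekker's
double-semi-partialing (each predictor's residual matrix on the others is
permuted; more robust under predictor collinearity). Exactly collinear
predictors are an error naming the pair. Significance stars follow the
0.01/0.05/0.1 convention. Given (seed, n_perm, method) every p-value is
bit-for-bit reproducible.

Calibration is tested, not assumed: under independence the QAP correlation
test rejects at 4–5% at nominal α = 5% (500 simulations, 999 permutations),
and MRQAP recovers planted effects of |β| = 2 on standardized predictors
(47 nodes, 5000 permutations) with the correct sign and p < 0.05 in
essentially every run.

## The synthetic yearbook generator

`generate_panel()` emulates the structure the analysis assumes, not any real
geography: 47 cities on a jittered grid (grid 4-neighborhood = contiguity,
so adjacency and distance are internally consistent without shapefiles),
four provinces as contiguous column bands, 2010–2020. City scale is
log-normal (sdlog 0.45); all four inputs are proportional to scale with
multiplicative mean-one log-normal noise (default coefficient of variation
0.15, a plausible cross-sectional dispersion for yearbook indicators) and
mild secular trends (machinery growing, labor declining); outputs multiply a
Cobb-Douglas input composite by a province productivity multiplier (defaults
1.00/0.85/0.72/0.62, ordered so provinces separate cleanly on the frontier)
and a common 3.5%/yr trend; carbon sources are proportional to fertilizer,
machinery and sown area. With noise off, inputs are exactly proportional to
scale, so under constant returns the province multiplier alone orders SBM
scores — the dominance property the tests exploit.

`generate_tie_network()` plants tie-formation effects: tie probability is
logistic in the standardized predictors with chosen coefficients (defaults:
adjacency +2, economic/income/mechanization differences negative, population
difference +0.8), and the intercept is calibrated by root-finding so the
expected density lands at the target (default 0.19, the empirically reported
density regime, so downstream code is exercised in-regime). Ties are drawn
independently per ordered pair; everything is deterministic given the seed.

What passing tests on this generator establish: the algorithms recover known
structure from data with the right correlation skeleton, magnitudes and
noise character. What they do not establish: behavior under real yearbook
pathologies — reporting breaks, administrative boundary changes, heaped or
interpolated values, spatially autocorrelated measurement error — or any
claim about the actual upper-Yangtze cities, whose raw data the generator
deliberately does not imitate.

## Reporting conventions

Provincial report tables are unweighted means: one cell per (province,
year), a yearly average that is the mean of the provincial cells (not the
mean over all cities — this is what reproduces published tables of this
shape), and an `Average` row of column means. Efficiency is printed to 3
decimals and percentages to 1, matching the field's print precision; grade
bands are high (P ≥ 1), relatively high [0.8, 1), medium [0.6, 0.8), low
[0.4, 0.6), lowest (< 0.4), with boundaries in the upper band. The two "low"
labels that appear in some published tables are disambiguated as
`low`/`lowest`; the band edges are what matter.

## Problem sizes used in the shipped checks

The test suite and acceptance script run at the study's native scale where
that is cheap (47 cities × 11 years for scoring and the pipeline; 47-node
networks for QAP recovery; 48-node planted networks for CONCOR) and at
reduced scale where an oracle is combinatorial (five-DMU instances for the
vertex-enumeration DEA oracle, whose cost is binomial in dimensions; graphs
of up to 12 nodes for the igraph comparisons, 8 for path enumeration). These
sizes were chosen as the smallest that still exercise every code path and
frontier configuration.
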