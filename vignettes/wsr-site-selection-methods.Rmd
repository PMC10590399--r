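---
title: "Staged WSR site selection: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged WSR site selection: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsrsite)
```

## The problem and the staged model

Siting a temporary emergency medical facility (a Fangcang-style shelter
hospital converted from a gymnasium or exhibition centre) is a
multi-criteria decision problem whose criteria are heterogeneous: some
are absolute physical requirements, some are quantifiable properties of
the built environment, and some exist only as expert judgment. The
Wuli–Shili–Renli (WSR) systems methodology handles this by *staging*
the decision rather than solving it in one shot:

1. **Wuli — hard constraints.** Each Wuli criterion carries a threshold
   and a comparator; a candidate survives only if it satisfies *all* of
   them (conjunction). "At least 20 m greening clearance" maps to
   `ge 20`, so exactly 20 m passes. A missing attribute is an error,
   never a silent exclusion: untraceable drops would defeat the audit
   trail, which records one row per violated constraint.
2. **Shili — entropy-weighted crisp TOPSIS.** Survivors are scored on
   objective criteria, ranked by relative closeness to the ideal, and
   the top fraction (default one half, by ceiling) is retained.
3. **Renli — BWM-weighted interval type-2 fuzzy TOPSIS.** The retained
   candidates are judged linguistically by experts; judgments become
   trapezoidal interval type-2 fuzzy sets, are normalised, weighted,
   defuzzified through a ranking value, and ranked by closeness, with
   Shili closeness breaking exact ties.

The stage containment chain (initial ⊇ post-Wuli ⊇ post-Shili ⊇ final)
is asserted at every boundary.

## Stage 2: normalisation, entropy weights, TOPSIS

Raw criterion values `b_ij` are min–max normalised per column: benefit
columns map `(b - min) / (max - min)`, cost columns reflect to
`(max - b) / (max - min)`. This makes the whole stage invariant to
positive affine rescaling of any raw column — units never matter.

The entropy weight method is applied **to the normalised matrix**:
shares `p_ij = f_ij / sum_i f_ij`, entropy
`e_j = -(1/ln m) sum_i p_ij ln p_ij` (with `0 ln 0 := 0`), divergence
`d_j = 1 - e_j`, weights `w_j = d_j / sum d_j`. The method itself is
stated without formulas in much of the applied literature; these are
the canonical ones, and the normalised-matrix convention follows the
position of the weighting step after normalisation in the staged
workflow. One practical consequence worth knowing: since min–max
normalisation is affine, two columns whose *normalised* values are the
same multiset receive equal weights even if their raw dispersions
differ; what the entropy weight rewards is concentration of the share
distribution, not raw variance.

Weighted values `h_ij = w_j f_ij` are compared against the column-wise
maxima (positive ideal) and minima (negative ideal); Euclidean
distances `d+`, `d-` give the closeness `E = d- / (d+ + d-)`, sorted
descending. Ties are broken by input order and flagged. Degenerate
inputs fail loudly: a matrix whose columns are all constant has no
information for entropy weighting, and identical alternatives make
`d+ = d- = 0` for every row.

A constant column is normalised to zeros with a warning and therefore
receives entropy weight 0 — a non-discriminating criterion carries no
information, and crashing on real data would be worse.

The retention rule keeps `ceiling(fraction * m)` candidates; if a
closeness tie straddles the cut, all tied candidates are kept, since
discarding an alternative indistinguishable from a kept one cannot be
justified.

## Stage 3 weights: the linear Best-Worst Method

Experts supply two 1–9 comparison vectors: best-to-others `a_Bj` and
others-to-worst `a_jW`. The package solves the *linear* BWM model —
minimise `xi` subject to `|w_B - a_Bj w_j| <= xi`,
`|w_j - a_jW w_W| <= xi`, `sum w = 1`, `w >= 0` — because it yields a
unique weight vector, which a downstream ranking pipeline needs; the
original nonlinear ratio model can return weight intervals. The LP is
solved with `boot::simplex()`. `xi* = 0` exactly when
`a_Bj * a_jW = a_BW` for every j, and consistent integer-ratio inputs
are recovered exactly (this is a tested invariant).

The consistency ratio divides `xi*` by the standard published
consistency index `CI(a_BW)` (0.00, 0.44, 1.00, 1.63, 2.30, 3.00,
3.73, 4.47, 5.23 for `a_BW` = 1..9). Two caveats. First, crossing the
advisory bound warns and never blocks: consistency policy belongs to
the decision makers. Second, that CI table was calibrated against the
nonlinear model's deviations; under the linear model the optimal `xi*`
is much smaller, and a numerical sweep over valid 1–9 inputs never
produced a ratio above about 0.23. The warning threshold is therefore
an argument (`cr_warn`, default 0.25) rather than a constant worth
trusting.

Several decision makers may each supply comparison vectors; the solved
weight vectors are averaged arithmetically and renormalised, with
per-DM consistency reported. This is the simplest transparent
aggregation; no consensus iteration is attempted.

## Stage 3 ranking: interval type-2 fuzzy TOPSIS

The seven-term vocabulary (VL, L, ML, M, MH, H, VH) maps to fixed
trapezoidal interval type-2 fuzzy sets on the 0–10 support, each a pair
of trapezoids (upper and lower membership bounds) with two heights.
The scale can be overridden from YAML, but the default parameters are
the ones in common use and their ranking values are strictly increasing
along the vocabulary — a property the package tests rather than
assumes.

Three conventions in this stage were genuinely open and are worth
recording:

* **Normalisation denominators.** Benefit columns divide all eight
  vertices by `a* = max_i a4u`, the largest upper-trapezoid right
  endpoint *in the column*; cost columns use the reciprocal form with
  `a- = min_i a1u`. The subscripting in parts of the applied
  literature can be read as indexing the maximum per *row*, but a
  row-wise reading would normalise an alternative against itself and
  destroy comparability across alternatives, so the column-wise
  (per-criterion) reading is implemented.
* **The heights term of the ranking value.** The defuzzification used
  here is `Rank = sum(M_p) - (1/4) sum(S_q) + sum(H_w)` over both
  trapezoids, with `M_p` the consecutive-vertex means, `S_q` the
  population standard deviations of consecutive vertex pairs plus all
  four vertices, and `H_w` the membership heights. A variant reading
  takes `H_w` to be the second and third vertices instead; it is
  implemented behind `hw = "vertex"` (and flagged by the config
  validator) so the two can be compared, but heights are the default:
  they make the crisp closed form `Rank = 6v + 4` hold for degenerate
  sets with unit heights and keep the vocabulary strictly ordered.
* **Closeness.** The closeness coefficient is
  `E = d- / (d+ + d-)` with `d±` the Euclidean distances of a row's
  ranking values to the column-wise ideal ranking values — the same
  form as the crisp stage. (A formula in which the ideals alone appear
  in the ratio is constant across alternatives and cannot produce a
  ranking, so it cannot be what any working pipeline computes.)

Weights multiply the normalised fuzzy values *before* defuzzification
(`v = w × r`, then `Rank(v)`), following the weighting-then-ranking
order of the staged workflow. Because `Rank` is affine in a scalar
weight (`Rank(w·v) = w·(ΣM − ¼ΣS) + ΣH`), the heights contribute a
constant offset per cell that cancels in the distances; this is also
why the two `hw` variants often produce very similar rankings.

With all-crisp judgments and unit heights the fuzzy engine reduces
exactly to crisp TOPSIS on the max-normalised value matrix — a tested
cross-engine consistency property.

Exact closeness ties are broken by the Shili-stage closeness (higher
wins), implementing the staged methodology's tie rule; without Shili
data, input order decides, and ties are flagged either way.

## Criterion calculators

Air and rail accessibility use the potential (gravity) model
`sum_j M_j / D_ij` over hubs: additive, increasing in capacity,
decreasing in distance, undefined at zero distance (an error, not a
clamp). Capacities are unitless service scores and distances are in
km; only internal consistency matters. Road accessibility is *not*
computed — it is the number of residential settlements covered by a
15-minute drive-time isochrone, a GIS product consumed as a plain
numeric column. Distance to hospital is the minimum over the
facility's designated-hospital distances (a cost criterion); hospital
eligibility is administrative data resolved upstream. Space scale is
available indoor area divided by the specified per-capita area
(default 4 m² per bed), i.e. bed-equivalent capacity.

## Sensitivity harness

`run_sensitivity_cases()` re-runs only the weighting-and-ranking
portion of a stage under alternative weight vectors, holding
normalisation, judgments and tie-break data fixed, and reports signed
rank shifts against the baseline (entropy weights for Shili, BWM
weights for Renli). Case weights that do not sum to one are
renormalised with a warning. The ten published perturbation designs
per stage ship as fixtures (`shanghai_sensitivity_cases()`). Two
properties anchor the harness: the baseline case shifts nothing, and a
weakly dominant alternative is rank 1 under every nonnegative weight
vector.

## The synthetic generator

`generate_case()` draws a latent quality `q_i ~ U(0,1)` per facility
and derives every criterion from it: hub distances `5 + 30(1-q)` km
(clamped), hospital distances `0.5 + (10+2h)(1-q)` km, road coverage
`5 + 95q` settlements, indoor area `5000 + 95000q` m², each plus
independent Gaussian noise of standard deviation `noise_sd` (default
0.05 on the latent scale — visible but not order-destroying at the
default cohort size). Greening clearances are drawn so that exactly
`floor(wuli_fail_fraction * n)` facilities fall below 20 m, which is
what makes screening counts exactly reproducible. Renli judgments are
quantile bins of `q` over the seven terms, optionally perturbed one
step with probability `linguistic_noise`; with zero noise all four
Renli columns tie within a bin, deliberately exercising the
Shili-closeness tie-breaker. Consistent BWM vectors are built from
`ground_truth_weights` by rounding ratios into 1..9 (clipping warns).

With `noise_sd = 0` and `linguistic_noise = 0` the end-to-end ranking
equals the latent ordering — the pipeline's rank-recovery ground
truth. What the generator does *not* emulate: spatially correlated hub
distances, realistic facility spatial point patterns, inter-criterion
correlation beyond the single latent factor, heteroscedastic expert
disagreement, or missing data. Passing the synthetic suite therefore
shows the pipeline's algebra and orderings are right, not that the
criteria capture any real city's geography.

## The published case and what is reproducible

The Shanghai case tables that the methodology was demonstrated on ship
as plain-text fixtures: stage-2 entropy weights and closeness for the
22 screened candidates, stage-3 weights and nine-decimal closeness for
the 11 finalists, and the sensitivity designs. The *raw* stage inputs
(the 22×5 evaluation matrix and the 11×4 linguistic judgment table)
exist only in supplementary files that are not redistributable, so the
printed weights and closeness values cannot be independently
recomputed here; the corresponding checks in the test suite look for
user-supplied copies (see `inst/extdata/shanghai/README.txt`) and fail
honestly without them.

For the judgment table a **synthetic reconstruction** is packaged
(`shanghai_renli_judgments()`): an exhaustive search over the
seven-term vocabulary (ideal-term combinations × per-row term tuples,
under both heights variants and both spread conventions) found no
assignment reproducing the printed nine decimals exactly — strong
evidence the published run used unrounded weights and/or aggregated
multiple experts — and the best self-consistent assignment reproduces
all 11 closeness values within 3.9e-4. Because that fixture was fitted
to the published output, agreement with it demonstrates the engine's
internal consistency with the published pipeline, not independent
reproduction; it is documented as synthetic everywhere it appears.
What *is* reproducible from print alone: retaining the top half of the
published stage-2 ranking yields exactly the 11 facilities of the
published final stage.

## Numerical choices and problem sizes

All arithmetic is double precision; printed precision (3 decimals in
stage-2 tables, 9 in the final ranking) is a rendering concern only,
applied in `write_ranking()`. Weight vectors must sum to 1 within
1e-9 unless renormalisation is requested. Oracle-equivalence tests
compare both engines against independent literal transcriptions of the
stage equations at 1e-12 on small random instances (4×3 crisp, 3×2
fuzzy); invariance tests run a handful of seeded repetitions each. The
test suite and the acceptance script use cohorts of 8–39 facilities,
100-repetition BWM recovery, and 10 zero-noise end-to-end runs —
sizes chosen to pin the algebra down while keeping the whole suite
interactive (seconds, not minutes).

## Limitations

* The framework ranks; it does not optimise capacity allocation or
  multi-facility portfolios.
* Group judgment handling is deliberately minimal (per-cell single
  judgments; arithmetic-mean BWM aggregation).
* GIS steps (isochrones, routing, geocoding) are out of scope by
  design; their products enter as plain columns.
* The published headline numbers remain partially unverifiable without
  the supplementary raw inputs, as described above.
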