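---
title: "Sorted-string alignment of LC-MS features: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorted-string alignment of LC-MS features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmalign)
```

## The model

A dataset is `N` features over `K` maps; a feature is `(rt, mz, map,
intensity)`.  We assume every observed feature is a noisy realisation of a
true metabolite at `(rt*, mz*)`, with `|rt − rt*| ≤ δr` and
`|mz − mz*| ≤ δm(mz*)`.  The retention-time tolerance `δr` is a constant
(default 0.3 min); the mass tolerance is proportional to the mass,
`δm(m) = ε·m·10⁻⁶` with `ε` in ppm (default 10, i.e. 0.00001 Da at 1 Da),
reflecting that spectrometer mass error scales with the measured mass.  A
fixed-Dalton mode exists only for comparison studies against tools with a
constant window (e.g. 0.0071 Da).

A *consensus* (predicted metabolite) is a set of features, at most one per
map (the collision condition), each within `(δr, δm)` of the consensus
centre.  The centre is the **midrange**, `(min + max) / 2` per dimension —
not the mean — so that members piling up on one side of the window do not
bias it.

## Why sorting works

Every feature is encoded as a record of fixed-width zero-padded decimal
fields (`1.5` → `001.5000`) joined by `$`.  Two facts carry the algorithm:

* For a common layout, lexicographic order of digit-aligned values equals
  numeric order (property-tested over random value sets).
* The byte `$` sorts below every digit and the letter `w` above, so field
  boundaries never interfere and "whitened" records sink to the bottom.

A sorted mass list is cut greedily into M-clusters: a new cluster starts
whenever consecutive masses differ by more than `2δm`.  The factor 2 is
necessary because two members of one consensus can sit on opposite extremes
of the window around the true mass.  With the gap rule, a planted consensus
can never be split: all members lie within `δm` of the centre, so adjacent
sorted members are at most `2δm` apart and no break can fall between them
(the same argument covers R-clusters with `2δr`).  This guarantee is
asserted in the tests with members placed exactly on the tolerance
boundary.

**Numerical choice.**  The break threshold could plausibly be evaluated
against the span from the cluster minimum instead of the adjacent gap.  We
use the adjacent gap, for a concrete reason: under the span rule a cluster
that begins at an unrelated lighter feature can place its boundary *inside*
a later consensus whose members then straddle it permanently — in two-map
simulations at nonzero noise this splits an expected handful of planted
pairs per ~1500-feature dataset and the recovery rate drops below 100%,
which contradicts the algorithm's own safety guarantee.  The adjacent-gap
rule is the reading under which that guarantee is a theorem.  The
mass-proportional tolerance is evaluated at the heavier mass of each
adjacent pair (the inclusive-safe choice; at 10 ppm the difference between
the candidate evaluation points is a relative 10⁻⁵ and has no practical
effect).

## The alignment loop

For the demanded size `n = K, K−1, …, 2`, passes repeat until one accepts
nothing: sort the S list (whitened records sink and are skipped), scan
M-clusters, copy each to an rt-leading list with an origin column, sort,
scan R-clusters, and refine each R-cluster:

1. compute the midrange centre of the current members;
2. if any member violates `(δr, δm)` against the centre, drop the worst
   offender (largest normalized distance
   `√((Δrt/δr)² + (Δmz/δm)²)`) and recompute;
3. if two members share a map, keep the one closest to the centre and drop
   the worst of the others, and recompute;
4. at the fixed point, accept only if exactly `n` members remain.

Accepted members are whitened immediately; everything else — including
members dropped from an accepted cluster — stays in the pool for the next
pass.  One removal per iteration bounds the refinement at cluster-size
iterations; the pass/decrement structure terminates because the pool only
shrinks.  At `n = 1` every remaining feature becomes a singleton directly:
running the cluster machinery there could reject a leftover cluster whose
fixed point has size above 1, which would leave features unassigned and
break conservation.  Conservation (`Σ i·cᵢ = N`) and collision-freedom are
therefore structural, and the tests assert them on random data.

The refinement procedure is a design choice: the collision condition only
demands that duplicates must not survive, not how to choose among them.
Our keep-the-closest rule agrees with an exhaustive best-subset search
(maximal size, ties by summed normalized distance) on the tested instances;
on pathological overlaps the greedy choice is not guaranteed optimal.

Boundary comparisons use a padded tolerance `t·(1+10⁻¹²)+10⁻¹²` so that
members placed exactly on the boundary (meaningful, because values pass
through fixed-decimal encoding) are not lost to floating-point noise.
Decimal widths are inferred from the data's printed precision, capped at 8
digits; all scanning decisions are made on the encoded (rounded) values, so
the observable behaviour is exactly that of the string path.  Sorting is
stable with ties falling through the full record, so reruns are
byte-identical; the aligner contains no randomness.

## The simulators: a stated world

`simulate_two_map()` plants "true simulated metabolites" (TSMs) uniformly
at `rt ∈ [1, 27]` min, `mz ∈ [1, 500]` Da over two maps: aligned TSMs
contribute one feature to *each* map, non-aligned TSMs a single feature to
a random map (defaults 493 and 504, giving 986 + 504 features).  Feature
noise is uniform, `U(−γδr, γδr)` and `U(−γδm(mz*), γδm(mz*))`, with the
noise level `γ ∈ [0, 1]` a fraction of the instrument resolution; at γ ≤ 1
every feature still satisfies the resolution condition against its own TSM.
`simulate_multi_map()` generalises to K maps (default 10) with a planted
count per consensus size (default 10 each, 550 features), each size-`s` TSM
occupying `s` distinct random maps.

Two choices close gaps the stated world leaves open.  (i) TSM centres are
rejection-sampled so every pair is separated by more than `4δr` in rt *or*
`4δm` in mass — separation in both dimensions simultaneously is infeasible
at ~1000 TSMs in this window.  Four because features stray up to one
tolerance from their TSM and cluster scans use doubled tolerances: beyond
4, features of different TSMs can never co-cluster in the separated
dimension.  This makes 100% sensitivity/specificity a correctness property
of the aligner rather than a statistical accident.  (ii) Intensities are
log-normal (meanlog 10, sdlog 1); they are inert for alignment and only
feed the differential-analysis pipeline.

What a green simulation test does **not** establish: real chromatography
drifts (the model deliberately ignores retention-time shift), real mass
error is not uniform, real data contain adducts/isotopes and genuinely
ambiguous co-eluting species with no separation guarantee, and peak picking
upstream is out of scope.  The simulators validate the algorithmic
contract, not instrument physics.

## Evaluation statistics

On two-map truth: sensitivity is the percentage of aligned TSMs recovered
*exactly* (both features, nothing else, one consensus — the strictest
reading of "correctly aligned"); specificity is the percentage of
non-aligned TSMs left as singletons.  On multi-map truth, `e = c − t`
per size: positive entries are false predictions, negative are missing
hypotheses.  Without truth, the cumulative alignment curve
`sᵢ = Σ_{j≤i} j·cⱼ` (counting *features*, normalized by `N`) summarises
coverage: flat-at-top = all singletons (disastrous), zero-until-K = all
full-size (perfect), with the biased H/L patterns flagged by exact zero
counts at the top or bottom sizes — counts are integers, so no epsilon
tuning is involved.  Curves are compared only by pointwise dominance;
crossing curves are reported incomparable.

## Differential metabolites

The aligned intensity matrix (consensus × map, `NA` for uncovered maps —
absence is not zero abundance) is tested per metabolite between two
treatment groups on log2 intensities (switchable); rows with fewer than 2
observations in either group are untestable.  Three simplified analogues
stand in for the classic panel: a Welch t-test; a moderated t-test whose
pooled variance is shrunk toward the panel-average with 4 prior degrees of
freedom; and a permutation t-test whose null pools the permuted statistics
across *all* rows (1000 label permutations, seeded).  The pooling matters:
with 6 maps per group a per-row permutation p cannot fall below
2/choose(12,6) ≈ 0.002, so the default α = 0.001 would be unreachable.  A
metabolite is significant only when **all** tests agree at α — an
intersection rule that trades power for a lower false-prediction chance,
with no further multiple-testing correction by default (a
Benjamini–Hochberg switch exists).  A large mean difference with a large
variance is deliberately not enough; the tests assert this case.  The
retention-time–mass density surface uses a Gaussian product-kernel KDE
(Scott's rule per dimension, 100×100 grid, renormalized to integrate to 1)
with significant metabolites overlaid at their consensus centres.

## Known limitations

* Greedy MCM is not provably coverage-optimal on adversarially overlapping
  clusters; equivalence with an exhaustive-partition oracle is verified on
  small separated instances only.
* No retention-time warping, gap-filling, or adduct annotation.
* The multi-map benchmark's composition (equal planted counts per size) is
  a reconstruction; its defaults are parameters, not facts about any
  particular instrument.
* Complexity is near `N log N` when consensus sizes are balanced (the
  scaling test logs a ~4× time ratio for 4× data); degenerate inputs in
  which almost all features share one cluster scan slower.
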