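---
title: "Methods: detectors, indicators, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detectors, indicators, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotgrid)
```

hotgrid detects and evaluates spatial hotspots on gridded count data. This
vignette records the statistical models behind each detector, the
conventions and defaults the package commits to, what the synthetic
generator does and does not emulate, and the design choices that were
genuinely open.

## The data model

A lattice is a tibble with one row per unit (`unit_id`, `row`/`col` for
regular grids, centroid `x`/`y`, `area`) and a `value` column holding the
case count. Coordinates are 0-based and row-major; the centroid of cell
`(r, c)` with side `s` is `((c + 0.5)s, (r + 0.5)s)`. Irregular lattices
enter through GeoJSON polygons; their centroids and areas come from the
shoelace formula and contiguity from shared boundary vertices (queen) or
shared edges (rook). All weights are binary and symmetric; G\* includes the
self-weight, local Moran excludes it — the standard conventions for these
statistics.

## Detectors

### Poisson circular scan

Under the constant-risk Poisson null, a window holding a share `p` of the
background population expects `mu = C p` of the `C` total cases. Each
window is scored with the one-sided likelihood ratio

\[
LR = \left(\frac{c}{\mu}\right)^{c}
     \left(\frac{C-c}{C-\mu}\right)^{C-c}, \qquad c > \mu,
\]

clamped to 1 for deficits, and evaluated in log space (a window with
`c = C` contributes only its first term; windows covering the whole
population are skipped, as `mu = C` leaves no alternative). Windows are
distance-ordered prefixes: for each center, units sorted by centroid
distance, cut at the ends of distance tie groups, truncated when the
cumulative population share exceeds `max_fraction` (default 0.5, i.e. half
the background population); every center keeps at least its singleton
window. The continuous-radius scan visits exactly these member sets, so
the enumeration is lossless. Cells carry population 1 by default —
appropriate for equal-area cells with no population layer — and a `pop`
argument activates population-weighted expectations.

Significance uses the distribution of the *maximum* log-LR over permuted
fields, and secondary clusters are taken greedily in descending LR,
skipping overlaps, each compared against the same max-LR null. Ties
resolve to the smaller window, then the lower center id, making results
deterministic.

### Local statistics

For G\*, the neighbourhood sum of a unit is a simple random sample of
`W_i` values under the randomization hypothesis, giving
`E[G*_i] = W_i/n` and
`var[G*_i] = W_i (n - W_i) s^2 / ((n-1) n^2 \bar x^2)` with `s^2` the
population (divide-by-`n`) variance; for local Moran the moments are the
standard total-randomization expressions involving the kurtosis ratio
`b_2 = m_4 / m_2^2`. Both default to one-sided upper analytic z-tests at
`alpha = 0.05` with no multiple-testing correction — the convention the
comparative experiment states — with conditional permutation tests and
Benjamini–Hochberg correction as opt-ins. Hotspot extraction keeps
significant units with `z > 0` (G\*) or with positive statistic and
above-mean center (Moran, high–high quadrant); low-tail extraction is
available behind a `direction` flag. Constant fields leave the z-scores
undefined; they are flagged `NA` rather than raising an error, and
extraction then returns an empty labeling.

### AMOEBA

Ecotope growth starts from a seed unit and repeatedly considers the
first-order (queen) neighbours of the current ecotope. Because the G\*
z-score at a fixed neighbourhood size is monotone in the added mass, the
best subset of a given size is always a prefix of the value-ranked
frontier; each round therefore evaluates all prefixes, takes the best, and
permanently excludes the rejected frontier units. Growth stops when no
addition strictly increases the statistic. The test suite verifies this
prefix device exhaustively against all frontier subsets, and verifies
that growth from seeds inside a planted cluster attains the exhaustive
maximum over all connected supersets of the seed. From arbitrary seeds the
procedure is a one-round-lookahead optimizer and can stop below that
global maximum — that is a property of the algorithm, not of this
implementation, and the tests assert the upper bound rather than
pretending equality.

Significance is Monte Carlo: every seed is regrown on each simulated null
field. Two choices matter and both are exposed:

* **Null field** (`null`). The default redistributes the `N` individual
  cases over units uniformly at random (`"rescatter"`, a multinomial
  draw), the same constant-risk null the scan uses. The alternative
  relabels the observed cell values across units (`"permute"`). Relabeling
  conditions on the observed value multiset; when hotspots hold much of
  the mass, the permuted fields retain that heavy upper tail and the
  region-growing optimizer chains the scattered high values into large
  null ecotopes, which costs substantial power on benchmark-scale
  scenarios. Rescattering matches the "rearrange the cases" reading of
  Monte Carlo testing for case data and keeps the null light-tailed.
* **Reference statistic** (`null_scope`). The default per-seed test
  compares each ecotope with regrowths from its own seed — the
  conventional AMOEBA test, and the one that reproduces the benchmark
  behaviour (near-complete recall of planted patches). Because it takes a
  level-`alpha` decision at every one of the `n` seeds, it flags a
  nontrivial share of a pure-noise field (roughly `alpha` of the seeds,
  each an ecotope of a few cells — an uncorrected battery of local tests).
  `null_scope = "max"` compares instead with the null maximum over all
  seeds, a family-wise convention whose expected flagged area on noise is
  at or below `alpha`, at the price of losing moderate elongated clusters
  whose statistic sits near the optimized noise maximum. The choice is a
  genuine power/calibration trade-off; the per-seed default favours power
  and benchmark fidelity, and users who need area calibration on
  null-like data should switch to `"max"` (or raise `n_sim` and use
  `correction = "bh"`, noting that the BH threshold can fall below the
  Monte Carlo floor `1/(1+n_sim)` and then flags nothing).

Significant ecotopes are resolved greedily by descending statistic,
discarding any that overlaps an already-accepted one; the union of
survivors is the labeling.

### Monte Carlo conventions

All permutation p-values use the add-one rank rule
`p = (1 + \#\{draws \ge observed\}) / (1 + n_{sim})` with ties counted
against the observed statistic, so `p` is super-uniform under the null and
its floor is `1/(1 + n_{sim})`. All stochastic entry points take an
explicit integer seed.

## Evaluation indicators

With `n` of `N` cases captured on area `a` of `A`:
HitRate `= n/N`, AreaRatio `= a/A`, PAI `= HitRate/AreaRatio`, and
DCR `= (n/a) / ((N-n)/(A-a))`. The identities
`PAI = HitRate/AreaRatio` and `DCR = PAI (1 - AreaRatio)/(1 - HitRate)`
hold algebraically and are tested to floating precision; DCR is undefined
(reported `NA`) when the labeling covers the whole area or captures every
case, and an empty labeling reports zero rates with `NA` density and shape
indicators.

The shape index compares the total hotspot boundary with the circumference
of an equal-area circle: `SSI = 1 - 2\sqrt{\pi a}/P`, zero for a circle,
below 1 for any patch, scale-invariant. For multi-patch labelings the
perimeters and areas are summed before the index is taken. Perimeters
count exposed cell edges (polygon-union boundary length on irregular
lattices), so interior holes contribute; patches are delimited by rook
connectivity, so a diagonal touch does not fuse two patches.

Cell-based accuracy against a truth mask uses the usual confusion counts
and precision/recall/F1, with undefined ratios flagged `NA` and F1 set to
0 when precision and recall are both 0.

## The synthetic benchmark

The generator plants four connected patches on a 30 × 40 grid — a
quasi-circular blob (101 cells), an elongated two-cell-wide snake (36), a
concave C (84), and a compact blob with a slender L-shaped tail (58);
279 cells in total, pairwise at least 2 cells apart so no patch touches
another even diagonally. Background cells draw i.i.d. Poisson counts with
mean `lam = 3`; patch cells draw from the same distribution conditioned on
the upper tail. "Top 5%" is implemented as conditioning on values at or
above the 95th-percentile count, `q = qpois(0.95, 3) = 6`: the expected
total count under that reading (≈ 4606) matches the benchmark's reported
total (4585) within sampling error, while conditioning strictly above the
5% exceedance probability (`q = 7`) would overshoot by ≈ 270 cases. Only
this sampling mode is implemented; truncated sampling is exact
inverse-CDF, so fields are reproducible bit-for-bit under a seed.

What the generator emulates: count data with a known, irregularly shaped
truth; strong but realistic contrast (patch cells average ≈ 6.6 against a
background of 3); patch archetypes spanning compact, elongated, concave
and tailed shapes. What it does not emulate: population heterogeneity
(all cells are equal-risk), spatially correlated background noise, edge
effects of merged boundary units, or the exact patch coordinates of any
particular published figure — those are not recoverable, so the patches
here are re-designed to the stated archetypes and total. Passing the
benchmark therefore shows that a detector separates high-valued irregular
patches from i.i.d. noise at this contrast; it does not certify behaviour
on population-adjusted rates or correlated fields.

`run_benchmark()` repeats the scenario with per-replicate seeds derived
from a master seed by a counter, runs each detector at `alpha = 0.05`, and
evaluates against the planted truth. The acceptance suite runs 20
replicates at `n_sim = 99` — sizes chosen so the whole suite stays
interactive — and checks the detector ordering (AMOEBA highest mean F1 and
DCR, scan lowest F1) rather than any exact indicator value, which a single
unpublished realization cannot pin down. Null calibration is checked on
truth-free fields at the same sizes.

## Numerical choices and degenerate inputs

* All likelihood ratios are computed in log space; `0 log 0` terms are
  handled explicitly.
* Distance comparisons (window radii, distance-band weights) use a
  relative tolerance of `1e-12` so tie groups are stable against
  floating-point noise.
* Scan ties: smaller member count wins, then lower center id. AMOEBA
  frontier ties: higher value first, then lower unit id. Both make runs
  deterministic under a fixed seed.
* Zero-total fields are rejected by the detectors ("no cases"); constant
  fields are rejected by AMOEBA (growth undefined) and flagged `NA` by
  the local statistics.
* `shape_index()` rejects perimeters below the circular minimum beyond
  floating tolerance; `hit_area_indicators()` validates `0 ≤ n ≤ N`,
  `0 < a ≤ A`.

## Known limitations

* The scan uses circular windows only; elongated hotspots are covered by
  several circles or overshoot into background, which is visible in its
  lower precision on the benchmark.
* AMOEBA's growth is greedy; it is exact per round and from in-cluster
  seeds, but it is not a global optimizer over connected subsets, and its
  default per-seed test is not calibrated in *area* on pure-noise fields
  (see above for the calibrated alternative).
* Analytic z-tests for the local statistics rely on moment approximations
  that are slightly liberal for skewed counts with small neighbourhoods;
  the permutation option is the remedy when that matters.
* No coordinate reference systems, no raster-image I/O, and no space-time
  scanning: the package works in abstract planar lattice coordinates.
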