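# hotgrid

Statistics-based hotspot detection and evaluation on gridded count data.

Crime analysts and spatial epidemiologists routinely need to find *hotspots*
— sets of spatial units whose case counts (burglaries, disease cases,
accidents) are significantly higher than spatial randomness would produce —
and then to decide *which* detection method to trust. Different detectors
draw very different maps from the same counts: circular scan windows produce
round, generous hotspots; local autocorrelation statistics produce tight,
conservative ones; region-growing methods trace irregular outlines. hotgrid
implements four classical detectors side by side, together with a
quantitative evaluation framework, so the comparison can be made with
numbers instead of eyeballing maps.

## Detectors

All detectors operate on a lattice of cells with one count per cell
(regular grids from CSV, irregular polygon lattices from GeoJSON) and a
queen-contiguity neighbourhood by default.

* **Poisson spatial scan** (`scan_detect()`): circular windows centered on
  every unit at every distinct radius up to a population cap (default 50%).
  Each window is scored with the Poisson likelihood ratio
  `LR = (c/mu)^c ((C-c)/(C-mu))^(C-c)` for observed cases `c` against the
  constant-risk expectation `mu`; the maximum LR is tested by Monte Carlo,
  and secondary clusters are reported greedily without overlap.
* **Getis–Ord G\*** (`getis_ord_gstar()`): per-unit ratio of the
  neighbourhood sum (self included) to the study-area total,
  `G*_i = Σ_j w_ij x_j / Σ_j x_j`, standardized with its
  randomization-hypothesis moments and tested one-sided.
* **Local Moran's I** (`local_morans_i()`):
  `I_i = ((x_i - x̄)/S²) Σ_j w_ij (x_j - x̄)`; significant positive values
  with above-mean centers (high–high quadrant) form hotspots.
* **AMOEBA** (`amoeba_detect()`): grows an irregular "ecotope" around every
  seed unit, adding the value-ranked prefix of frontier neighbours that
  maximizes the G\* z-score until no addition improves it, then tests each
  ecotope by Monte Carlo regrowth on simulated null fields.

## Evaluation framework

`evaluate()` scores any hotspot labeling with:

* **HitRate** `n/N` and **AreaRatio** `a/A` — cases captured and area spent;
* **PAI** `= HitRate/AreaRatio` — hotspot case density standardized by the
  overall density;
* **DCR** `= (n/a) / ((N-n)/(A-a))` — hotspot density against the density
  *outside* the hotspots, which rewards capturing cases and discarding
  empty area simultaneously;
* **SSI** `= 1 - 2√(πa)/P` — a standardized landscape shape index in
  `[0, 1)`: 0 for a circle, approaching 1 for complex shapes;
* **precision / recall / F1** against a ground-truth mask, when one exists.

A synthetic generator (`generate_counts()`) reproduces the benchmark design
used for the comparison: a 30 × 40 grid, Poisson(3) background, and four
planted patches of deliberately different shapes (a quasi-circular blob, an
elongated snake, a concave C, and a blob with a slender tail — 279 cells in
total) whose counts come from the top-5% upper tail of the same Poisson
distribution. `run_benchmark()` repeats the scenario and tabulates all
indicators per detector.

## Worked example

```r
library(hotgrid)

grid <- generate_counts(nrows = 30, ncols = 40, lam = 3, tail_q = 0.05, seed = 7)
sum(grid$value)
#> [1] 4630

det <- detect_hotspots(grid, method = "amoeba", n_sim = 999, seed = 7)
glance(det)
#> # A tibble: 1 × 6
#>   method alpha n_clusters n_hotspot_cells cases_captured min_p
#>   <chr>  <dbl>      <int>           <int>          <dbl> <dbl>
#> 1 amoeba  0.05          2             353           2264 0.002

evaluate(det, truth = attr(grid, "truth"))
#> # A tibble: 1 × 17
#>   n_cases total_cases  area total_area hit_rate area_ratio   pai   dcr perimeter
#>     <dbl>       <dbl> <dbl>      <dbl>    <dbl>      <dbl> <dbl> <dbl>     <dbl>
#> 1    2264        4630   353       1200    0.489      0.294  1.66  2.30       382
#> # ℹ 8 more variables: ssi <dbl>, tp <int>, fp <int>, fn <int>, tn <int>,
#> #   precision <dbl>, recall <dbl>, f1 <dbl>
```

Reading the report: the detected hotspots hold 2264 of the 4630 simulated
cases (hit rate 48.9%) on 29.4% of the study area, so the case density
inside hotspots is 1.66× the overall density (PAI) and 2.30× the density
outside them (DCR). Against the planted truth this run recovers every
hotspot cell (recall 1.00) at precision 0.79, for F1 = 0.883; the SSI of
0.826 reflects the irregular outlines AMOEBA traces. The same arithmetic is
available directly, e.g. for a detector that captured 1857 of 4585 cases on
320 of 1200 cells:

```r
hit_area_indicators(n = 1857, N = 4585, a = 320, A = 1200)
#> # A tibble: 1 × 4
#>   hit_rate area_ratio   pai   dcr
#>      <dbl>      <dbl> <dbl> <dbl>
#> 1    0.405      0.267  1.52  1.87
```

A command-line interface covers the same workflows
(`exec/hotgrid simulate|detect|evaluate|benchmark`), reading grid CSV /
GeoJSON and writing per-unit CSV, GeoJSON and JSON reports.

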