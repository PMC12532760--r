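---
title: "Quantifying multiscale landscape pattern change with landpatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multiscale landscape pattern change with landpatterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landpatterns)
library(dplyr)
```

## The problem

Land-use/land-cover (LULC) change alters landscapes in two distinct ways:
it changes how much of each cover class a landscape contains
(*composition*) and how that cover is arranged (*configuration*).  For
natural classes these two axes correspond to habitat loss and to
fragmentation *per se* — configurational change independent of amount.
Because the drivers and ecological consequences of pattern change act at
different spatial scales, pattern metrics have to be computed at several
landscape extents; but most class-level landscape metrics behave
erratically as extent grows, which confounds cross-scale comparison.

`landpatterns` implements the part of this workflow that is scale-safe:
it computes six class-level metrics whose means follow smooth power-law
or linear functions of landscape side length — class area (CA), number of
patches (NP), total edge (TE), total core area (TCA), number of disjunct
core area patches (NDCA) and the Landscape Shape Index (LSI) — on yearly
categorical rasters tessellated into square landscapes, screens them for
predictable scaling, and classifies per-landscape change between two
years into nine directional CA/LSI categories.

## The metrics and their conventions

All metrics are class-level: computed for one cover class within one
square landscape window.  For a class occupying $n$ cells of side $c$ km:

* **CA** $= n\,c^2$ (km²) — composition.
* **NP** — number of maximal connected same-class components.
* **TE** (km) — number of cell faces separating the class from any other
  cover, times $c$.
* **TCA** (km²) — area of *core* cells, those whose entire neighbourhood
  is same-class (edge depth one cell).
* **NDCA** — number of connected components of the core mask:
  "patches within patches".
* **LSI** $= e_{\mathrm{total}} / \min e(n)$ — the class's total edge
  (in faces, window boundary included) over the smallest possible edge of
  an equally sized, maximally aggregated class.  $\min e(n)$ is the
  minimum perimeter of an $n$-cell polyomino: with $m = \lfloor\sqrt n\rfloor$,
  it is $4m$ if $n = m^2$, $4m+2$ if $n \le m(m+1)$, else $4m+4$.
  LSI $= 1$ means a maximally compact shape; it is the package's
  measure of fragmentation *per se*, because the denominator controls
  for class amount.

The standard definitions these metrics descend from leave several
conventions implicit, so the package fixes and exposes them in
`metric_config()`:

* patch connectivity **8** (queen) for NP and NDCA; core neighbourhood
  **4** (rook);
* TE **excludes** the window's outer boundary by default (a landscape
  fully covered by one class has TE = 0), while the LSI numerator
  **includes** it (so that same landscape has LSI exactly 1);
* window border cells are never core: a neighbour missing beyond the
  window border disqualifies, which is the conservative reading of
  "surrounded by cells of the same class";
* water and NoData cells count as "different" neighbours for edges and
  core, but water-class *records* are never emitted — water is excluded
  at the record level, not masked out of the raster.

Edge counts are integers in face units until the final multiplication by
the cell size, so TE and both LSI terms are exact; LSI ≥ 1 holds whenever
it is defined.

**Absence semantics.**  When a class is absent from a landscape, CA, NP,
TE, TCA and NDCA are genuinely zero and `apply_absence_rules()` records
them as such; LSI is undefined for an absent class and stays missing.
Downstream means and net changes honour this: zero-semantics metrics
average over all landscapes, LSI only over landscapes where it is
defined.

## Landscapes: tessellation rules

`build_grid()` tiles the raster with square windows of one extent,
anchored at the raster's top-left origin.  Two rules needed a decision
the underlying data cannot make for us:

* **Partial windows are dropped.**  Whether coastal part-windows should
  be padded, truncated or kept is genuinely open; keeping only full-sized
  windows makes landscapes of one extent strictly comparable, at the cost
  of a trailing margin.
* **All-ocean windows are removed** only when every cell is ocean (or
  NoData) in *every* year — a window that gains land in any year is
  retained.

Cropping to a region polygon keeps cells whose centres fall inside
(even-odd rule over rings, boundary counts as inside), applied
identically to every year, which makes the crop idempotent.  Continent
labels are assigned by centroid containment with ties broken by the first
polygon in input order — deterministic, if arbitrary on shared borders.

## Scaling screening

For each metric and class, `mean_metric_by_extent()` averages the metric
over all landscapes of each extent, and `fit_scaling()` fits two models
of the mean against landscape side length $L$: linear least squares, and
a power law fitted (and scored) as least squares of $\log(\text{mean})$
on $\log L$ — the $R^2$ of the power model is deliberately computed in
log space, where the fit lives.  The original screening of candidate
metrics was done by visual inspection of such curves; this package
operationalises "smooth, consistently directed" as a reproducible proxy:
a metric is *predictable* iff for every class the better of the two fits
reaches an $R^2$ threshold (default 0.98, exposed in `run_config()`) and
the fitted direction is identical across classes.  The threshold is this
package's choice, intended for sensitivity testing, not an empirical
constant.

On stationary synthetic maps the expectation of mean CA at side $L$ is
$p L^2$ for a class of frequency $p$, so the power exponent should be
2 — the package's acceptance suite verifies 2.00 with $R^2 > 0.999$ and
that LSI's best fit on the same maps is linear, matching the qualitative
behaviour reported for real global land cover.

## Change analysis

`net_change()` differences each metric per landscape between two years.
The nine-category classification crosses the sign of ΔCA with the sign of
ΔLSI (`+`, `−`, `=`), evaluated only for landscapes that contain the
class in *both* years (presence = CA > 0; a minimum-cell threshold is
available).  Because CA is an integer cell count times a constant and
both LSI terms are integers, "no change" can be exact: the CA tolerance
defaults to 0 and the LSI tolerance to 1e-9, guarding only against float
division noise.  Swapping the two years negates every delta and maps each
category to its sign-reflected partner, which the test suite checks as an
invariant.  Percentages are reported over classified (non-excluded)
landscapes, always covering all nine labels and summing to 100.
Mean ± SD summaries use the sample (n−1) standard deviation throughout.

## The synthetic generator

`generate_series()` exists so that every downstream stage can be tested
against known ground truth without downloading a global LULC product.  It
emulates the structural features the analysis relies on — a persistent
ocean/water mask, six land classes in spatially clustered patches, yearly
maps with gradual spatially autocorrelated transitions, NoData outside
the study region — using a modified-random-clusters neutral landscape
model:

1. a contiguous, edge-anchored **ocean blob** is grown (Eden growth) to
   `ocean_fraction` of the grid, so coastal landscapes and all-ocean
   window removal are exercised;
2. land cells receive a **percolation map** at `cluster_density`; its
   8-connected clusters are assigned **largest-first** to classes by
   greedy filling of the target proportions (targets scaled to the
   filled cells being distributed);
3. remaining cells take the **modal class of their assigned
   neighbours**, iterating outwards, with seeded random tie-breaks.

The default `cluster_density` of 0.35 sits safely below the 8-connected
site-percolation threshold (≈ 0.407): clusters are large enough to give
realistic aggregation but no single cluster dominates, which keeps
realized compositions within ±0.01 of their targets on 200×200 maps
(the acceptance bound is ±0.05).  Default class proportions (urban 0.02,
cropland 0.13, pasture/rangeland 0.20, forest 0.30, grass/shrubland
0.20, sparse 0.15) are round figures chosen once to resemble global land
shares.

Change is driven by four **operators** — `expand` (growth along class
boundaries), `contract` (boundary retreat), `fragment` (removal of
articulation/corridor cells, verified to raise the patch count, with a
boundary-cell fallback), and `convert` (relabelling whole smallest
patches while their cumulative size fits within the yearly cell budget;
the budget is in cells, like every other rate).  Ocean and NoData are
never modified.  A single seeded RNG stream is advanced in a documented
order (ocean, percolation, assignment tie-breaks, gap filling, then
operators by year and list position), so a scenario plus its seed fixes
the series bit-for-bit.  Every change is recorded in a truth log whose
replay reproduces each year exactly — the basis for the
parameter-recovery tests.

What the generator does *not* emulate: real geography, class-specific
transition probabilities of any particular product, classification
uncertainty, or resolution effects.  Green tests therefore demonstrate
the correctness of the machinery under known structure, not the
substantive findings one would obtain from real data.

## Problem sizes and numerical choices

The package's own verification uses deliberately modest sizes chosen to
exercise every code path: a 1000-window oracle sweep at 12×12 cells
against brute-force BFS/face-enumeration implementations; exhaustive
polyomino search up to n = 9 for the LSI denominator; scaling on ten
400×400 maps at extents 10/20/40 km; and expansion recovery on ten
100×100 maps (100 landscapes, 25 designated, 5 cells/year, 1992–2020).
Degenerate inputs are handled explicitly: absent classes (NP = 0, LSI
missing), constant means (R² defined as 1 for an exact constant fit),
all-equal side lengths (error), empty crop intersections (error), and
zero-rate operators (identity with an empty log).

## A worked example

```{r example, eval = FALSE}
sc <- lulc_scenario(
  100, 100, years = 1992:2020, seed = 1,
  operators = list(
    list(kind = "contract", source = 44L, target = 33L, rate = 25L),
    list(kind = "expand", source = 55L, rate = 20L)
  )
)
res <- run_pipeline(run_config(scenario = sc, extents_km = c(10, 20),
                               out_dir = tempfile(), seed = 1))
res$frequencies %>% filter(class == 44, extent_km == 10, n > 0)
report_figures(res$paths[["metrics"]] |> dirname())
```

## Known limitations

* No reprojection or resampling: inputs must already be equal-area and
  co-registered; raster I/O is the plain-text ASCII grid format.
* Only the six scale-predictable metrics are implemented; the engine's
  conventions are configurable but the metric set is fixed.
* Core area uses a fixed one-cell edge depth.
* No significance testing of trends, no biome/climate stratification,
  and no LULC transition matrices — the outputs are descriptive.
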