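---
title: "Meristograms: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meristograms: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meristo)
library(dplyr)
```

## The problem

Acanthocephalan worms attach to the gut wall of their host with a
retractable proboscis armed with recurved hooks arranged in longitudinal
rows. Hook size and shape vary serially along a row, and the pattern of
that variation carries taxonomic information — different species, including
morphologically cryptic ones, can show different positional profiles even
when their hooks overlap in absolute size. The difficulty is that rows
differ in hook number and worms differ in overall size (females are often
larger than males), so raw measurements cannot be compared directly.

The meristogram solves this with two standardizations and a smoothing
step, turning each collection of worms into four comparable curves.

## The algorithm

For each longitudinal row of `n` hooks, with hooks counted from the distal
end and blade `length` and `base` width measured in µm:

1. **Position standardization.** Hook `i` is placed at percent-position
   `p = i · 100 / (n + 1)`. The `+ 1` centres the points: a single hook
   sits at 50, and no hook ever reaches 0 or 100. Homologous regions of
   probosces with different hook counts now align.
2. **Derived variables.** Each hook gains a triangular area estimate
   `A = length · base / 2` (µm²) and a robustness ("stoutness") ratio
   `R = base · 100 / length`.
3. **Row standardization.** Within each row, each of the four variables
   (L, B, A, R) is expressed as a percentage of its own row maximum. This
   removes absolute size — and with it allometric and sexual size
   differences, which is why data from females and males can be pooled.
   The four maxima may sit at different hooks.
4. **Moving average.** A window of width `w` percent slides along the
   position axis in 1% steps. For every window containing at least one
   hook, one curve point is emitted: its x-coordinate is the *mean
   percent-position of the hooks in the window* (not the window midpoint),
   and its values are the means of the standardized variables. This is why
   raw meristograms have non-uniformly spaced points.
5. **Optional linear interpolation** (between smoothing and rescaling):
   the four curves are resampled by `stats::approx()` at every integer
   position inside the observed range. No extrapolation is performed.
   Besides smoothing the appearance, this puts every collection on a
   common integer grid, which is what makes multivariate comparison
   possible.
6. **Collection rescaling.** Each curve is multiplied by 100 and divided
   by its largest value, so every final curve peaks at exactly 100
   ("percent-max-collection-value").

```{r pipeline}
hooks <- synthetic_hooks(synthetic_spec(seed = 1), label = "demo")
m <- meristogram(hooks, mai = "auto", interpolate = TRUE)
m
peak_positions(m)
```

## The minimum moving-average interval (MMAI)

Every worm should contribute to every smoothing window; otherwise segment
means mix different subsets of specimens and the curves can jump. The
smallest window with that guarantee is

```
MMAI = ceiling(100 / (n_min + 1))
```

where `n_min` is the hook count of the shortest row in the collection.
With `w = MMAI`, any window lying inside the positions actually occupied
by hooks contains at least one hook from every row (window width ≥ the
position spacing of every row). `meristogram(..., mai = "auto")` resolves
to the MMAI; smaller windows are refused with the computed MMAI in the
error. A collection whose shortest row has 5 hooks has MMAI
`ceiling(100/6) = 17`; a shortest row of 9 gives 10.

In comparative work all collections must share one window, because curve
shape depends on `w`; the natural choice is the largest MMAI across the
collections (`run_compare(..., mai = "auto")`).

## Windowing conventions

The published description of the smoothing step leaves the exact window
placement open. This implementation uses half-open windows `[s, s + w)`
with left edge `s ∈ {0, 1, …, 100 − w}` — the simplest reading of a 1%
step that tiles the axis without counting a hook twice at a boundary.
Consecutive windows catching the identical hook set produce identical
points, which are collapsed; distinct windows that happen to share a mean
position are averaged (the tie rule of `approx(ties = mean)`). `w` is
restricted to integers, matching the 1% step semantics. Under a different
but equally defensible convention (closed windows, different edge set),
reported peak positions can shift by one or two position units; published
peak values should therefore be compared with a ±2-unit allowance.

All arithmetic is double precision; nothing is rounded before output
formatting (the CSV writer uses 6 significant digits).

## Area-formula validation

The triangular approximation `A = length · base / 2` is validated by
ordinary least squares with the estimate as response and the digitized
area as predictor, so the fitted line reads
`estimated = slope · measured + intercept` and a slope above 1 means the
formula over-estimates. `area_regression()` reports slope, intercept and
R² (the squared Pearson correlation, printed to 3 decimals). At least 3
records and non-degenerate predictor variance are required. Since the
meristogram standardizes areas within rows, the formula only needs to be
*proportional* to the true area for the curves to be correct; the
regression quantifies how close it comes in absolute terms.

## Comparative pipeline

`feature_matrix()` concatenates interpolated meristograms computed at a
common MAI into a collections × features matrix, the features being the
four variables at each integer position of the *intersection* of the
collections' position grids (how to align mismatched ranges is not fixed
by the published analysis; intersection is this package's choice — it
uses only positions observed in every collection, at the cost of
discarding curve tails).

`meristogram_pca()` performs covariance PCA: columns are mean-centred but
not variance-scaled, since all features already share the percent scale —
scaling would up-weight near-constant positions. Component signs are
fixed (largest-magnitude loading positive) for reproducibility.
`cluster_collections()` then applies UPGMA to the first two component
scores — two components capture the dominant curve contrasts while
keeping the phenetic distances interpretable; more can be requested via
`components`.

Four distance metrics are supported: Euclidean, Manhattan, maximum
(Chebyshev) and Minkowski. The Minkowski exponent defaults to `p = 3`:
`p = 2` would duplicate Euclidean, and the exponent used in the original
analysis is unpublished. Agreement between the dendrograms produced by
different metrics is evidence that the clusters are robust.

The UPGMA agglomeration is implemented in the package (average linkage
weighted by cluster size, node height = half the merge distance) with a
deterministic tie rule — among equally distant pairs, the pair whose
alphabetically first leaves are lexicographically smallest is merged
first. `stats::hclust(method = "average")` computes the same linkage but
leaves tie order unspecified; the test suite uses it, plus a brute-force
agglomerator, as independent cross-checks. Trees are `ape::phylo` objects
and export to Newick.

```{r compare}
cols <- lapply(1:4, function(i)
  synthetic_hooks(synthetic_spec(length_peak = 0.15 + 0.1 * i, seed = i),
                  label = paste0("taxon", i)))
names(cols) <- paste0("taxon", 1:4)
res <- run_compare(cols, mai = "auto", metric = "euclidean")
glance(res$pca)
```

## The synthetic-data generator

`synthetic_spec()` / `synthetic_hooks()` emulate a collection of worms
whose hook dimensions follow smooth unimodal positional trends:

* trend family: a beta-like bump over a positive floor,
  `f(u) = scale · (floor + (1 − floor) · (u/m)^(mk) ((1−u)/(1−m))^((1−m)k))`,
  parameterized directly by its peak location `m` — unimodal, strictly
  positive, closed-form argmax;
* defaults: blade length peaking at 30% of the row and base width at 60%
  (longest hooks distal, broadest bases proximal of mid-row, the pattern
  typical of *Echinorhynchus*), trend maxima 70 µm and 25 µm, floor 0.5
  (shortest hooks about half the longest, inside the observed 42–82%
  range), concentration 4, rows of 8–12 hooks, 10 worms;
* a per-row lognormal allometry factor (sd 0.15 on the log scale)
  multiplying both variables, emulating between-worm size variation —
  annihilated exactly by row standardization;
* multiplicative lognormal measurement noise (sd 0.03 ≈ 3%), chosen
  because measurement error scales with hook size and positivity must be
  preserved.

`recovery_experiment()` measures how closely the full pipeline relocates
the known trend peaks. Two caveats delimit what passing tests show. First,
peak recovery is limited by the position grid the data offer: if every row
has the same hook count `n`, hooks only occupy multiples of `100/(n+1)`,
and a trend peak midway between two of them cannot be located more
precisely than the ~`50/(n+1)` offset to the nearest sample (for `n = 10`,
up to ~4.5 units) — no smoothing convention can beat that resolution. With
the default mixed row lengths the grids interleave and the noiseless
median error is ≤ 1 unit (max ≈ 2). Second, the generator produces
independent rows with stationary trends and i.i.d. noise; real collections
add host, geographic and preparation effects, so passing recovery tests
demonstrates correctness of the algorithm, not field performance.

```{r recovery}
rec <- recovery_experiment(synthetic_spec(n_rows = 20, noise_sd = 0,
                                          seed = 11),
                           w = "auto", replicates = 5)
rec |> group_by(variable) |> summarise(median_error = median(abs_error))
```

## Degenerate inputs and edge rules

* Rows with fewer than 3 hooks are accepted with a warning (the algorithm
  is defined for any `n ≥ 1`, but smoothing such rows is weak).
* Duplicate `(specimen, hook)` pairs in one file are a hard error — a
  silent last-wins rule would corrupt row maxima.
* Peak ties are reported at the smallest (most distal) position, so flat
  curves and shared maxima resolve deterministically.
* Interpolation requires two distinct x values; single-point curve sets
  are refused with a pointer to disable interpolation.
* Identical collections give a zero-variance feature matrix; clustering
  is refused rather than returning an arbitrary tree.
* Dimorphism panels use MMAI, 1.5×MMAI and 2×MMAI rounded half *up*
  (17 → 17, 26, 34).

## Problem sizes

The test suite and the acceptance script work on generated collections of
5–20 worms with 3–25 hooks per row, feature matrices of up to nine
collections, and UPGMA problems of up to nine leaves — the scale of the
published *Echinorhynchus* analyses they emulate; every check runs in
seconds.

## Limitations

* Sexes and surfaces are pooled or split by the caller; no automatic
  stratification.
* Only the defined moving average is offered for smoothing, and only
  linear interpolation for resampling; no extrapolated tails.
* The deposited hook-measurement files of the original study are not
  redistributed; data-dependent checks in the test suite activate when
  those CSVs are placed under `inst/extdata/supplementary/`.
* No bootstrap support on dendrograms; clustering is phenetic, not a
  phylogenetic inference.
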