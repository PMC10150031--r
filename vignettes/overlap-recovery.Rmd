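---
title: "Recovering hidden overlap area between elongated objects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering hidden overlap area between elongated objects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shredcot)
```

## The model

When one elongated object partially covers another, the covered object's
visible instance mask splits into fragments and its pixel area misses
the hidden stretch. `shredcot` models that hidden stretch purely
geometrically. The assumptions are:

* the occluded object is *ribbon-like*: locally straight, of slowly
  varying width, so the corridor between its two visible fragments is
  well approximated by a straight-sided band;
* the width of the ribbon where it disappears under the coverer is
  captured by the maximum inscribed circle of each fragment — for an
  elongated fragment this circle's diameter is the local ribbon width;
* the hidden region lies inside the covering instance, so intersecting
  the fitted band with the coverer's mask cannot count pixels that are
  visible elsewhere (instance masks are pairwise disjoint by
  construction, which also rules out double counting of the occluded
  object's own visible pixels).

The fitted band is the quadrilateral bounded by the two common external
tangent lines of the two inscribed circles, closed by the chords through
the tangent points on each circle. With `u` the unit vector between the
circle centers, distance `d` apart and radii `r1`, `r2`, the tangent
normals solve `n · u = (r2 − r1) / d`, which exists exactly when
`d > |r1 − r2|`. Closing with chords (rather than circular arcs) keeps
the fitted region a simple convex polygon; the area difference against
arc closure is below one ribbon-width squared and is partially absorbed
by the final intersection with the coverer.

Two ratios track recovery quality for a sample with true areas `Area_1`,
`Area_2`, visible composite area `AD` and recovered hidden area `CD`:
`AAR = AD / (Area_1 + Area_2)` and `CAR = (AD + CD) / (Area_1 +
Area_2)`. `CAR` is not clipped at 1: over-recovery is information, and
the summary's *negative optimization* count — samples with
`|CAR − 1| > |AAR − 1|` — makes it visible. The phrase is formalized
here as that inequality; an over-recovered sample whose `CAR` stays
closer to 1 than its `AAR` was is still an improvement.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `min_blob_px` | `extract_foreground()` | 25 px | removes sensor speckle after thresholding without deleting thin ribbon tips; at the package's working resolutions a genuine object fragment is larger |
| `pad` | `crop_to_object()` | 10 px | context margin kept around the enclosing circle so downstream segmentation sees the full contour |
| `width_range` | `generator_config()` | 14–24 px | ribbon widths, chosen so fragments comfortably contain an inscribed circle on a 192×192 canvas while staying thin relative to their length, the regime the geometry assumes |
| `curvature` | `generator_config()` | 25 px | perpendicular spread of the spine's middle control point; moderate bending, so ribbons are curved but not hairpins |
| `min_fragments` | `generator_config()` | 2 | an inter-overlapped sample must split the covered ribbon's visible mask |
| `adhesion_max_frac` | `generator_config()` | 0.05 | "touching" samples may share at most 5% of the smaller ribbon's area |

Thresholding in `extract_foreground()` is Otsu's method on luminance
(`0.299 R + 0.587 G + 0.114 B`) over 256 levels, with the brighter side
taken as foreground — parameter-free and checkable against an
exhaustive between-class-variance scan, which the test suite does. The
binarization method and crop padding are not dictated by the problem;
both are exposed as arguments.

## What the synthetic generator emulates — and what it does not

`make_overlapped_sample()` draws two quadratic-Bezier ribbons. For the
default inter-overlapped type, the second ribbon crosses the first at
90° ± 30°, the first is composited on top, and the sample is accepted
only if the covered ribbon's visible mask splits into at least
`min_fragments` components with a non-trivial second fragment
(≥ 25 px). Adhesion samples are built by sliding a parallel ribbon one
pixel at a time until first contact; separated samples place the two
ribbons in opposite half-canvases. Every sample carries its amodal
masks, so `Area_1`, `Area_2` and the true overlap are known exactly, and
the bookkeeping identity `(AD + true overlap) / (Area_1 + Area_2) = 1`
holds on every sample — the test suite asserts it.

The generator reproduces the *geometry* of overlapped ribbons, not their
photometry: no texture, no color differences between varieties, no
illumination gradients, no boundary noise from a real segmentation
network. Passing benchmarks therefore demonstrate that the
reconstruction is sound when given clean masks; they do not bound the
additional error contributed by imperfect upstream segmentation.
Three-way stacking and self-winding objects are out of scope — the
pipeline explicitly assumes one coverer and one covered object.

Ribbons are rasterized by thresholding a 2× supersampled Euclidean
distance transform of the spine at `width / 2`, so spines at half-pixel
positions render even widths symmetrically; a straight width-20 ribbon
is exactly 20 pixels across and the canonical perpendicular 20×20
crossing hides exactly 400 px.

## Numerical choices

* **Distance transforms** are exact Euclidean (`EBImage::distmap`); the
  image border is *not* treated as background, matching the definition
  of the inscribed radius as distance to the nearest background pixel.
* **Connectivity** is 8-connected throughout (a 4-connected labelling
  pass plus a union-find merge of diagonal adjacencies): thin diagonal
  necks must not split an instance spuriously.
* **Tie-breaks**: the distance-transform arg-max takes the smallest row,
  then the smallest column; components of equal area are ordered by
  their top-left-most pixel. Both make every result deterministic.
* **Polygon rasterization** uses the boundary-inclusive even–odd rule on
  integer pixel centers; zero-area polygons rasterize empty.
* **Degenerate tangents** (`d ≤ |r1 − r2|`, one circle inside the
  other's span): the fitted region falls back to the convex hull of the
  two fragments — always defined and conservative. For genuine disjoint
  fragments this is nearly unreachable (an inscribed circle contains
  only its own fragment's pixels), but mask noise can produce it.
* **Welzl's algorithm** computes the minimum enclosing circle on the
  convex hull of the foreground pixel set, with a deterministic
  pseudo-shuffle; support-point tolerance is `1e-10` relative.
* **Rounding** of printed ratios is half-up (`round_half_up()`), not
  banker's, to match conventional table formatting; summaries are
  computed on raw values and rounded only for display.
* **Seeding**: every stochastic entry point takes an explicit seed;
  per-sample streams are keyed by `(seed, index)` so sample `i` is
  identical regardless of how many samples are drawn. The global RNG
  state is saved and restored around generator calls.

## Design choices where the design was open

* *Inscribed-circle fitting*: the fragment-width circle is implemented
  as the **maximum** inscribed circle via the distance-transform
  arg-max — the standard idiom; a literally smallest inscribed circle
  would be a point.
* *Fragment selection*: the two largest components by area. With more
  than two fragments (rare for a single coverer) the smaller ones are
  ignored; their hidden continuations are not modeled.
* *Contested pixels in polygon annotations*: the first-listed polygon
  wins. Annotators draw the covering object first, and a deterministic
  rule guarantees the disjointness invariant that the rest of the
  pipeline relies on.
* *Both instances occluded*: each is fitted against the other and the
  recovered areas are summed, with a warning — the configuration
  violates the one-coverer assumption, and results should be treated
  accordingly.
* *Anchor parameterization*: `ratio = height / width` with
  `width = size / √ratio`, so every anchor's area is exactly `size²`.
  The improved set (sizes 32–256, ratios 0.5–2, 16 per position) is
  aimed at small elongated objects; the legacy set (128–512 × 3 ratios,
  9 per position) cannot cover a 40×40 box at IoU 0.5 at all, which
  `anchor_coverage()` demonstrates.
* *Fusion topology*: to keep the emitted graph acyclic, the top-down
  pyramid intermediates are exposed as named levels `M2`–`M5`; each
  output `Pk` (k = 3..6) then fuses its top-down intermediate with a
  stride-2 bottom-up edge from `P(k−1)`, and `P3` additionally takes a
  3×3 lateral from `C3` (configurable to include `C2`). In the plain
  FPN variant `P6` is a stride-2 pool of `P5`, tagged
  `downsample-pool2` to keep it distinct from the learned bottom-up
  convolutions.

## Problem sizes used by the test suite

The shipped tests validate the inscribed-circle fit against an
exhaustive nearest-background search on 50 random blobs of 24–56 px,
tangency residuals on 1000 random circle pairs (`< 1e-6`), the minimum
enclosing circle against an O(n³) support-point oracle on point sets of
up to 60, and the end-to-end recovery on a 100-sample seeded benchmark
at 192×192 — sizes at which the oracles are exact and the full suite
runs in well under a minute, chosen as the package's own verification
scale.

## Known limitations

* The band model under-performs when the occluded ribbon bends sharply
  *under* the coverer: the straight corridor misses the bent portion.
* Fragments thinner than ~3 px yield unstable inscribed circles; the
  generator's acceptance rules avoid them, real masks may not.
* Only two-instance samples are processed; ≥3-way stacks are refused by
  design rather than mis-handled.
* `AD` is taken from the visible masks as given; segmentation errors
  upstream propagate directly into `AAR` and `CAR`.
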