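---
title: "Brush-driven MART: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brush-driven MART: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctbrush)
```

## The acquisition model

`ctbrush` simulates selective-ray computed tomography: instead of acquiring a
complete, regular set of projections, an agent (a human player or a scripted
strategy) moves a *CT brush* — a star of `R` views equally spaced over
[0°, 180°), all passing through one central point — across a hidden image,
and only the rays the star sweeps over are ever measured. The hidden image
plays the role of the patient cross-section; its raysums are
*pseudoprojections*, computed from an already digitized grid rather than
physical measurements.

Three conventions fix everything else:

* **Coordinates.** Pixels are 0-based `(row, col)` with rows indexing
  downward; angles are degrees measured clockwise from horizontal, so 0° runs
  along a row and 90° down a column. A ray and its 180° opposite are the
  same line, so all angles are reduced to [0°, 180°).
* **Rasterization.** A ray is a binary *staircase*: a midpoint
  (Bresenham-style) trace stepping once per pixel along the dominant axis,
  minor coordinate rounded half-up. No anti-aliasing, no per-pixel weights:
  every covered pixel contributes with weight 1 to the raysum. The chain is
  8-connected and runs edge to edge.
* **Ray identity.** Two rays are *the same ray* exactly when they are the
  same geometric line. The canonical key quantises the view angle (10⁻⁷
  degree) and the line's perpendicular offset from the origin (10⁻⁹ pixel),
  making the key invariant under traversal reversal and anchor changes.
  Identity is deliberately **not** the rasterized pixel set: staircase
  truncation maps many nearby parallel lines onto one pixel chain, and the
  dose accounting counts those as distinct rays. This is what makes the
  closed form `T = R·N² − N(N−1)` exact for all-pixel star coverage — on the
  4×4 grid with views {0°, 36°, 72°, 108°, 144°}, the count is 4 rows plus
  16 lines per irrational-tangent view, 68 in total, which pixel-set
  deduplication could never reach (it gives 58 under the same rasterizer).
  The practical consequence is conservative: dose is never under-counted.

The quantisation tolerances matter only for rational-tangent views (0°, 45°,
90°, 135°), where distinct anchors produce offsets equal up to floating
error; 10⁻⁹ pixel collapses those while keeping genuinely different lines
(separated by at least ~`1/N` pixel offsets for realistic angle sets) apart.

## MART and its invariants

Reconstruction is the multiplicative ART: from `A0 ≡ 1`, each ray with
measured raysum `S` rescales its pixels by `S / S_i`. The engine preserves,
and the test suite asserts, the classical properties: estimates stay
non-negative; immediately after an update the ray's raysum equals `S` to
1 part in 10⁹; a zero raysum zeroes its pixels permanently (hence the
all-ones, zero-free start); pixels no measured ray crosses keep their
initial value; and *refine* — one pass of updates over all registered rays,
in insertion order — never touches the registry, so dose is invariant under
refinement.

Numerical choices, where the underlying procedure leaves them open:

* **Division guard.** `S_i = 0` with `S > 0` cannot arise from the all-ones
  start, but user-supplied estimates can produce it; the update is skipped
  and counted rather than dividing by zero. Relative residuals use
  `|S_i − S| / max(S, 1e-12)`.
* **Convergence.** `refine_to_convergence()` stops when the per-pass maximum
  relative residual falls below `tol` (default `1e-6`) or after `max_passes`
  (default 200), reporting which. Consistent systems (raysums measured from
  a real hidden image) have an exact solution; how fast refinement reaches
  it depends strongly on coverage. All-pixel star coverage of a smooth
  64×64 phantom converges in a handful of passes, while sparse coverage or
  small bright structures can need thousands; the defaults are a pragmatic
  interactive budget, not a guarantee, and the uniform-image fixed point is
  only approached to ~10⁻³ at the default tolerance (the test suite
  tightens `tol` where it asserts the fixed point).
* **Refine order** is registry insertion order. Orderings that interleave
  near-perpendicular rays converge faster, but reproducing the recorded
  processing order exactly — replay determinism — was judged more valuable
  for a telemetry-driven engine.

`full_view_reconstruction()` emulates classical equally spaced-view MART by
looping the star over every pixel (row-major), deduplicating rays by line
identity, then refining to convergence. It runs in compiled code and caches
every ray's pixel chain (about 1.6 GB at most; beyond that it transparently
re-traces each pass). A small-grid test pins the compiled path to the
R-level registry path to within accumulation order (~10⁻¹⁶).

## Star geometry and width

For `width > 1` each view contributes `width` parallel rays at integer
perpendicular offsets centred on the central point (odd widths symmetric,
even widths biased one step positive), with offset anchors rounded to pixel
positions and off-grid rays dropped. The bundle members are genuinely
separate rays — dose scales with both `R` and `width` before deduplication.
Where bundled rays coincide with already-measured lines they add no dose:
dose is unique rays, period.

## The level generator

A level's hidden image contains circles and right-isosceles, axis-aligned
triangles, each either *full-tone* or *half-tone* (the tumor gray); the
level's answer is its number of gray circles. The printed rules are followed
with integer (floor) division and `random(k)` uniform on `[0, k)`:

* canvas: each dimension independently `256 + 128·k`, `k` uniform on
  `{0, …, ⌊level/5⌋}`;
* shape count: `⌊mindim/64⌋ + random(⌊mindim/11⌋ − ⌊mindim/64⌋)`;
* inversion: never below level 8; always when the level ends in digit 8
  (the digit rule wins over the random rule when both apply); otherwise
  with probability 1/6 past level 8.

Values the rules leave open were fixed once: tones are 0 (background), 1
(full-tone), 0.5 (half-tone), swapped background/full-tone when inverted;
shape size is uniform on `[mindim/32, mindim/8]` ("proportional to the
canvas"); triangles' legs extend toward +x and +y from the recorded corner;
overlaps are allowed and painted in draw order. The answer counts all gray
circles drawn, so a guard redraws the shape set until at least one gray
circle exists and none is fully occluded — keeping the answer well defined
without biasing sizes or positions. Level numbers are unbounded positive
integers.

The generator emulates the *structure* of the game's levels — tones,
shapes, difficulty scaling — not the textures, noise, beam hardening or
anatomy of real CT slices. Tests passing on these phantoms demonstrate the
engine's bookkeeping and convergence behavior, not clinical detectability;
user-supplied PGM/PNG slices can stand in for real data.

## Sessions, interpolation and replay

Mouse sampling is irrelevant headless, so a stroke is an explicit list of
sample points; consecutive samples are joined by linear interpolation
stepping once per dominant-axis increment (the same midpoint rounding as the
rasterizer), giving a connected path of central points. Every *irradiated*
central point is logged as one `m()` record — the log is the complete
sequence of star placements, not the sparse mouse samples. Replay therefore
re-stamps each logged point without re-interpolating (interpolating between
log records would bridge separate strokes, which the grammar cannot
delimit), and `(seed, log)` reproduces dose and estimate bit for bit.

Progression: a correct guess advances one level, a wrong one demotes one
level (floored at 1) — the demotion magnitude is this engine's choice.
Brush bounds are 1–180 rays (180 is the hard maximum, one view per degree)
and width 1–9 (no stated maximum; 9 keeps even the widest bundle small
against a 256-pixel canvas). Phantoms are regenerated from sub-seeds derived
from `(master seed, level, visit)`, so replays are stable and revisiting a
level after demotion yields a fresh draw per visit. The tracking grammar
lacks an inversion flag, so replay regenerates the phantom from the seed and
cross-checks the logged shape list, failing loudly on mismatch.

Session and reconstruction state are environment-backed objects with
reference semantics — play operations mutate in place and return flags or
the state for chaining — which keeps long strokes linear-time instead of
copying the registry per ray.

## Dose formulas

`n_theta()` evaluates the parallel-ray count across an N×N square as
`N(|cos θ| + |sin θ|)`, algebraically identical to `N(1 + |tan θ|)|cos θ|`
but finite at 90°; it is symmetric about 45° and bounded by `N` and `N√2`.
`emitted_dose_E()` sums a per-view rounding of `n_theta` over the views; the
default, per-view **ceiling**, reproduces the tabulated 5-view (1,618) and
9-view (2,930) totals for N = 256 exactly. No single simple rounding
reproduces the remaining tabulated entries (computed values are 1 to ~100
below them); the rounding rule is therefore a parameter, the two matching
rows are the only asserted ones, and the discrepancy is documented rather
than chased.

## Scripted players

A strategy is a function from the play-facing view (estimate, dose, brush,
dims — never hidden pixels) to the next action. The built-in `grid-sweep`
drags the brush along every `step`-th row and `random-walk` plays a few
random strokes; both then refine and guess via a crude gray-blob counter.
They exist to exercise the session layer and to report dose ratios between
exhaustive and sparing play; neither is a serious detection strategy, and
the engine asserts nothing about human-play dose factors.

## Problem sizes in the test suite

The suite's empirical checks use 64×64 phantoms for convergence, a seeded
128×128 phantom for the view-count sweep {5, 6, 9, 18, 36, 72} (relative L2
error against the hidden image, non-increasing in views; gray-circle
interiors recovered to within 10 % of 0.5 at 72 views), 10⁴ draws per
canvas size for generator bounds, 6×10⁴ draws for the inversion rate, and
10⁴ random event lists for the tracking-grammar round trip. These sizes were
chosen as the smallest that exercise the claims convincingly.

## Known limitations

Only parallel-beam stars are built (the mask formalism would admit fan or
cone beams); no limited-angle ranges; no brush rotation from the session
layer (the grammar records it, always 0); no additive-ART/SIRT/SART
variants; no compressive-sensing solver; no point-spread-function
deconvolution; file-based logs only (no live socket telemetry). Convergence
below `tol` within the pass cap is not guaranteed for sparse ray sets — the
engine reports rather than hides this.
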