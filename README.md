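# ctbrush

Headless R engine for **brush-driven sparse-view computed tomography**.

In conventional CT the scanner sprays X-rays across the whole patient and an
algorithm reconstructs the image from the complete projection set. `ctbrush`
implements the opposite acquisition model: a **CT brush** — a "star" of `R`
equally spaced rays all passing through one movable *central point* — is
stroked over a hidden image, and only the rays the brush touches are ever
measured. Each geometrically distinct ray is measured exactly once
(re-selecting it adds no information and no dose), so the **emitted dose is
the number of unique rays**, and the question the engine exists to study is
how much image quality a given ray budget buys. The package is aimed at
people experimenting with object-dependent ray-selection strategies for dose
reduction: it provides the reconstruction core, closed-form dose accounting,
a procedural phantom generator with difficulty levels, scripted headless
gameplay, a bit-exact telemetry-log format, and a CLI.

## The model

The hidden image `U(i,j)` is probed through binary staircase rays: a ray at
angle θ through an anchor pixel is rasterized as a midpoint (Bresenham-style)
8-connected pixel chain, and its **raysum** is the unweighted sum of `U` over
those pixels (a pseudoprojection). Reconstruction is the multiplicative
algebraic reconstruction technique (**MART**): starting from an all-ones
estimate `A0 ≡ 1`, each newly measured ray with raysum `S` rescales the
pixels it covers,

    A_{i+1} = A_i * S / S_i        (on the ray's pixels; S_i = current raysum)

so the ray's constraint holds exactly after its update. A **refine** pass
re-applies every measured ray in insertion order and costs no dose. A zero
raysum zeroes its pixels forever, which is why the start must not contain
zeros.

Dose accounting uses the closed forms for stars placed at *every* pixel of an
N×N grid: the unique-ray total

    T = R·N² − N(N−1)    (with the 0° view, whose rational tangent makes its
                          N² placements collapse to N rows; T = R·N² without it)

and the equally-spaced-parallel-ray emitted dose

    N_θ = N(|cos θ| + |sin θ|),    E = Σ_views ⌈N_θ⌉ .

Ray identity is the *geometric line* (view angle + perpendicular offset),
not the truncated staircase — staircase truncation makes many distinct rays
share a pixel set, and the dose bookkeeping deliberately does not merge
them; that convention is what makes `T` exact.

## Worked example

```r
library(ctbrush)

# the canonical 4x4 example: 5-view stars (0, 36, 72, 108, 144 degrees)
# through all 16 pixels
centers <- as.matrix(expand.grid(0:3, 0:3))
count_unique_rays(c(4, 4), c(0, 36, 72, 108, 144), centers)
#> [1] 68

# dose table for a 256x256 image, compared with a 2,126-ray manual play
cmd_dose_table(256, c(5, 9, 180), manual_rays = 2126)
#>     R angle_deg        T     E      pct_T      pct_E
#> 1   5        36   262400  1618 0.81021341 131.396786
#> 2   9        20   524544  2930 0.40530442  72.559727
#> 3 180         1 11731200 58770 0.01812261   3.617492

# play a level headlessly
ses <- new_session(seed = 7, n_rays = 5)
stroke(ses, rbind(c(100, 40), c(100, 200)))   # drag along row 100
refine_action(ses)
dose_report(ses)
#> <ct_dose_report> 645 unique rays over 1 strokes (brush 5 x 1)
#>   all-pixel references at R=5, N=256: T=262,400 (0.246%), E=1,618 (39.9%)
```

The `68` is the unique-ray count of the worked 4×4 example: 4 distinct rows
from the 0° view plus 16 distinct lines for each of the four
irrational-tangent views (`T = 5·16 − 4·3 = 68`). In the dose table, `T` is
the ceiling any play can reach with that brush, and `pct_T` says the manual
play used 0.81 % of the 5-view ceiling. In the session, one straight drag at
5 views costs 645 unique rays — the dose readout a player would minimize.

`full_view_reconstruction(hidden, n_views)` emulates classical equally
spaced-view MART by looping the star over every pixel and refining to
convergence; `line_profile()` extracts the horizontal profiles used to
compare reconstructions against the hidden image.

A thin launcher is installed at `exec/ctbrush`:

```sh
ctbrush dose-table --N 256 --manual 2126 --out dose.csv
ctbrush gen-phantom --level 3 --seed 11 --out phantom.pgm
ctbrush reconstruct --in phantom.pgm --views 18 --out recon.pgm --profile-row 145
ctbrush play --strategy random-walk --seed 5 --track run.cttrack
ctbrush replay --track run.cttrack --seed 5
```

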