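---
title: "How octcyst decides whether a B-scan is cystic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How octcyst decides whether a B-scan is cystic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octcyst)
```

## The problem

Fluid-filled regions (cysts) between retinal layers are a key manifestation
of diabetic macular edema and related diseases. For triage — deciding
*which* B-scans an ophthalmologist should look at — a full cyst
segmentation is unnecessary and slow. `octcyst` answers the simpler
question *does this B-scan contain a cyst?* with a purely rule-based
analysis of local intensity changes, with no layer segmentation and no
training data.

A cyst appears as a dark region inside brighter tissue. Reading a column of
the image downward, the top boundary of a cyst is a **light-to-dark
vertical transition**; its upper-left and upper-right arcs are
**light-to-dark diagonal transitions**. The detector looks for pixels where
a significant vertical transition co-occurs with many nearby significant
diagonal transitions — a configuration typical of a dark blob's upper
boundary and rare elsewhere.

## Phase 1 — denoising

OCT images carry multiplicative speckle noise. Intensities are first
passed through a small median filter (`denoise_median()`, default
`median_kernel = 3`, edges handled by reflection). The detector only
consumes $3\times3$ neighborhood means and their differences, so it is
deliberately insensitive to the choice of denoiser; 3 is the minimal
speckle-suppressing window and larger kernels mainly cost edge sharpness.

## Phase 2 — boundary pixel determination

Let $X_{i,j}$ be the intensity at row $i$, column $j$ (1-based, row index
increasing downward), and let

$$A^{a,b}_{i,j} = \frac{\sum_{q=j-b}^{j+b}\sum_{p=i-a}^{i+a} X_{p,q}}{(2a+1)(2b+1)}$$

be the windowed mean (`mean_map()`, defaults $a=b=1$). Four directional
difference maps are derived (`diff_maps()`):

* $dv_{i,j} = A_{i-1,j} - A_{i+1,j}$ — vertical change,
* $dl_{i,j} = A_{i-1,j-1} - A_{i+1,j+1}$ — down-right diagonal change,
* $dr_{i,j} = A_{i-1,j+1} - A_{i+1,j-1}$ — down-left diagonal change,
* $df_{i,j} = A_{i+2,j} - A_{i-2,j}$ — offset-2 vertical change (phase 3).

All maps are `NA` wherever an operand would fall outside the image. The
border is *not* padded: padding would fabricate intensity transitions at
the image edges and those transitions would be indistinguishable from real
ones downstream.

Seed pixels (`find_vertical_seeds()`) are the set $V$: strict vertical
local maxima of $dv$ with $dv > 0$ (brighter above than below — the
entrance point of a possible cyst) and $|dv| > thv$. The sets $L$ and $R$
(`find_diagonal_sets()`) are the analogous strict local maxima of $dl$ and
$dr$ along their own diagonals, positive and above $thv$. Local maxima are
strict (`>`), so exactly tied plateaus yield no maximum; on real, noisy
data exact ties are measure-zero, and the convention is documented so
users understand that perfectly flat synthetic edges are invisible to the
seed detector.

For every seed, two patches of $s$ rows and $t$ columns are formed
(`detect_candidates()`, defaults $s = t = 11$): the left patch covers the
$t$ columns immediately left of the seed column, the right patch the $t$
columns immediately right, both vertically centred on the seed row (for
even $s$ the extra row falls below; the seed's own column is excluded,
since the diagonal transitions of a blob's arc flank the entrance point).
A patch is *accepted* when it contains strictly more than `num` pixels of
$L$ (left patch) or $R$ (right patch); `num = 10` by default, so every
accepted patch certifies at least 11 diagonal-transition member pixels
plus the seed. Patches at the image border are clipped and the count is
still compared against the unchanged `num` — discarding clipped patches
would blind the detector near the edges, and users who prefer that
strictness can raise `num`.

### The significance threshold `thv`

`thv` separates *cyst-boundary* transitions from ordinary *inter-layer*
transitions, so its useful range is bracketed by two contrasts: the step
from mid-retinal tissue into fluid (large — fluid is among the darkest
structures in the scan) and the steps between adjacent tissue bands
(moderate). For a sharp step of contrast $C$ seen through the $3\times3$
mean, the peak of $dv$ is about $\tfrac{2}{3}C$, so a threshold around one
quarter of the image's dynamic range sits above typical band-to-band steps
and below tissue-to-fluid steps. The default is therefore **relative**:
`thv = 0.25 ×` (intensity range of the denoised image), which keeps the
operating point stable across acquisition brightness; an absolute `thv`
(on the fixed `[0, 255]` scale) can be given instead, and the sweep
harness (`sweep_params()`) is the intended calibration tool for other
scanners or presets. Note the patch-voting stage makes the detector
forgiving of a slightly-low `thv`: isolated noise exceedances do not
cluster into 11 members of one patch.

## Phase 3 — shadow columns

Blood vessels in the inner retina cast dark vertical shadows that
attenuate everything beneath them, including the bright outer band
(retinal pigment epithelium, RPE). The *top* edge of such an attenuated
region is a light-to-dark transition with exactly the signature of phase 2
— the main source of false positives. Instead of segmenting layers, the
method tracks, per column, the **bottom-most significant dark-to-light
transition into a bright region** (`column_transition()`):

1. Sort the column's $A$ values descending; let $m_{th}$ be the minimum of
   the top $\lfloor \alpha m \rfloor$ values ($\alpha = 0.08$ by default;
   the floor is clamped to $\ge 1$ so the count is always a positive
   integer). Ties in the sort are irrelevant — only the order statistic is
   used. $m_{th}$ is computed per column, matching the per-column loop of
   the procedure.
2. Find the largest row $i$ with: $|df|$ a local maximum along the column,
   $df_{i,j} < 0$ (brighter above, darker below — read bottom-up, a
   dark-to-light transition), and $A_{i-2,j} \ge m_{th}$ (the region
   entered is genuinely bright). That row is $Q_j$; if no row qualifies,
   $Q_j$ is absent.

Two numerical choices here deserve a note. First, the local-maximum test
on $df$ is applied to $|df|$ — significance of the transition is carried
by the magnitude, and a literal local maximum of the (negative) signed
$df$ would select the *weakest* transitions. Second, this test is
**non-strict** (`>=`): an ideal step edge produces an exact two-sample
plateau in $|df|$, and a strict test would reject both samples, making
noise-free images undetectable on principle. With the non-strict test the
bottom-most plateau row is selected, deterministically.

In an unshadowed column, $Q_j$ sits at the lower edge of the RPE band —
the deepest transition out of a region bright enough to clear $m_{th}$.
Under a vessel shadow the attenuated RPE no longer clears the cutoff and
$Q_j$ jumps to a much higher structure (or disappears). The decision rule
(`detect_shadow_columns()`) therefore places a *boundary* between
consecutive columns whose $Q$ differ by more than `jump_thr` rows (or
where $Q$ is present on one side only). Boundaries partition the columns
into runs, and a run is flagged as shadow when the median of its $Q$
values deviates from the global median $Q$ by more than `jump_thr`, or
when the run has no transitions at all but is delimited by a boundary (a
shadow deep enough to kill the transition outright). Flagging whole runs,
not just the jump positions, reflects that a shadow is a *region* of
consecutive columns between an entry and an exit jump; using the global
median as the reference assumes shadows cover a minority of columns,
which holds for vessel shadows. `jump_thr` defaults to
`max(10, ceil(0.05 m))` rows: a true shadow displaces the transition by a
large fraction of the retinal thickness, while the unshadowed $Q$ varies
by a row or two, so the two scales are well separated and the default
adapts to image height. Absolute row change is used when comparing
consecutive columns (the displacement direction at an exit jump mirrors
the entry jump).

Finally (`remove_near_shadow()`), every candidate whose seed column lies
within `shadow_margin` columns of a flagged column is discarded.
`shadow_margin` defaults to `t`, the patch width: any candidate whose
patch could overlap a shadow column is suspect. The scan is labelled
**cystic** when at least `min_candidates` candidates survive (default 1 —
a single accepted patch already certifies `num + 1` boundary pixels;
raise it for a more conservative reading).

## The phantom generator

`generate_phantom()` renders synthetic B-scans with known ground truth so
that every stage is testable without clinical data. The standard preset
(`dme_phantom_spec()`, 100 × 256) emulates, top to bottom: dark vitreous
(intensity 30), a bright inner band (180, rows 20–28), mid retinal tissue
(120, rows 29–70), the bright RPE band (200, rows 71–80), a moderately
bright choroid (140, rows 81–90), and a linear posterior roll-off back to
30 (rows 91–100). The choroid plateau and gradual roll-off matter: real
B-scans do not end in a hard bright-to-black edge below the RPE — signal
decays through the choroid — so the RPE's lower boundary is a *moderate*
step (contrast 60) followed by a slow ramp, and the only strong
light-to-dark step in a healthy phantom column is nowhere. A phantom that
instead dropped straight from 200 to 30 would put a cyst-grade transition
across the full width of every image, which no real healthy scan exhibits.

Cysts are dark ellipses (preset: centre (50, 128), semi-axes 10 × 24,
interior 35) overwriting the tissue band; the ground-truth mask covers
exactly the discrete ellipse interior. Shadows multiply all intensities in
a column range, from just below the inner bright band (row 29) downward,
by an attenuation factor (preset 0.2) — mimicking beam attenuation beneath
a vessel sitting in the inner retina. Speckle is approximated by
multiplicative Gaussian noise, `pixel ← pixel · (1 + σ z)` with σ = 0.05
by default, clipped to `[0, 255]`: the detector consumes local means and
differences, for which the second-order structure of the noise matters,
not the exact (Rayleigh/gamma-like) speckle law, and users can substitute
their own noise by building images directly.

`generate_batch()` randomizes, per scan, the cyst centre (rows 44–56,
columns 60 to n−60), semi-axes (7–12 rows × 16–30 columns) and interior
intensity (30–42), and the shadow position (width 8–14 columns, anywhere
away from the borders) and attenuation (0.15–0.3) — ranges chosen to span
small-to-medium DME cysts that remain inside the tissue band, and vessel
shadows from moderate to strong. All randomness is driven by one seed,
and the generator restores the caller's RNG state.

**What the phantoms do not emulate** — and hence what passing tests do not
demonstrate about clinical data: curved/foveal layer geometry, layer
texture, multiple or confluent cysts per scan, sub-retinal fluid shapes,
true speckle statistics, scanner-specific vignetting, and motion
artifacts. The phantom results characterize the *mechanism* (which
transitions fire, what the shadow tracker removes), not clinical accuracy;
for that, the sweep harness exists to calibrate `thv`, `α` and the window
on labelled data.

## Degenerate inputs and edge behavior

Images must be at least 7 × 7 (the smallest size on which all offset-2
differences have an interior). Inputs of any bit depth are linearly
rescaled to `[0, 255]` float on load, multi-channel files are collapsed by
channel average with a warning. A column with no defined means yields an
absent transition with a diagnostic; an undefined SE or SP (zero
denominator) is reported as `NA` with a warning, never imputed as 0 or 1.
Candidates are never merged or deduplicated — one accepted patch is one
candidate, and any grouping is a rendering concern.

## Problem sizes in the test suite

The suite validates the vectorized maps, masks and full detection pass
against brute-force loop re-implementations on fifty random 30 × 30
images, exercises the pipeline end-to-end on 100 × 256 phantoms, and
measures operating characteristics on a 50-phantom batch (25 cystic, 25
shadow-only) plus 30-phantom sweep batches — sizes at which the whole
suite runs in about a minute while leaving every code path covered.
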