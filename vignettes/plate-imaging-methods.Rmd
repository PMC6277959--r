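---
title: "Methods: calibration, scan planning, stack segmentation and focus fusion"
author: "platescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibration, scan planning, stack segmentation and focus fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platescan)
```

platescan is the software half of a low-cost plate-imaging microscope
built on a repurposed CNC engraving stage: the stage carries the
multi-well plate under a fixed video microscope, a relay wired in place
of the cutting-tool switch pulses the camera shutter (G-code `m3`
closes it, `m5` opens it), and the camera writes sequentially numbered
JPEGs to its card. The package computes everything around that
hardware: where each well is, the G-code that visits it, how the
resulting image pile is cut back into per-well z-stacks, and how each
stack is merged into one extended-depth-of-field micrograph.

## Four-corner calibration

Rather than aligning the plate holder mechanically to tens of
micrometres, the system is calibrated in software. The operator drives
the stage until the top-left drop (well A1) is centred and focused,
zeroes all three axes there, then notes the machine coordinates of the
three remaining corner drops. Wells are indexed on the unit square,
$u = \mathrm{col}/(n_\mathrm{cols}-1)$,
$v = \mathrm{row}/(n_\mathrm{rows}-1)$, and each machine axis
$a \in \{x, y, z\}$ is modelled by the tensor-product linear surface

$$ f_a(u, v) = k_0 + k_1 u + k_2 v + k_3\, u v . $$

Four corner measurements determine the four coefficients exactly, in
closed form ($k_0 = c_{00}$, $k_1 = c_{10}-c_{00}$,
$k_2 = c_{01}-c_{00}$, $k_3 = c_{11}-c_{10}-c_{01}+c_{00}$), so the
fitted surface reproduces all four corners to machine precision. We
chose the bilinear surface as the minimal curved model with this
property: it is the unique polynomial exactly determined by the four
corner values, and it degenerates to a plane precisely when the fourth
corner is coplanar with the other three ($k_3 = 0$). The $uv$ term is
what a three-point planar fit cannot represent; on a warped plate or a
stage with slightly non-orthogonal axes the plane's prediction error
grows as $|k_3|\,u v$ — worst at the far corner well, where it misses
by the full warp term, and a quarter of it at the plate centre. Since a
typical $k_3$ on the focus axis is a few tenths of a millimetre while
the depth of field is smaller than one z-step (0.15 mm), the planar
model visibly defocuses part of the plate; `planar_fit()` is therefore
kept only as a diagnostic, and `calibration_report()` tabulates
per-well differences between the two models against a focus tolerance.

Assumptions worth stating: corner coordinates are typed in exactly as
the G-code sender displays them after manual centring (absolute mm,
origin at A1); measurement noise is not averaged out (four points,
four coefficients), so a sloppy corner measurement propagates — the
residual table from `residuals()` on a re-measured corner set is the
check. Predictions outside a soft travel window (defaults
$x \in [-5, 160]$, $y \in [-110, 5]$, $z \in [-10, 10]$ mm) warn
rather than fail, because over-driving this class of stage grinds but
does not break; the couplings should simply be checked before
recalibrating.

## Scan planning

`plan_scan()` emits a deterministic GRBL-dialect program: `g90`/`g21`
modal setup, then for each well a rapid move to the well's predicted
$xy$ at the top of its z-stack, and per z level a z move, a settle
dwell, a relay pulse and a write dwell. The protocol defaults mirror
the 2 µl crystallization-drop settings:

| parameter         | default          | why                                           |
|-------------------|------------------|-----------------------------------------------|
| `n_z`             | 5 images         | covers focus uncertainty across the plate     |
| `dz`              | 0.15 mm          | one step ≈ optical depth of field for 2 µl drops |
| `settle_dwell`    | 0.1 s            | lets the stage stop ringing after a move      |
| `write_dwell`     | 0.5 s (0.4–0.6)  | camera file-write time; shorter skips frames  |
| `pulse_dwell`     | 0.2 s            | relay closure long enough to register a click |
| `sentinel_offset` | 1.0 mm           | far enough above focus to be obviously blurred |
| `order`           | row-serpentine   | consecutive wells one grid step apart         |

Choices that were genuinely open:

* **Stack centring.** The z levels are centred on the calibrated focus,
  $z_0 + dz\,(i - (n_z-1)/2)$, stepped top to bottom. Nothing in the
  protocol dictates centred versus one-sided; centred tolerates
  calibration error symmetrically, which is the reason to take several
  z-spaced images at all.
* **Sentinel position.** The deliberately defocused frame is taken
  last within each well, `sentinel_offset` above the stack top, so it
  terminates the well's run of files on disk and delimits the stack
  even when data frames are missing. A warning fires if the offset is
  under $3\,dz$, where the "sentinel" might not be obviously blurred.
* **Rendering dialect.** Lowercase words, coordinates at a fixed three
  decimals (1 µm, below the stage's step size), LF endings — chosen so
  rendered programs are byte-for-byte reproducible and round-trip
  exactly through `parse_gcode()`. Pulse width is not specified by the
  hardware notes anywhere, so 0.2 s is a configurable default chosen
  above typical switch debounce.

Streaming to the controller is out of scope; any G-code sender can
feed the file to the stage.

## Sentinel segmentation

Segmentation never decodes pixels. JPEG compression makes a defocused
frame markedly smaller than the in-focus frames around it, so the file
listing alone — names for ordering, sizes for detection — partitions
the series. Two stages:

**Candidates.** A record is a sentinel candidate when its size falls
below `rel_threshold` (default 0.75) times the median size of its up
to `n_z + 1` nearest neighbours, excluding records already flagged;
the set is grown from empty to a fixpoint, which makes it monotone in
the threshold. On realistic series this rule is deliberately
over-inclusive — deeply defocused *data* frames can also sit below
0.75 of the local median — so candidacy is treated as permission, not
proof.

**Reconciliation.** The candidate set is aligned with the expected
structure by dynamic programming over stack boundaries. Each stack
takes 1 to `n_z` data records and is optionally terminated by one
candidate acting as its sentinel, subject to two hard constraints that
encode what a sentinel *is*: it must be strictly smaller than every
data record of its own stack, and strictly smaller than the record
that follows it (the next well's first frame). Among feasible
partitions the algorithm optimizes, lexicographically: fewest stacks
without a sentinel; most stacks of the expected shape (exactly `n_z`
data + sentinel); fewest stacks; data counts closest to `n_z`;
smallest files used as sentinels; and sentinel-less boundaries placed
after the smallest file. The ordering matters: ranking expected-shape
count first would reward chopping the whole series into runs of five
and ignoring the sentinels, or "completing" a short stack by
swallowing its sentinel as data — both failure modes we observed and
excluded by construction. A missing data frame simply shortens its
stack; a missing sentinel merges two stacks, which the length cap
forces apart again at a sentinel-less boundary, placed after the
smallest file. Because sentinel-less boundaries make any series
partitionable, the structure-error path is defensive only.

On series of ≤ 30 records the dynamic program is checked against
exhaustive enumeration of all threshold-consistent partitions under
the same objective; they agree exactly.

Stacks are then labelled with wells in the scan order the plate was
acquired in — segmentation must be told the same `order` the planner
used, since the k-th stack is the k-th visited well. Fewer stacks than
wells flags a mismatch; more is an error.

## Alignment and fusion

Each stack is registered to its middle image by the integer translation
(within ±`max_shift` px, default 20) maximizing the cross-correlation
of mean-centred intensities, computed via FFT; images are then cropped
to the common overlap. Integer-only registration is a deliberate
floor: the settle dwell keeps frame-to-frame drift below a pixel, and
residual blur on this hardware comes from shutter vibration, which no
translation fixes. A shift landing on the search boundary raises a
warning rather than silently truncating.

The focus measure is local absolute-Laplacian energy — luminance
convolved with the discrete Laplacian, magnitude box-averaged over a
5 px window — raised to the power 2 and normalized across the stack
per pixel ($\varepsilon = 10^{-6}$ keeps flat regions defined, where
all frames then weigh $1/n$). The exponent sharpens the competition
between frames: with proportional weights the fused image mixes in
defocused copies and its local sharpness sags a few percent below the
best parent; with the square it tracks the per-region sharpest frame
to within ~1%. Saturation and exposedness terms common in exposure
fusion are omitted: droplet micrographs are near-monochrome and the
only axis that varies is focus.

Blending happens in the pyramid domain: each image's Burt–Adelson
Laplacian pyramid is averaged level-by-level under the Gaussian
pyramid of its weight map, and the blended pyramid is collapsed.
Per-pixel selection would produce seams at focus boundaries;
multiresolution blending does not. Numerical notes: the 5-tap binomial
kernel (1 4 6 4 1)/16 with replicate padding preserves constants, so
normalized weights sum to one at every level and fusing $n$ copies of
an image returns it to rounding error ($<10^{-9}$); blending is a
symmetric weighted sum, so the result is invariant to stack order;
pyramid depth defaults to $\lfloor\log_2 \min(h, w)\rfloor - 3$
(at least 1); odd dimensions are handled by upsampling to an explicit
target size; the collapsed image is clipped to [0, 1]. Color stacks
are blended channel-wise under shared luminance weights.

## The synthetic acquisition generator

Hardware-free testing needs images whose *file sizes* behave like the
real camera's, not photorealistic drops. `render_scene()` draws, from
a seed, a gentle illumination gradient, dark droplet-boundary arcs,
bright crystal needles, several hundred precipitate specks and
Gaussian sensor noise — enough high-frequency content that Gaussian
blur measurably shrinks both Laplacian energy and compressed size.
Defocus follows $\sigma(z) = k\,|z - z_\mathrm{best}| + \sigma_0$ px
with $k = 8$ px/mm and $\sigma_0 = 0.5$ px, defaults chosen so that
one 0.15 mm z-step changes blur visibly (1.2 px) and the worst
in-stack defocus (≈ 4 px) still compresses several times larger than
the sentinel blur (floor 8 px). Each well's true focus is drawn
uniformly within ±`dz` of the calibrated plane — the plate/drop
variability that motivates z-stacks — so the sharpest frame lands
inside the captured stack. Images are written as JPEG quality 85
(recorded in the ground truth; the sharp/blurred size gap is stable
there), numbered by a counter that, like a real camera's, advances
only on written files; data frames are dropped independently with
`missing_prob`, sentinels never (the premise of sentinel-based
segmentation). After writing each sentinel the generator verifies it
is strictly the smallest file of its well and re-renders with more
blur in the rare violation.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: optical point-spread functions
beyond Gaussian blur, shutter-shake blur, exposure drift across a
plate, real JPEG size statistics of crystal drops versus clear drops,
and skew between wells' content. The segmentation margin on real
acquisitions depends on the real size gap between the most defocused
data frame and the sentinel; the `rel_threshold` and the sentinel
offset are the knobs if that gap is thin.

## Problem sizes and runtime choices

The test suite and the acceptance script run simulations at the sizes
a desk check needs, chosen once: the default scene is 640 × 360 px
(the 1080p detector aspect); the single end-to-end protocol check
segments one full-size 24-well acquisition (144 images); the
20-acquisition robustness suite and the repeated recovery measurements
use 192 × 108 px scenes, which preserve the size-signature behaviour
the test exercises while keeping the whole suite in a few minutes.
Exhaustive-search cross-checks use series of ≤ 30 records with
`n_z = 3`, where enumeration is tractable.

## Known limitations

* Calibration models each axis independently and bilinearly; it cannot
  represent higher-order stage nonlinearity inside the plate interior,
  backlash, or thermal drift between calibration and scan.
* Segmentation requires sentinels. Without them the series has no
  decode-free structure signal; content-based (pixel) detection is
  deliberately out of scope.
* Sub-pixel registration and deconvolution are out of scope; fusion
  output is bounded by the sharpest parent frame by design.
* Scan-order bookkeeping is by convention: segmenting with a different
  `order` than the scan was planned with silently mislabels wells.
  The manifest records the order used.
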