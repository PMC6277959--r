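# platescan

Software for an open-hardware multi-well plate imager built on a
repurposed CNC translation stage. A fixed video microscope looks down at
the plate; the stage moves the plate beneath it; a relay wired in place
of the spindle switch (G-code `m3`/`m5`) clicks the camera shutter; the
camera writes numbered JPEGs to its card. platescan computes everything
around that hardware, for crystallographers and cell biologists who want
automated plate imaging without a commercial imaging robot:

* **Stage calibration** — from four manually measured corner-well
  coordinates, fit for each machine axis the bilinear surface
  `f(u, v) = k0 + k1·u + k2·v + k3·u·v` over normalized well indices
  `(u, v) ∈ [0, 1]²`. Four points determine the four coefficients in
  closed form, so all corners are reproduced exactly, and the `u·v` term
  captures the plate/stage warp that a three-point planar fit misses —
  enough to defocus wells, since the depth of field is smaller than one
  focus step.
* **Scan planning** — a GRBL-dialect G-code program that visits every
  well (serpentine by default), steps a z-stack centred on the
  calibrated focus (default 5 images, 0.15 mm apart), and pulses the
  shutter with settle (0.1 s) and file-write (0.5 s) dwells. One extra,
  deliberately defocused *sentinel* image ends each well.
* **Stack segmentation** — JPEG compression makes the defocused sentinel
  much smaller on disk than the frames flanking it. File names and sizes
  alone (no pixel decoding) partition the numbered series back into
  per-well z-stacks, robust to occasionally missing frames, via
  candidate detection plus a dynamic alignment against the expected
  stack structure.
* **Focus fusion** — each stack is translation-aligned, weighted by
  local Laplacian contrast, and blended through Laplacian pyramids into
  one extended-depth-of-field micrograph per well.
* **Synthetic acquisition** — a seeded generator of defocus-blurred
  droplet scenes with ground truth, reproducing the defocus/file-size
  physics, so the full pipeline runs and is tested without hardware.

## Worked example

Calibrate from corner measurements, plan a 96-well scan, and inspect
the program:

```r
library(platescan)

corners <- corner_set(c10 = c(100.15, -1.34, 0.13),
                      c01 = c(0.80, -63.10, -0.05),
                      c11 = c(101.00, -64.40, 0.21))
cal <- fit_corners(corners)
cal
#> <bilinear_map> (bilinear) f(u,v) = k0 + k1 u + k2 v + k3 u v  [mm]
#>         x      y     z
#> k0   0.00   0.00  0.00
#> k1 100.15  -1.34  0.13
#> k2   0.80 -63.10 -0.05
#> k3   0.05   0.04  0.13
#>   max centre-well warp |k3|/4: x 0.012  y 0.010  z 0.033 mm
```

The `k3` row is the warp a planar calibration cannot represent: here the
plate centre would be predicted 0.033 mm out of focus in z — a fifth of
a z-step — and the far corner by the full 0.13 mm, nearly one step.

```r
prog <- plan_scan(cal, builtin_plate("96"), scan_config())
prog
#> <gcode_program> 3554 commands, 96 wells, 576 camera triggers
write_gcode(prog, "scan.gcode")
```

576 triggers = 96 wells × (5 z-images + 1 sentinel). The file starts:

```
g90
g21
g0 x0.000 y0.000 z0.300
g0 z0.300
g4 p0.1
m3
g4 p0.2
m5
g4 p0.5
g0 z0.150
...
```

Simulate an acquisition (3% of frames lost), segment it, and fuse:

```r
truth <- simulate_acquisition("24", scan_config(), scene_params(seed = 7),
                              missing_prob = 0.03, out_dir = "acq/")
m <- segment_series("acq/", "24")
m
#> <series_manifest> plate 24: 24 stacks (23 complete with 5 images)
head(as.data.frame(m), 6)
#>   well z_index     filename
#> 1   A1       1 img_0001.jpg
#> 2   A1       2 img_0002.jpg
#> 3   A1       3 img_0003.jpg
#> 4   A1       4 img_0004.jpg
#> 5   A1       5 img_0005.jpg
#> 6   A1       0 img_0006.jpg        # z_index 0 marks the sentinel

write_manifest(m, "manifest.json", csv = "manifest.csv")
fuse_manifest(m, "fused/")           # writes fused/A1.png, fused/A2.png, ...
```

The well that lost a frame is segmented as a 4-image stack in the right
position; `manifest_matches_truth(m, truth)` confirms the recovered
partition equals the generator's ground truth.

A thin command-line front end over the same functions is installed at
`inst/cli/platescan.R` (`plan`, `segment`, `fuse`, `simulate`
subcommands); run configurations (plate, corner coordinates, protocol)
live in a single YAML file read by `load_run_config()`.

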