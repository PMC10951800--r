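# phseg

Topological segmentation and tracking for volumetric and time-lapse
fluorescence microscopy.

Fluorescence stacks encode structures of interest as bright regions over a
dark background, but 3-D data defeats most classical segmenters: methods
that assume object geometry fail on irregular morphologies, and per-slice
2-D analysis cannot follow structures through depth or time. `phseg`
segments stacks by **persistent homology over cubical complexes**: voxels
are swept along the superlevel-set filtration of intensity, connected
components are born at local maxima (each anchored at its brightest voxel,
the *root*) and a single persistence threshold τ controls the whole
pipeline —

* a voxel *v* attaches to the brightest neighbouring component *C* only if
  `root(C) − I(v) ≤ τ`,
* two components merge where they meet only if their roots differ by at
  most τ,
* components rooted below τ are discarded as background.

The sweep is dimension-agnostic (2-D frames and 3-D z-stacks run the same
code) and makes no assumption about object shape. For videos, each frame
is segmented in 2-D and components are linked across frames by pixel
overlap, with explicit split handling (lineage edges to child tracks) and
merge handling (the track with the brightest spatiotemporal root
survives) — so divisions and fusions are tracked rather than fused away.
Because the component count is provably non-increasing in τ, the threshold
can be calibrated automatically against a known object count by bisection
from τ = 0.5.

The package also ships per-object summary statistics (centroid, spread,
intensity, volume in voxels and µm³, track lifespans), a synthetic
ground-truth stack generator with scripted divisions/merges, a windowed
sensitivity/specificity benchmark over a 3×3 blur × noise grid, TIFF/CSV/
JSON input-output and a command-line interface
(`inst/scripts/phseg.R`).

## Worked example

Simulate a degraded z-stack with known ground truth, calibrate τ from the
known object count, segment, and score against the truth:

```r
library(phseg)

sim <- simulate_stack(simulation_spec(seed = 42, blur_sigma = 5, noise_sigma = 5))
sim
#> <ph_simulation> volume 8x256x256, 3 object(s), sigma1 = 5, sigma2 = 5, seed 42

cal <- calibrate_tau(sim$degraded, sim$truth$n_objects)
cal$tau
#> [1] 0.5

seg <- cal$result
seg
#> <ph_segmentation> volume 8x256x256: 3 component(s), tau = 0.5, full

component_stats(seg, sim$degraded)[, c("id", "centroid_y", "centroid_x",
                                       "mean_intensity", "volume_vox")]
#>   id centroid_y centroid_x mean_intensity volume_vox
#> 1  1     157.84     167.67           0.74       9039
#> 2  2      50.32     131.37           0.68      11337
#> 3  3     217.31      57.70           0.49      15916

windowed_confusion(seg$labels, sim$truth$mask, window = c(5, 5, 5))[1:2]
#> $sensitivity
#> [1] 0.8160878
#> $specificity
#> [1] 0.7295081
```

The segmentation recovers all three objects at the initial threshold; the
windowed metrics quantify how much the blurred, noisy label map deviates
from the pre-degradation truth inside an 11×11×11 neighbourhood of every
true foreground voxel. For a video, replace `segment_stack()` with
`track_video()` to get tracks, lineage edges and merge annotations; see
the methods vignette (`vignettes/phseg-methods.Rmd`) for the model,
parameter guidance and known limitations.

From the shell:

```sh
Rscript inst/scripts/phseg.R --mode simulate --seed 4 -o sim/
Rscript inst/scripts/phseg.R --mode calibrate --expected 3 -o out/ sim/simulated.tif
```

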