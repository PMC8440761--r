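# voxuq

Segmentation is rarely certain: two plausible segmentations of the same CT
scan of a battery electrode, woven composite or organ can disagree on every
boundary voxel, and any physics quantity computed from the segmented
geometry inherits that ambiguity. `voxuq` quantifies this segmentation
uncertainty and propagates it to physics quantities, for researchers doing
image-based simulation on 3D voxel data.

## The method

Given *N* co-registered segmentation samples (from Monte-Carlo sampling of
a segmentation network, threshold jitter, multiple annotators, ...), the
per-voxel **probability map** for class *i* is the inclusion frequency

&nbsp;&nbsp;&nbsp;&nbsp;ε<sub>v,i</sub> = (1/N) Σ<sub>k</sub> p<sup>k</sup><sub>v,i</sub>,

where p<sup>k</sup><sub>v,i</sub> ∈ {0, 1} indicates membership of voxel
*v* in class *i* for sample *k*. Uncertainty is summarised by the
normalized Shannon entropy

&nbsp;&nbsp;&nbsp;&nbsp;H(ε<sub>v</sub>) = −Σ<sub>i</sub> ε<sub>v,i</sub> log₂ ε<sub>v,i</sub> / log₂ n<sub>c</sub> ∈ [0, 1],

with per-class contributions −ε<sub>v,i</sub> log₂ ε<sub>v,i</sub> / log₂ n<sub>c</sub>.
Thresholding ε at t = 1 − P/100 gives the nested **percentile
segmentations**; the three *standard segmentations* at P = 15.9, 50.0,
84.1 (the printed percentiles of μ−σ, μ, μ+σ of a Normal) feed voxel
physics solves — volume fraction, effective transport from a finite-volume
Laplace solve (conducting phase k = 1, blocking phase k = 10⁻⁶), and
tortuosity = porosity / effective transport. Interpreting the physics value
at percentile P as the P/100 quantile of its unknown uncertainty
distribution, the standard segmentations specify a **characteristic
Normal** (mean from P = 50, σ from the 15.9–84.1 spread); held-out
percentiles diagnose non-Normal quantities, for which beta, half-Cauchy and
empirical fits are available. Smooth level-set surfaces of ε can be
exported as binary STL for external meshing tools.

A synthetic-scene generator (planar blurred interfaces, Gaussian-random-field
blob microstructures, seeded segmentation samplers with closed-form
inclusion probabilities) makes the whole chain testable end to end.

## Worked example

```r
library(voxuq)

scene <- make_planar_interface(c(64, 16, 16), x0 = 32.25, w = 6)
stack <- sample_segmentations(scene, N = 48, "threshold_jitter", seed = 1)
pmap  <- compute_probability_map(stack)
pmap
#> <probability_map> grid 64x16x16 (x,y,z), classes {0, 1}, binary (map stored for class 1), N = 48

entropy_map(pmap)
#> <uncertainty_map> total, grid 64x16x16, mean H = 0.2261, frac(H > 0.5) = 0.1875

sw <- run_physics_sweep(pmap, percentiles = standard_percentiles(),
                        quantities = c("volume_fraction", "effective_conductivity"),
                        axis = "z")
sw
#>   percentile threshold               quantity axis  value iterations  residual
#> 1       15.9     0.841        volume_fraction <NA> 0.4062          0 0.000e+00
#> 2       15.9     0.841 effective_conductivity    z 0.4063        146 9.738e-13
#> 3       50.0     0.500        volume_fraction <NA> 0.4844          0 0.000e+00
#> 4       50.0     0.500 effective_conductivity    z 0.4844        141 8.489e-13
#> 5       84.1     0.159        volume_fraction <NA> 0.5781          0 0.000e+00
#> 6       84.1     0.159 effective_conductivity    z 0.5781        145 9.206e-13

tab <- quantity_table(sw$percentile[sw$quantity == "effective_conductivity"],
                      sw$value[sw$quantity == "effective_conductivity"])
fit_characteristic_normal(tab)
#> <characteristic_distribution> normal(mean = 0.484376, sd = 0.0860599)
```

The sweep reads as follows: the blurred interface leaves about 17% of the
volume ambiguous, so the conservative (P = 15.9) and inclusive (P = 84.1)
segmentations bracket the volume fraction between 0.41 and 0.58, and the
effective conductivity along z (slabs parallel to the transport axis, so
conductivity tracks volume fraction) inherits the same spread. The fitted
characteristic Normal says: segmentation uncertainty alone makes this
conductivity uncertain with σ ≈ 0.086 around a mean of 0.484.

Config-driven end-to-end runs (`run_pipeline("config.yaml")`, or
`Rscript inst/cli/voxuq.R run config.yaml`) write the probability map,
entropy map, masks, optional STL surfaces, a physics CSV, the distribution
fit JSON and a manifest.

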