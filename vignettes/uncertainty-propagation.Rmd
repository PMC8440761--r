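---
title: "Propagating segmentation uncertainty to physics quantities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating segmentation uncertainty to physics quantities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxuq)
```

## The model

Image-based simulation treats a segmentation as if it were the geometry.
`voxuq` instead treats segmentation as a per-voxel random variable. Its
central object is the probability map: given $N$ co-registered
segmentation samples over classes $C = \{1,\dots,n_c\}$, the map for class
$i$ is the inclusion frequency
$$\epsilon_{v,i} = \frac{1}{N}\sum_{k=1}^{N} p^k_{v,i},$$
with $p^k_{v,i} \in \{0,1\}$ the binarized membership of voxel $v$ in
sample $k$. The package is agnostic to where the samples come from — a
Bayesian or Monte-Carlo-dropout network, threshold jitter, several human
annotators — it only requires co-registered label volumes on one grid. Any
external model that directly outputs a voxel-wise probability volume can
be loaded in place of the sample ensemble. For a binary problem a single
foreground map suffices and the complement class is implied as
$1-\epsilon$; multi-class problems are treated one-vs-rest per class.

Uncertainty is summarised by the normalized Shannon entropy
$$H(\epsilon_v) = -\sum_{i\in C}\epsilon_{v,i}\log_2(\epsilon_{v,i}) / \log_2(n_c) \in [0,1],$$
so a voxel assignable to every class with equal probability scores exactly
1 and a one-hot voxel exactly 0. The $0\log_2 0$ terms are removed by
masking, not by adding an epsilon, so certainty is exact. Per-class maps
$-\epsilon_{v,i}\log_2(\epsilon_{v,i})/\log_2(n_c)$ sum to the total over
the class set, which the tests verify voxel-wise.

## Percentile segmentations

The map's per-voxel distribution is probed by thresholding: the percentile-
$P$ segmentation keeps voxels with $\epsilon \ge t$, $t = 1 - P/100$, so a
larger percentile is a more inclusive geometry and masks are nested in
$P$. The comparison is inclusive — a voxel with exactly the threshold
probability belongs to the segmentation. The mapping direction was a
genuine design choice: with $t = P/100$ higher percentiles would *shrink*
the segmented phase, which contradicts the physical narrative that the
$\mu+\sigma$ probe adds material and raises conductivity; we adopt
$t = 1 - P/100$ and do not implement the alternative.

The three *standard segmentations* sit at $P = 15.9, 50.0, 84.1$ — the
conventional one-decimal printing of $100\,\Phi(\mp 1)$ — and are used
exactly as printed; the package does not silently substitute
$\Phi(\pm 1)$ when thresholding.

Smooth surfaces are extracted from the *real-valued* map at the threshold
level, never from a binarized mask, so the mesh tracks the sub-voxel
position of the level set instead of stair-stepping. The triangulation is
marching tetrahedra: each cell of the dual grid (corners at voxel centers,
located at $(\mathrm{index}-0.5)\cdot\mathrm{spacing}$) is split into six
tetrahedra sharing a main diagonal and the level set is interpolated
linearly along edges. Shared faces get identical decompositions, so the
triangle soup is watertight wherever the level set stays inside the grid;
windings are oriented away from the included phase. On a 40³ spherical
test profile the mesh area is within 0.2% of the analytic sphere.

## Voxel physics

Three quantities are propagated per percentile segmentation:

* **volume fraction** — the voxel count ratio, no solve;
* **effective transport** (electrical or thermal conductivity) — a
  cell-centered finite-volume Laplace solve on the voxel grid. Face
  conductances are harmonic means of the adjacent cell conductivities
  along the face normal (the standard treatment for discontinuous
  coefficients; it reproduces the series-slab closed form exactly). A unit
  potential difference is imposed via Dirichlet conditions at half-cell
  ghost distance on the two faces normal to the transport axis — which
  makes a homogeneous medium exact — with zero flux on the remaining
  boundaries. The effective property is the area-averaged boundary flux
  over the imposed gradient;
* **tortuosity** — porosity divided by the effective transport of the pore
  network, with $k = 1$ in the transporting phase and $k = 10^{-6}$ in the
  blocking phase. The blocking phase is kept in the domain at small
  conductivity rather than carved out, keeping the grid structured.

Phase conductivities may be scalars or axis-diagonal triples, which covers
transversely isotropic materials (e.g. a fabric with in-plane conductivity
4.0 W m⁻¹ K⁻¹ and half that through-plane, in a 0.278 W m⁻¹ K⁻¹ matrix)
without modelling full tensors or per-voxel fiber orientation.

### Numerical choices

The linear system is symmetric positive definite and solved with
Jacobi-preconditioned conjugate gradients. The default relative-residual
tolerance is $10^{-12}$ rather than a looser engineering tolerance: the
residual is measured against $\lVert b\rVert$, which scales with the
*largest* conductance, while the physical flux through a $10^6$-contrast
medium is $O(10^{-6})$; at $10^{-9}$ the effective property would carry
$\sim 10^{-5}$ relative error, whereas $10^{-12}$ achieves better than
$10^{-10}$ agreement with the series/parallel closed forms at a cost of a
couple of extra iterations. After the residual test the solve is polished
at tighter tolerance until inflow and outflow balance to `flux_rtol`
(default $10^{-8}$) or the double-precision floor (about $3\times10^{-11}$
relative for $10^6$-contrast fields) is reached. Every solve reports the
Wiener bounds (harmonic and arithmetic means of the cell conductivities
along the transport axis), which bracket the result; the tests assert
this on random fields and check the iterative path against a dense direct
solve on small grids to $10^{-8}$.

## The characteristic distribution

The physics value at percentile $P$ is read as the $P/100$ quantile of the
quantity's unknown uncertainty distribution. The standard segmentations
then specify a characteristic Normal: the mean is $Q(50.0)$ and
$$\hat\sigma = \frac{Q(84.1) - Q(15.9)}{2\,\Phi^{-1}(0.841)}.$$
The denominator is a deliberate choice: since the printed percentiles are
rounded, dividing the spread by exactly 2 would bias $\hat\sigma$ by
$\Phi^{-1}(0.841) \approx 0.9986$, i.e. 0.14%, and a table of exact Normal
quantiles would not round-trip. With the exact quantile distance the fit
recovers $(\mu, \sigma)$ of a Normal-quantile table to machine precision.
The raw symmetric half-width and both one-sided half-widths are kept in
the diagnostics so asymmetry stays visible, and a quantity that decreases
with percentile is fitted on $|\cdot|$ with an orientation flag.

Held-out percentile rows (beyond the standard three) assess the fit by
$|\mathrm{CDF}(Q(P)) - P/100|$, with a default 0.05 absolute tolerance —
tight enough to separate a genuinely Normal table (discrepancy at the
rounding level) from a skewed, bounded quantity fitted as Normal, whose
tails fail clearly. For such quantities beta (on a finite support),
half-Cauchy and empirical families are fitted by least-squares quantile
matching with Nelder-Mead from moment-based starts and three jittered
restarts under a fixed restart seed; parametric families need at least 4
rows. The beta support defaults to $[0,\ 1.1\max Q]$ — bounded-below
quantities such as permeability should not receive negative mass — and
with at least 6 rows and no supplied support the bounds are estimated as
free parameters. The empirical family is the monotone interpolant of
$(Q(P), P/100)$ and requires a monotone table.

Non-monotone tables are the workflow's failure mode: if $Q(50)$ escapes
the $[Q(15.9), Q(84.1)]$ band, three segmentations cannot bound the
quantity. `check_monotonicity()` flags both conditions, characteristic
fitting refuses non-monotone tables without an explicit override, and the
pipeline downgrades to the empirical family with a recorded warning.

## What the synthetic scenes do and do not emulate

`make_planar_interface()` renders a two-phase interface blurred to width
$w$ as $g(x) = \Phi((x-x_0)/w)$; `make_blob_microstructure()` thresholds a
Gaussian random field smoothed to correlation length $\ell$ at the
$(1-\phi)$ quantile, re-blurs the truth and adds grayscale noise of
amplitude $a$. The samplers have closed-form per-voxel inclusion
probabilities: threshold jitter (uniform threshold per sample) converges
to the grayscale itself, and noise-then-threshold to
$\Phi((g-0.5)/a)$ — so the probability map, the entropy band around the
interface, the standard-segmentation offsets ($x_0 + w\,\Phi^{-1}(t)$, to
within one voxel) and the Normal-quantile shape of the planar scene's
volume-fraction curve are all checkable analytically. The noise amplitude
is the image-quality knob: a larger $a$ must and does widen every fitted
$\sigma$ downstream.

These scenes deliberately omit what real CT brings: spatially correlated
noise, beam hardening and ring artifacts, anisotropic resolution, and
segmentation-model bias that no ensemble spread can reveal. Passing tests
therefore demonstrate that the machinery is correct, not that a particular
scanner-plus-network combination is well calibrated.

All generators draw from a single seeded stream recorded in the scene
recipe, and samplers restore the caller's RNG state, so fixtures are
reproducible bit for bit.

## Problem sizes and defaults

The test suite runs on grids from $4^3$ oracle cases to $48^3$
microstructures, ensembles of up to 2000 samples on a 32×32×8 scene
(3-binomial-standard-error agreement at ≥ 99% of voxels), 10-percentile
sweeps with full Laplace solves at 24³, and dense-solve oracle comparisons
up to 12³ — sizes chosen so every property is exercised meaningfully while
the whole suite stays in the ten-second range on one CPU. Default
generator settings (48 samples, blur widths of 1–6 voxels, noise
amplitudes 0.05–0.15) mirror the ensemble size and boundary-ambiguity
scale of the imaging workflows the package targets.

## Known limitations

* Spatial correlation between neighboring voxels' uncertainties is not
  modelled; each voxel's probability is marginal.
* Aleatoric and epistemic contributions are not separated; the map mixes
  whatever the sample generator mixes.
* Physics is limited to structured-voxel-grid diffusion; flow and
  elasticity solvers are external, but their (percentile, value) tables
  can be fitted through the same distribution machinery.
* Soft (real-valued) sample outputs are not combined directly; samples
  must be binarized (at 0.5) before stacking. Averaging soft outputs is a
  plausible alternative estimator of $\epsilon$ that the package
  deliberately does not implement.
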