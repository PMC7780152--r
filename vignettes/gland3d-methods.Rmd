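---
title: "Quantifying vascular niches in 3D gland volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular niches in 3D gland volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Endocrine glands — pancreatic islets, adrenal cortex and medulla, thyroid,
ovary, testis, pituitary — are among the most densely vascularized tissues,
and their capillaries are not passive plumbing: endothelial subsets with
distinct marker profiles (e.g. CD31\*+\* Emcn\*hi\* islet capillaries versus
CD31\*+\* Emcn\*lo\* exocrine capillaries, or CD102/VCAM-1/Vimentin
combinations across adrenal zones) sit in defined spatial relationships with
pericytes, stromal cells, macrophages and hormone-producing cells, and these
relationships change with age.

Multiplex immunofluorescence of thick sections imaged as confocal z-stacks
(in-plane pixel 0.69 um, z-interval 0.82 um by default here) produces
multi-channel 3D volumes from which such niche organisation can be
quantified. `gland3d` implements the quantification chain as an open,
tested pipeline:

1. **Vessel surface segmentation** — background subtraction, Gaussian
   smoothing, thresholding, 26-connected components with shape statistics,
   and removal of small high-sphericity specks as noise.
2. **Vascular metrics** — vessel density (vessel volume / tissue volume),
   artery identification among alpha-SMA+ structures by tubular shape and
   artery counts per mm^3, and capillary/artery diameters read from skeleton
   radii in randomly sampled regions.
3. **Cell–vessel interactome** — an exact anisotropic Euclidean distance
   transform of the vessel mask, per-cell distances at segmented centroids,
   and the proximity rule that a cell within 18 um of a vessel subset
   belongs to that subset's interactome; interaction matrices per vessel
   subset and cell type, and young-versus-aged differential calls
   (gained / lost / stable).
4. **Cell segmentation and phenotyping** — nuclei-seeded segmentation
   (local maxima of the smoothed nuclear channel seeding a bounded
   watershed/nearest-seed partition), per-cell marker intensities, and
   band-based phenotype rules (`neg`/`pos`/`lo`/`hi` per marker).
5. **Scalar quantifications and statistics** — stained-area fractions
   (beta-cell mass, VEGFA coverage per islet), positive-cell fractions
   (Ki67+ beta cells over all beta cells), counts per mm^3, follicle
   density, ordinal expression heatmap levels, Pearson correlation, and
   group comparisons (two-tailed unpaired Student's t-test for two groups,
   one-way ANOVA with Tukey HSD beyond that).

Because the raw atlas volumes live on an image server rather than in a
deposited archive, validation is phantom-based: a first-class synthetic
generator (`phantom_spec()` / `generate_phantom()`) renders vascularized
tissue with complete ground truth, and every stage is tested against it.

## Core definitions

**Distance field.** For a vessel mask $V$ on a grid with spacing
$(d_z, d_y, d_x)$, the field assigns every voxel
$D(p) = \min_{q \in V} \lVert p - q \rVert_2$ in micrometres (0 inside the
mask). It is computed exactly by a separable lower-envelope-of-parabolas
pass per axis, with the per-axis spacing folded into the parabola widths;
the test suite checks it to $10^{-9}$ um against a brute-force all-pairs
search. Cell distances are trilinear interpolations of $D$ at centroids,
and membership in the interactome is $D \le 18$ um, boundary inclusive.
The 18 um cut-off is roughly one cell diameter — contact or immediate
juxtaposition rather than mere residence in the same region.

**Sphericity.** $\psi = \pi^{1/3} (6V)^{2/3} / A$, which is 1 for a ball
and decreases with elongation and roughness. $V$ is voxel count times voxel
volume; $A$ is the area of a marching-tetrahedra mesh of the component
indicator, lightly smoothed (sigma = 1 voxel) before extracting the 0.5
isosurface so that staircase artefacts do not inflate $A$. The noise filter
removes components with $V < 500\ \mu m^3$ **and** $\psi \ge 0.8$: small
bright specks are near-spherical, genuine vessel fragments are elongated.

**Artery criterion.** Alpha-SMA labels arteries but also stromal cells, so
arteries are recognised by structure: skeleton length $\ge 50$ um, mean
radius $\ge 3$ um (interior distance transform on the medial ridge), and
elongation $= L / 2\bar r \ge 2$. All three are configuration-exposed; the
defaults were fixed from the geometry of arteries versus stromal patches
and are deliberately generous against the phantoms' 20% margins.

**Diameters.** The mask is skeletonised as the medial ridge of the interior
distance transform (26-neighbourhood local maxima); the local radius at a
ridge voxel is its interior distance. Seven random cubic sub-blocks of side
50 um containing skeleton voxels are drawn (seeded, vessel-free blocks
resampled), and each region's diameter is twice its mean ridge radius. This
replaces interactive caliper measurements with a deterministic estimator;
on axis-aligned and 45-degree cylinders it is accurate within one in-plane
voxel.

## Numerical and design choices

* **Axis order and coordinates.** Arrays are `(channel, z, y, x)`; voxel
  centres sit at 0-based index times spacing. All kernels are specified in
  micrometres and converted per axis, so anisotropy is handled everywhere.
* **Skeleton length.** Rather than a full iterative 3D thinning, skeleton
  length is measured as the component's geodesic diameter (double-sweep
  Dijkstra over 26-neighbour steps with physical edge lengths). For
  tube-like structures this equals the centreline length to within a
  diameter; for blobs it is about one diameter, which is exactly what makes
  the elongation criterion discriminate. A topological thinning would add
  cost without changing any of the three artery measurements.
* **Radius read-out.** The raw ridge value of the interior distance
  transform is used as the local radius without a half-pitch "surface
  correction": the discrete ridge voxel sits up to half a pitch off the true
  axis (biasing low) while voxel-centre-to-voxel-centre distances overshoot
  the true surface by up to half a pitch (biasing high), and the two biases
  largely cancel. Empirically this halves the error of the corrected
  variant.
* **Thresholds.** Default `"auto"` is Otsu on the smoothed histogram (256
  bins); every realized threshold is recorded in the run report, and group
  contrasts should use one fixed manual threshold across samples — the
  pipeline takes the threshold as data, it does not re-derive it per
  sample when told not to.
* **Phenotype bands.** `t_pos` defaults to Otsu over the per-cell mean
  intensities of that marker and `t_hi` to the median of above-`t_pos`
  values; bands are inclusive on the positive side (`pos` is
  $\ge t_{pos}$, `hi` is $\ge t_{hi}$), so a cell exactly at a threshold is
  positive. Rules are evaluated in priority order; the first match wins.
* **Background subtraction.** The baseline is a Gaussian blur with
  sigma = `scale_um`/3 (about 99% of the kernel mass within one scale), so
  a flat field maps to zero and linear ramps are suppressed while objects
  much smaller than the scale keep their contrast.
* **Storage.** Volumes are written as multi-page 32-bit TIFF; the TIFF
  library stores samples scaled into [0, 1] at 32-bit depth (~2e-10
  relative precision), so intensities are divided by a power-of-two scale
  recorded in a JSON sidecar together with spacing, channel names and an
  integer flag. Integer-valued volumes — the realistic microscopy case —
  round-trip exactly; `write_volume()` returns the grid exactly as stored
  so downstream code can rely on write/read stability for floating data
  too.
* **Degenerate inputs.** Empty foreground yields a valid empty component
  set, an empty vessel mask an infinite distance field with a warning,
  empty regions are omitted with warnings, empty denominators flag the
  fraction as undefined instead of dividing by zero, and NaN intensity is
  an error.

## What the phantom generator emulates — and what it does not

`generate_phantom()` renders, per marker, foreground/background intensities
(defaults 200/10) on geometric masks, optionally blurred by an isotropic
Gaussian PSF and corrupted by additive Gaussian noise clipped at zero:

* capillary networks as randomly oriented tubes rasterised by an exact
  point-to-segment distance test (flat caps, so a tube's analytic volume is
  $\pi r^2 L$), filled until a target volume fraction is met — the final
  segment's length is chosen to land the rasterised fraction on the target,
  kept at least 12 radii long so it remains clearly tubular;
* arteries as thicker alpha-SMA+ tubes;
* islets as insulin+ spheroids with an internal capillary plexus; the
  insulin-positive core is a concentric ball of volume fraction
  `insulin_fraction`, so the true area fraction is analytic;
* cell populations with controlled placement: uniform in tissue, uniform
  in islets, or at exact distance bands from the vessel surface (the voxel
  distance field is the placement law, so planted distances are exact);
  proliferating subsets of exactly `round(n * p)` cells carry a Ki67+
  nucleus;
* nuclei as Gaussian blobs (sigma 2 um) at every cell centroid.

Two placement rules keep the phantoms inside the regime the analysis
assumes: centroids are at least 8 um (four nucleus sigmas) apart, so blob
detection can resolve them, and at least one nucleus diameter away from the
volume borders, because a nucleus cut by the section border is not
analysable (and reflective padding would bias its detected position).

The generator deliberately does **not** model depth-dependent PSFs,
spectral bleed-through, Poisson photon statistics, vessel curvature or
branching angles, tissue deformation, or segmentation-adversarial contact
between cells. Passing phantom tests therefore demonstrates that the
measurement chain is correct and unbiased on resolvable structures under
known noise — not that segmentation will be error-free on arbitrary tissue.
On real volumes the manual-threshold route and the recorded run report are
the reproducibility mechanism.

## Problem sizes and runtime

The test-suite phantoms are 64x128x128 voxels at (0.82, 0.69, 0.69) um —
about 52x88x88 um of tissue — which is large enough to hold a target-
fraction capillary bed, seven 50-um diameter-sampling regions, and
hundreds of separable cells, while keeping the full suite near two minutes
on one core. Distance-oracle grids are at most 32^3 because the
brute-force all-pairs reference is quadratic. The acceptance script
(`scripts/acceptance.R`) re-runs the pipeline end-to-end on three such
phantoms in under a minute.

## Known limitations

* Sphericity of very thin or short tubes is biased upward by roughly
  0.05–0.1 because the smoothed mesh underestimates their area; the noise
  filter's joint volume-and-sphericity rule absorbs this, but a sphericity
  cut below ~0.75 on sub-500 um^3 components would start removing genuine
  vessel fragments.
* The watershed territory bound (`max_radius_um`) is a hard geometric cap,
  not a learned cell boundary; in dense tissue neighbouring territories
  simply tile the space between nuclei.
* Distances are centroid-to-nearest-vessel-voxel. Membrane-to-membrane
  distances would shift every value down by roughly one cell radius; with
  the 18 um rule this changes individual memberships near the boundary.
  The choice is recorded in the interaction matrix metadata.
* `estimate_diameters` reports the mean over ridge voxels in each region,
  so within a region it is vessel-length-weighted, not vessel-count-
  weighted.
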