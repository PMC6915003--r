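---
title: "Validating MR-based attenuation correction with digital phantoms"
author: "acval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating MR-based attenuation correction with digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acval)
```

## The problem

PET quantification stands or falls with attenuation correction (AC). On a
PET/CT system the CT image provides, after an energy conversion, a voxelwise
map of 511 keV linear attenuation coefficients (LACs, here always mm⁻¹).
A simultaneous PET/MR system has no transmission measurement: MR signal
reflects proton density and relaxation, not electron density, so the μ-map
must be inferred. The widespread vendor approach segments a two-echo Dixon
water–fat acquisition into four classes — soft tissue, fat, lung, air — and
assigns each a predetermined LAC (0.096, 0.080, 0.032 and 0 cm⁻¹). Bone is
not among the classes: it is silently treated as soft tissue, which makes
bone the canonical failure mode of segmentation-based MRAC. A second
complication specific to PET/MR is the rigid hardware in the field of view
(patient-bed track, bed, spine and head coils): these attenuate annihilation
photons but are invisible to MR, so CT-derived templates of them are
hardcoded into the reconstruction.

`acval` rebuilds the validation machinery for this situation at desk scale:
fully synthetic phantoms, a 2D emission simulation in which attenuation is
the *only* physics effect, OSEM reconstruction whose AC μ-map is the single
experimental knob, and the quantification statistics used in PET/MR
acceptance work — NEMA-style cylinder uniformity, circular-ROI SUV means,
50 %-isocontour lesion VOIs, relative differences between AC arms, and
paired tests on their magnitudes.

## Attenuation models

Three μ-maps are compared, all derived from the same ground-truth tissue
labels:

* **Continuous CT** (`huToLac`). A CT image in Hounsfield units is mapped
  through the standard two-segment ("bilinear") conversion:
  LAC = 0.0096·(1 + HU/1000) mm⁻¹ below 0 HU (floored at zero) and
  0.0096 + 5.1×10⁻⁶·HU mm⁻¹ above. A single linear segment cannot pass
  through air, water and bone simultaneously; the two-segment form is the
  accepted realization of a "linear" CT conversion. Since no scanner CT
  exists here, `synthCtFromLabels` *inverts* this mapping on the
  ground-truth LACs (optionally adding seeded Gaussian HU noise), so the
  continuous-CT arm reproduces the true μ-map to within 10⁻⁶ mm⁻¹ — it
  plays the role of the reference arm.
* **Segmented CT** (`segmentCtLac`). LAC thresholds at 0.003, 0.009 and
  0.011 mm⁻¹ assign air (0), fat (0.008), water (0.0096) and bone
  (0.0161 mm⁻¹); lung regions are overridden to 0.0032 mm⁻¹ afterwards.
  The printed ranges of such rules overlap at their endpoints; we adopt
  half-open bins [lo, hi) with bone as [0.011, ∞), which is unambiguous and
  makes the operation idempotent (each assigned value falls inside its own
  bin). The lung override must come after binning because 0.0032 itself
  lies inside the fat bin. The lung mask comes from the phantom's
  ground-truth labels; no lung segmentation is modeled.
* **MRAC** (`mracMuMap`). The four-class table applied to the labels: fat,
  lung and air keep their class values; soft tissue, liver, lesions *and
  bone* all receive 0.0096 mm⁻¹. Patient tissue therefore never exceeds the
  water value — the structural source of bone under-attenuation. Hardware
  is composited in from its ground-truth template when requested, emulating
  the hardcoded hardware maps; truncation completion is an explicit no-op
  (`completeTruncation`) because no truncation is simulated.

All LACs are held internally in mm⁻¹; class tables stated in cm⁻¹ are
converted once at the table boundary.

## Phantoms and their ground truth

`makeCylinderPhantom` builds the uniform 20 cm cylinder (soft-tissue
interior, unit activity) with optional hardware: track and bed as slabs
below the phantom (LAC 0.020 mm⁻¹, an aluminum-like magnitude), spine and
head coils as thin shells (0.012 mm⁻¹). Hardware LACs are not published for
any scanner; the experiments only require hardware attenuation to be
material, and both values are configurable. The configurations are
cumulative — each is a strict superset of the previous — mirroring how
hardware is added to a scanner bore.

`makeBodyPhantom` builds a transaxial body slice: an elliptical body with an
8 mm subcutaneous fat rim, two lungs, a liver analog, a vertebra analog and
FDG-avid lesions in soft tissue and in/around bone. Ground-truth LACs are
lung 0.0034, fat 0.0086, soft tissue/liver/lesion 0.0100 and bone
0.0161 mm⁻¹. Two of these choices are deliberate. Soft tissue sits slightly
*above* the 0.0096 water value used by both segmented methods, so the
segmented-CT arm shares the MRAC soft-tissue bias — which is exactly why
MR-vs-segmented-CT differences (RD2) should be smaller than
MR-vs-continuous-CT differences (RD1) in soft tissue. Lung sits slightly
above the 0.0032 class value (a lung density near 0.35 g/cm³), so
segmentation under-corrects lung mildly as it does soft tissue. Bone equals
the segmented-CT bone value, so in bone the two reference arms nearly agree
and the MRAC deficit dominates both RDs equally. Relative uptake defaults
are soft 1.0, liver 1.2, lung 0.3, fat 0.4, bone 0.6, lesions 4.0. For
cohort emulation, lesion position, radius (5–10 mm soft, 4–7 mm bone) and
uptake (3–5×) are drawn reproducibly from the phantom seed, with soft
lesions constrained to soft tissue/liver and bone lesions centered just
inside the vertebra rim.

The axial dimension carries no physics in this 2D setting: the five
analysis planes of the uniformity layout are simulated as independent
replicate slices and stacked, rather than reconstructing a full 3D volume
whose extra slices would never be read.

## Projection, noise and reconstruction

The forward model is an exact parallel-beam Radon transform: compiled
Siddon-style traversal accumulates per-pixel intersection lengths, and the
backprojector scatters with identical weights, so the pair is an exact
adjoint (the test suite checks ⟨Px, y⟩ = ⟨x, Pᵀy⟩ to 10⁻¹⁰ and compares
against an independent brute-force slab-clipping integrator written in R).
We chose exact intersection over interpolated ray sampling because it is
equally fast in compiled code and removes interpolation bias entirely,
which keeps the oracle comparison sharp. Rays that run exactly along a
pixel boundary (axis-aligned angles on even grids) are a measure-zero
degeneracy; both implementations resolve them with the same explicit
convention (a 10⁻⁹ mm bias toward the upper cell).

Emission data are Poisson draws around expected counts = line integrals of
activity × Beer–Lambert factors of the *true* μ-map, rescaled to a target
total (default 5×10⁶ counts per slice; a scanner count level cannot be
mapped to desk scale without a sensitivity model, so this is a free,
recorded parameter). Scatter, randoms, normalization, decay, dead time and
time-of-flight are deliberately absent: the studies compare AC methods on
otherwise identical data, and attenuation is the only effect that differs
between arms.

`osemReconstruct` implements attenuation-weighted OSEM with the clinical
protocol as defaults: 20 subsets, 3 iterations, 256×256 matrix at 2.4 mm,
3 mm FWHM Gaussian post-filter. Angles are assigned to subsets by stride in
fixed order; initialization is 1 inside the inscribed field of view; zero
expected-count bins follow the 0/0 → 0 convention; subset sensitivities are
precomputed, and a subset with zero sensitivity is an error. The post-filter
is a separable sampled Gaussian divided by the blurred all-ones image, so
constants are preserved exactly and interior mass to machine precision.
Everything is deterministic given the sinogram.

## Quantification

ROI membership is by voxel-center-in-circle, with no partial-volume
weighting — simple and exactly testable. Slice uniformity is the larger
absolute relative deviation of the extreme peripheral 60 mm means (B1–B4)
from the central 120 mm mean (A1):
max(|max B − A1|, |min B − A1|)/A1. The printed form of such statistics
lists two signed terms under a max; we take the larger magnitude, since a
signed max would score large negative deviations as "good". Whole-image
uniformity is the maximum over the five planes (center, ±30, ±60 mm). The
B circles sit at ±45 mm along the two grid axes — an axial cross that keeps
60 mm circles inside the 200 mm phantom with margin; positions are
configurable since published diagrams of this layout are schematic.

Lesion VOIs use the 50 % isocontour of the regional maximum, inclusive
threshold, restricted to the connected component containing the maximum
(8-connectivity, via `EBImage::bwlabel`). SUV scaling is activity ×
weight / dose; under the simulation convention dose = weight it is the
identity, and all relative differences are scale-free anyway.

## The two studies

`runUniformityStudy` sweeps hardware configurations: per configuration,
Poisson data from the cylinder attenuated by phantom + hardware, OSEM with
an MRAC-style AC map *including* the hardware template, whole-image
uniformity over the five-plane layout. An ablation arm reconstructs the
same data with hardware excluded from AC, which measurably degrades
uniformity — the property the hardware templates exist to prevent. At the
default count level all four configurations land well under the 10 %
system requirement (about 0.9–1.8 % across seeds).

`runAcComparison` emulates the patient comparison with (by default) 30
seeded body phantoms: one emission simulation per replicate with the true
μ-map, then one reconstruction per arm differing only in AC. Within a
replicate all arms consume the identical sinogram, which is the design
point — no tracer-clearance or registration confounds, only AC. Per target,
RD1 = (SUV_MR − SUV_CT)/SUV_CT and RD2 = (SUV_MR − SUV_CTSeg)/SUV_CTSeg;
per group, Pearson's r between arms, mean ± SD of the RDs, and a paired
t-test on |RD1| − |RD2| (the paired structure of the design makes the
paired test primary; a one-way ANOVA across arms answers a different
question and is not shipped as the headline statistic). The paired test
guards the degenerate zero-variance case explicitly: all-zero differences
give p = 1, constant nonzero differences an effectively zero p.

What the generator reproduces is the *structure* of the clinical finding,
not its magnitudes: bone RDs are negative essentially always, RD1 ≈ RD2 in
bone (the shared MRAC deficit), and |RD2| < |RD1| — smaller segmented-CT
differences — in soft tissue and soft-tissue lesions. Magnitudes in
normal bone are strongly exaggerated relative to patient studies: the
vertebra analog is small, its uptake low, and iterative reconstruction
concentrates the whole along-ray attenuation deficit into the few voxels
every deficient ray shares, so a −19 %-style clinical bias appears here as
tens of percent. This is the same mechanism that makes percentage errors in
low-uptake bone large clinically, amplified by scale; the studies therefore
assert signs and orderings, never magnitudes.

## Numerical choices and problem sizes

Defaults used by the test suite and the acceptance script: 256×256 grid at
2.4 mm, 180 angles, radial bins at the voxel pitch covering the image
diagonal, 5×10⁶ counts per slice, OSEM 20×3 with a 3 mm filter; the
uniformity study runs 4 configurations × 5 planes and the comparison study
20–30 replicates × 3 arms. One reconstruction takes on the order of a
second on a single core. Unit tests exercise the same code paths on
64–128-voxel grids. All randomness flows through explicit integer seeds
(phantom seed, per-slice and per-replicate sub-seeds derived by a fixed
affine rule), and RNG state is always restored, so every study is a pure
function of its configuration.

## Limitations

No 3D geometry, TOF, scatter, randoms, motion, registration error,
truncation, Dixon simulation or learned lung segmentation — each of these
is either irrelevant to the AC-arm comparison at this scale or explicitly
out of scope. Passing studies here demonstrate that the quantification
machinery and the bias mechanisms behave correctly; they do not predict
patient-level SUV magnitudes, which depend on anatomy, count statistics
and scanner physics that a desk-scale phantom does not carry. The
command-line workflow of a scanner console is likewise out of scope: the
exported functions and the scripts shipped with the source tree are the
interface.
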