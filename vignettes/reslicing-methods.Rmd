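---
title: "Reslicing 3D volumes at 2D reference geometry: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reslicing 3D volumes at 2D reference geometry: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpreslice)
```

## The model

`mpreslice` answers one question: what would a 2D slice with a given
patient-space geometry, slice thickness and through-plane slice profile
have looked like, had it been "acquired" from an available 3D volume?
Its use case is cardiovascular MR, where 3D sequences (e.g. isotropic
3D LGE) must be quantified with 2D post-processing tools and compared
against their established 2D counterparts at the exact same location.

The computation is a two-step interpolation.

**Step 1 — in-plane discretization.** The reference slice's DICOM tags
(ImagePositionPatient, ImageOrientationPatient, PixelSpacing, matrix
size) define pixel centers in LPS patient coordinates:
$\mathbf{x}_{ij} = \mathbf{o} + i\,s_r\,\mathbf{e}_r + j\,s_c\,\mathbf{e}_c$,
with the plane normal $\mathbf{n} = \mathbf{e}_c \times \mathbf{e}_r$
(the standard DICOM normal; an axial slice gets $(0,0,1)$). All
positions refer to pixel/voxel centers, indices are 0-based in formulas.

**Step 2 — through-plane thickness.** A slice thickness $T$ is
represented by $2\,\mathit{num}+1$ parallel planes along $\mathbf{n}$:
$$\mathit{num} = \operatorname{round}\!\left(\frac{T}{2\,z_{res}}\right),
\qquad \mathit{dist} = \frac{T}{2\,\mathit{num}} \;(\mathit{num}>0),$$
where $z_{res}$ is the volume's through-plane resolution (its
inter-slice distance). The offsets $k\cdot\mathit{dist}$,
$k=-\mathit{num}..\mathit{num}$, span exactly $[-T/2, +T/2]$. The
volume is sampled trilinearly at every offset pixel center
($v_{ijk}$), and the samples are totalized under profile weights
$w_k = w(k/\mathit{num})$:
$$\mathrm{value}_{ij} = \operatorname{round}\!\left(
\frac{\sum_k w_k\, v_{ijk}}{\sum_k w_k}\right).$$

The weighted mean models the partial-volume averaging of a thick
slice; the profile models how strongly locations away from the slice
center contribute. At $T = 0$, $\mathit{num}=0$ and only the central
plane is sampled, so the profile provably has no effect — the package
treats this as an invariant and tests all six profiles for bit-identical
output at 0 mm.

## Parameters

* **Slice thickness** (mm): any value in $[0, 99.99]$, or the presets
  `reference_2d` (the reference slice's own SliceThickness tag — an
  absent tag is an error, never silently defaulted) and `volume_z`
  (the volume's $z_{res}$). Thicknesses below $z_{res}$ round to
  $\mathit{num}=0$; they are handled like 0 mm with a warning, since
  the discretization cannot represent them.
* **Slice profile**: one of

  | name | $w(u)$, $u = k/\mathit{num} \in [-1,1]$ |
  |---|---|
  | `rectangular` | $1$ |
  | `triangular` | $1-\lvert u\rvert$ |
  | `cosine_plus_1` | $\cos(\pi u)+1$ |
  | `sinc` | $\sin(\pi u)/(\pi u)$, $w(0)=1$ |
  | `std_normal_2` | $\exp(-(2u)^2/2)$ |
  | `std_normal_5` | $\exp(-(5u)^2/2)$ |

  The analytic forms are package conventions chosen to match the
  profile names: the "standard normal $\sigma$" profiles place the
  profile's $\pm\sigma$ points at the slice borders, which gives
  `std_normal_5` the rapid border decay that makes it the sharpest
  (least partial-volume-affected) option and `rectangular` the
  bluntest — the ordering the blur measure reproduces on the edge
  phantom. Weights are evaluated unnormalized; normalization happens
  in the totalization denominator.
* **Export**: unsigned 16-bit stored pixels (slope 1, intercept 0),
  values clipped to $[0, 65535]$ after rounding; fresh
  SOPInstanceUID/SeriesInstanceUID per export; series number
  `3000 + source series number` by default (the DICOM standard demands
  a *new* number for derived series but prescribes no rule; the offset
  keeps outputs visually grouped with their source study), overridable
  per call or via the CLI.

## Numerical choices

* **Trilinear interpolation** on the regular grid, for both the
  in-plane and through-plane sampling. Linear interpolation is the
  standard for regular-grid resampling, is exactly reproducible by
  hand, and is exact for the validation phantom's piecewise-linear
  value law — which is what makes the phantom's expected values
  computable in closed form.
* **Rounding** is half away from zero everywhere (`round_half_away`),
  both in $\mathit{num}$ and in the final pixel value. IEEE banker's
  rounding would silently change $\mathit{num}$ at exact $.5$
  boundaries (e.g. $T = z_{res}$) and mismatch everyday hand
  calculation.
* **Volume boundary.** A sample is valid iff it lies inside the
  bounding box of the voxel *centers* (no extrapolation; tolerance
  $10^{-9}$ grid units for points exactly on a face). Invalid samples
  are excluded from both sums — i.e. the profile weights are
  renormalized over the surviving samples — rather than zero-filled,
  which would artificially darken the image near the boundary. Pixels
  with no valid sample, *or* whose only valid samples carry zero
  profile weight (possible at the boundary for profiles that vanish at
  $u=\pm1$: triangular, sinc, cosine\_plus\_1), are set to 0 and
  counted in a reported out-of-volume tally so partial overlap is
  visible to the user.
* **Series assembly.** Slices are sorted by the projection of their
  position onto the slice normal, making the loaded volume independent
  of file order; inter-slice gaps must be uniform to a relative
  $10^{-3}$ (loose enough to absorb decimal-string truncation of
  position tags, tight enough to catch a missing slice). Direction
  cosines must be unit and orthogonal to $10^{-4}$ (header tolerance)
  and the derived plane normal is normalized to $10^{-6}$.
* **DICOM layer.** Part-10 uncompressed little-endian single-frame
  files are read (explicit and implicit VR) and written (explicit VR)
  by a small built-in codec; sequences, undefined lengths, compressed
  transfer syntaxes and multi-frame (enhanced) objects are rejected
  with explicit errors. Interoperability is pinned by tests that read
  the package's files with an independent Python DICOM library and
  vice versa.

## The synthetic datasets

**Validation phantom** (`generate_validation_dataset`): an
$11^3$ cube, 1 mm isotropic, iso-center at the volume midpoint; value
constant in x/y, decreasing linearly in z from 100 at the center by 20
per mm to 0 at both borders. Three $11\times11$ reference planes with a
2 mm thickness tag: `parplane` (axial, z = 0), `perplane` (x–z plane at
y = 0, rows along z), and `diagplane` (tilted 45° in y–z through the
iso-center; pixel spacing $1 \times \sqrt2$ mm, its diagonal axis
centered so the 11 positions span the cube's full y–z diagonal of
$10\sqrt2$ mm — the only centering under which those counts and
spacings fit the cube). Every reformatted value of this phantom is
computable by hand; `expected_values_oracle()` does exactly that from
the closed-form value law, sharing no code with the resampler, for
thicknesses 0, 2, 2.82 and 4.23 mm (used verbatim, not "corrected" to
$2\sqrt2$/$3\sqrt2$) under the rectangular profile. At larger
thicknesses the diagplane's border pixels push samples outside the
cube, where results depend on the boundary convention; comparisons
therefore assert interior pixels.

**Edge phantom** (`generate_edge_phantom`): two intensity compartments
(100/400) separated by a sharp planar boundary oblique to the grid, on
a 1.25 mm isotropic grid — the geometry of an isotropic 3D LGE research
acquisition with a scar-like interface — plus mild Gaussian noise
(sd 5) for spectral realism; regeneration under a fixed seed is
bit-identical. Reslicing its middle slice at 0/7/14 mm (7 mm being the
typical 2D LGE slice thickness) blurs the oblique edge progressively,
which the blur measure must track monotonically, and the
`std_normal_5` vs `rectangular` ordering must hold at nonzero
thickness.

What these phantoms do **not** emulate: anatomy, coil-profile shading,
Rician noise statistics, motion or misregistration between the 3D and
2D acquisitions. Passing tests therefore demonstrate geometric and
numerical correctness of the resampling, not clinical image quality;
sharpness statistics on real patient data will differ in magnitude
(though not in the direction of the thickness effect, which is a
partial-volume property).

## The blur measure

`compute_fm()` scores sharpness as the fraction of 2D-FFT magnitude
coefficients strictly above $1/1000$ of the spectral maximum (the
threshold constant follows the measure's standard definition). Closed
forms pin the scale: a constant $m\times n$ image scores $1/(mn)$, a
single-pixel impulse scores 1. The measure is invariant to positive
rescaling of the image but not to adding constants (the DC term moves),
so no such invariance is asserted. Inside the pipeline the measure can
be taken on the pre-rounding floating-point reformat (QC use); the CLI
computes it on stored integer pixels of DICOM files and labels the
basis — both paths are exposed because rounding slightly perturbs the
spectrum.

## Problem sizes

The test suite and acceptance script run entirely on generated data:
the $11^3$ phantom, $48^3$ (and smaller) edge phantoms, and 100+
random volume/plane configurations with volumes up to $16^3$ voxels
checked against a brute-force scalar trilinear oracle to $10^{-9}$.
These sizes keep every hand calculation tractable while exercising all
code paths; the implementation itself is vectorized and handles
clinical matrix sizes (e.g. $256^2 \times 144$ at three thicknesses
and six profiles) in seconds.

## Known limitations

* Single-frame DICOM only; enhanced multi-frame objects are rejected.
* No compressed transfer syntaxes; no DICOMDIR or network services.
* Time-resolved (4D) data are not handled; reslice each phase's series
  separately if needed.
* The in-plane pixel is sampled at its center only — no supersampling
  of the pixel's rectangular footprint, matching the
  single-value-per-pixel totalization formula.
* The volume is never re-gridded: it stays on its native grid and is
  interpolated on demand, so strongly non-isotropic volumes are more
  prone to through-plane sampling error.
* Exports copy patient/study context from the reference slice and
  record the source series in the series description only; modality-
  specific tags (inversion time, etc.) are not propagated.
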