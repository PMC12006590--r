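---
title: "Phantom-based robustness screening of quantitative SPECT radiomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based robustness screening of quantitative SPECT radiomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spectrad)
```

## The problem

Textural-analysis (radiomic) features are only useful clinically if they are
(a) stable under repeat measurement and (b) not merely surrogates for lesion
volume. Recent nuclear-medicine guidelines recommend two simple phantom
experiments to screen features before clinical use: a **uniform cylindrical
phantom**, in which a series of growing spherical VOIs probes how each
feature depends on VOI volume when the underlying signal is homogeneous, and
a **"Revolver" insert** — seven syringes at graded activity concentrations
bound into a ring inside a body phantom — whose repeat scans probe
test–retest repeatability in an inhomogeneous, lesion-like object.

`spectrad` implements this protocol end to end for quantitative SPECT of
two radiopharmaceutical profiles (⁹⁹ᵐTc with LEHR collimation, ¹⁷⁷Lu with
medium-energy collimation): phantom simulation, VOI segmentation, a
67-feature texture engine, and the two-stage feature reduction.

## The imaging surrogate

Full projection-domain SPECT simulation (collimator response, scatter,
attenuation, iterative reconstruction) is deliberately out of scope: those
components are hardware- and site-specific and would not transfer. The
simulator works in the image domain:

1. a ground-truth activity concentration map (kBq/ml) is voxelised at
   1.95 mm isotropic spacing by voxel-centre inclusion;
2. it is blurred with an isotropic Gaussian PSF (`psf_fwhm`, default 8 mm
   for the ⁹⁹ᵐTc profile, 12 mm for ¹⁷⁷Lu, reflecting their reconstructed
   resolutions);
3. voxel values are scaled to expected counts by `count_scale` (counts per
   kBq/ml per voxel), Poisson-sampled with an explicit seed, and rescaled;
4. the result is converted to SUV with the phantom mass (1 g/ml water
   equivalence): `SUV = conc × mass / activity`, so a uniform phantom maps
   to SUV 1.

Because sampling happens after the blur, the voxel noise is white with
coefficient of variation `1 / sqrt(count_scale × concentration)`. The
`count_scale` defaults are calibrated in closed form against the reported
uniform-phantom noise levels of the two radionuclides: at the protocol
fills (278 MBq in 6244 ml ⇒ 44.5 kBq/ml for ⁹⁹ᵐTc; 670 MBq ⇒ 107.3 kBq/ml
for ¹⁷⁷Lu), voxel CoVs of 14.3 % and 20.2 % give
`count_scale = 1.10` and `0.23`. `uniform_noise_cov()` re-measures these
from a simulated scan (the package's tests check 14.3 / 20.1 %). This
reproduces the essential ordering — ¹⁷⁷Lu images are noisier and smoother
than ⁹⁹ᵐTc — without pretending to model a specific camera.

What the simulator does **not** emulate: correlated reconstruction noise,
scatter/attenuation artefacts, dead time, decay across consecutive scans
(activity is held fixed per scan), patient motion, and anatomical
complexity. Passing the screens here therefore demonstrates that the
pipeline's statistics behave correctly under controlled noise and
resolution, not that any particular feature is robust on a given camera —
the protocol itself is explicitly centre-dependent.

### Phantom geometry choices

* The uniform cylinder is rendered at its nominal 22 cm diameter, filled to
  the stated 6244 ml (fill height 164 mm); this keeps the integral of the
  concentration map equal to the dispensed activity, which the tests check
  to 2 % rasterisation error.
* Syringes have typical barrel inner diameters (10/12/16 mm for
  2.5/5/10 ml), lengths set by volume, packed hexagonally and touching,
  axes along the phantom's long axis; the published protocol does not give
  syringe dimensions. The ratio arrangement (which syringe holds 16:1) is
  likewise unstated and is configurable; the default places 16:1 centrally
  with 4:1/8:1 alternating on the ring.
* The body is a NEMA-IQ-style elliptical cylinder (half-axes 150 × 110 mm,
  length 180 mm, ≈ 9.3 l), one insert mounted per simulated phantom.
  Background activities default to the protocol fills (472 MBq ⁹⁹ᵐTc,
  386 MBq ¹⁷⁷Lu).

## Feature catalogue and discretisation

Features are computed on fixed-bin-width discretised SUVs: 64 bins over
SUV 0–20, bin width 0.3125 (reported as "0.3 SUV/bin" at one decimal).
`discretise()` uses the floor rule with boundary clamping; discretised SUV
statistics are computed on bin centres so they stay in SUV units.

The 67-name catalogue (`feature_catalog()`) follows LIFEx v6.3-style naming
in eight families: conventional SUV statistics (13, including two SUVpeak
variants and the TLSRE composite `SUVmean × volume`), their discretised
counterparts (12), histogram features (6), shape (4), GLCM (7), GLRLM (11),
NGLDM (3) and GLZLM (11). Two reconciliation points are worth knowing:

* The published exclusion/retention tables name 68 distinct features while
  stating a 67-feature set. The shipped catalogue omits
  "Discretised SUVmax", the only name that appears exclusively as an
  exclusion; with that choice the table replay reproduces the published
  retained lists exactly, and the loader surfaces the orphan name rather
  than hiding it.
* "Discretised SUV skewness" and "Discretised histogram skewness" are kept
  as separate catalogue entries because the retention tables list both —
  numerically they coincide in this implementation (moments are affine
  invariant, and histogram moments are computed on the same discretised
  sample), which is itself a documented observation, not a bug.

Texture conventions: distance-1 co-occurrences and runs are pooled over the
13 unique 3D directions before normalisation (the merged strategy;
per-direction averaging is the main alternative and is not used); zones use
26-connectivity; the NGLDM aggregates use the standard (Amadasun-style)
coarseness/contrast/busyness with neighbourhoods restricted to the mask and
the coarseness of a uniform region capped at 10⁶. GLCM homogeneity is
`Σ p/(1+(i−j)²)`. Run percentage is normalised by `voxels × directions` so
it stays in (0, 1]. Quartiles use the standard type-7 quantile. Every
family is verified against independent brute-force enumeration (direct
pair/run/zone/neighbourhood walks) on random masked arrays at 10⁻¹⁰
relative tolerance.

Degenerate values (moments of constant regions, GLCM correlation of a
single grey level, pair-based families of single-voxel masks) are returned
as `NA` and listed in the vector's `degenerate` attribute; the CoV screen
treats them as unevaluable rather than as zeros.

### Surface area and sphericity

The mesh surface is a marching-tetrahedra iso-surface of the binary mask
(six tetrahedra per cell, crossings at edge midpoints), with a single-voxel
mask special-cased to its exposed cube faces (6 s²). Two numerical facts
are documented rather than hidden: the binary mesh retains 45° staircase
facets at every resolution, so the surface of a large digitised sphere
converges to 4/π times the smooth-sphere area and sphericity plateaus near
π/4 ≈ 0.785 instead of rising to 1; and compacity uses the
`V / (√π A^{3/2})` convention (V in mm³, A in mm²). Comparisons between
masks of similar processing are meaningful; absolute comparison with
smooth-surface areas is not.

## Segmentation

Two threshold methods are implemented behind one interface
(`segment_voi()`), both returning the 26-connected component containing the
seed:

* `adaptive_background` — threshold 2.5 × mean SUV of a background region
  (default a 30 mm sphere placed in the body background away from the
  insert; the protocol does not state the published region's position).
  This is the guideline method; it is scale invariant by construction.
* `percent_max` — threshold 0.40 × SUVmax within a search radius of the
  seed, the method that produced the published post-threshold VOI volumes.

The pipeline default for the Revolver analysis is `percent_max` (0.40). At
the default 8 mm PSF the blurred 4:1 syringes fall *below* 0.4 × SUVmax, so
the percent-max mask covers the hot core rather than all seven syringes;
the adaptive mask does contain all seven syringe axes and shows the
expected partial-volume inflation (≈ 24 ml segmented for the 17.5 ml
nominal hot volume of the 2.5 ml insert). The seed voxel is snapped to the
hottest voxel within 6 mm so that a noise-depressed voxel at the geometric
centre cannot abort an otherwise valid segmentation; snapping is
deterministic.

## The two screens and the reduction

**Repeatability.** For each feature, insert size and radionuclide, the CoV
(100 × sample sd / |mean|, the conventional test–retest estimator for four
repeats) is computed across the repeat scans; a feature fails if CoV > 10 %
in *any* insert, and per-insert failure counts are reported.

**Volume dependency.** The published screen was visual; `spectrad` replaces
the eyeball with an explicit, configurable rule. With curve range `R`:
a feature is *converging* if every value at volumes ≥ 25 ml lies within
0.10 × R of the tail median (the 25 ml pivot reflects the observation that
converging features settle below roughly that volume); otherwise
*correlated* if the tail trend is monotone (Spearman |ρ| ≥ 0.8), else
*random*. The reported convergence volume is the last curve volume at
which the tail condition still fails. The classifier is validated on 300
constructed curves with planted labels (100 per class, recovered 100 %).

**Reduction.** `reduce_features()` excludes non-converging and
CoV-failing features, except those on an explicit keep-exception list —
features with known or intrinsic volume dependence but established
clinical value (volume, surface area, sphericity, compacity, TLSRE and the
core SUV statistics). The exception list is shipped as data with a
per-feature rationale, not hard-coded. Replaying the published exclusion
tables through the same function retains 39 features for ⁹⁹ᵐTc and 33 for
¹⁷⁷Lu and reproduces the published retained sets exactly; for ¹⁷⁷Lu this
requires rescuing SUVmin, NGLDM contrast and GLZLM ZP, which the
publication flags as CoV failures yet retains — the consistency checker
(`validate_against_tables()`) reports exactly this discrepancy when run
without exceptions.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; repeat series use
`seed, seed+1, …`; `run_experiment()` derives all stage seeds from one
master seed and writes a manifest with an MD5 checksum per output file, so
two runs from the same config are bit-identical (this is tested).

The package's test suite exercises the full protocol geometry where the
quantity demands it (the 29-sphere series, the noiseless full-size insert,
the uniform-phantom noise calibration) and reduced geometries elsewhere: a
60 mm cylinder with a 10-sphere series and a 55 × 45 × 70 mm body for the
end-to-end and noise-ordering checks, chosen so that the statistical
properties under test (determinism, noise monotonicity between
radionuclide profiles, CoV behaviour) are scale invariant. The simulated
noise-ordering check uses five independent four-scan groups per
radionuclide and requires a majority ordering, reflecting that the count
of CoV-failing features is itself a noisy statistic.

## Interfaces

The package is an R analysis library: the exported functions, one
`run_config()`/`run_experiment()` pair, YAML config round-tripping and
NIfTI input/output (`read_voxel_nifti()` accepts externally produced
quantitative SPECT volumes) are the interface; no shell entry point is
provided beyond `scripts/acceptance.R`, since the intended users drive the
pipeline from R.

## Known limitations

* Image-domain surrogate only; no scatter, attenuation, reconstruction
  correlations or decay between repeats.
* Staircase bias in mesh surface area (above); shape features are
  internally consistent but not comparable to smooth-surface conventions.
* The volume-dependency rule is a formalisation of a visual judgement; its
  two parameters (25 ml pivot, 10 % tail tolerance) are config, and
  different choices will move borderline features between labels.
* Feature robustness conclusions from simulation transfer to real systems
  only as far as the noise/resolution surrogate does; the protocol is
  explicitly centre-dependent.
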