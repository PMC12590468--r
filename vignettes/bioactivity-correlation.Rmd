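---
title: "Compound-resolved bioactivity correlation for micro-fractionated LC-MS runs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound-resolved bioactivity correlation for micro-fractionated LC-MS runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biospot)
```

## The measurement model

biospot analyses experiments in which the eluate of an LC run is split
post-column: a minor share goes to the ESI source for MS1/MS2
acquisition, the rest is deposited at high frequency (around 1 Hz, the
same order as the MS/MS duty cycle) onto the wax-printed circles of a
paper-based analytical device (uPAD), one fraction per circle, following
a serpentine path so that consecutive fractions stay spatially adjacent.
After drying, the uPAD is overlaid with a luciferase bioreporter strain:
fractions containing antibacterial compounds induce a stress promoter
and emit light, sometimes as an annular halo at sublethal concentrations
in the diffusion gradient around an inhibition zone.

Three signals therefore share a single retention-time axis:

* per-fraction **bioactivity**, read densitometrically from the
  luminescence image;
* **MS1 features**, (m/z, RT) entities with Gaussian-ish elution
  profiles;
* **MS2 spectra**, data-dependent fragmentations with precursor m/z.

A compound is a candidate for the observed bioactivity when its feature
apex matches the bioactivity peak apex up to a systematic bias within a
tolerance window, *and* its elution profile has the same shape as the
bioactivity peak.  The shape score is the Pearson correlation between
the activity values across the peak and the feature profile interpolated
onto the same fraction times; candidates with $r$ strictly above a
threshold (0.8 by default) are kept and ranked per activity peak.

## Stage by stage

### Image densitometry

`analyze_upad_image()` measures each fraction as the **mean pixel
intensity** of a disk at the spot center, quantifies halos when present,
and normalizes by the **median activity of the image** so different
images and samples are comparable.  The steps, each exposed separately:

1. `detect_candidate_spots()` segments bright blobs above a robust
   threshold (median background + the larger of a dynamic-range fraction
   and four robust noise SDs).  Dark, inactive fractions are invisible
   here by design.
2. `fit_spot_grid()` fits origin plus two lattice basis vectors (pitch
   and rotation jointly) by least squares, iterating
   assignment/refit.  Centers of dark spots are imputed from the
   lattice.  When whole border rows are dark, candidate indices alone
   cannot anchor the window, so the anchor maximizing the border margin
   inside the image is chosen; 2--4 manual corner hints are an explicit
   fallback for nearly-blank images.
3. `enumerate_spots()` assigns serpentine fraction indices (row A
   left-to-right, row B right-to-left, ...) and labels (`"K3"`).
4. `measure_spot_intensity()` uses a disk of 0.8 spot radii by default,
   keeping the wax rim out of the measurement.
5. `measure_halo()` takes the median radial intensity profile in 1-px
   annuli and reports the outermost radius of a contiguous band above
   background + `k_mad` robust SDs.  The band must be *detached* (the
   profile drops below the threshold at least once beyond the
   measurement radius first) so the tail of a bright spot is never
   counted as a halo; absence is a valid result.
6. `compute_activity()` forms the fraction's activity as the sum of
   luminescence and halo size.  The two are not commensurate (intensity
   vs length), so the halo diameter is expressed in pitch units and
   scaled by the image's median spot intensity:
   $a = \bar I + w \cdot \frac{2 r_\text{halo}}{\text{pitch}} \cdot
   \tilde I$.  With $w = 0$ this reduces to pure densitometry.  The
   exact rule the original readout software uses is not published; this
   commensuration is this package's documented choice.
7. `normalize_by_median()` divides by the per-image median; when one PAD
   is imaged in blocks, normalization happens per image *before*
   `merge_spot_tables()`, since illumination and exposure vary per
   image.  (Whether the reference implementation normalizes per image or
   per PAD is ambiguous; per image is the safer choice under varying
   exposure.)

### Bioactivity chromatogram

`assign_retention_times()` maps fraction $i$ (0-based) to
$t_i = t_0 + (i + 0.5)/(60 f)$ minutes — the midpoint of its
$1/f$-second collection interval, an unbiased stamp; only the coverage
window is fixed by the experiment ($n/f$ seconds from $t_0$; 500
fractions at 1 Hz cover 8 min 20 s), the midpoint-vs-start choice
within a fraction is a convention and is documented as such.  Fractions
before $t_0$ (the dead time) go to waste and are simply absent.

`smooth_chromatogram()` applies a discrete Gaussian kernel with
$\sigma = 1$ in fraction units by default, truncated at $4\sigma$,
renormalized to unit sum, with reflect boundaries — flat traces pass
through unchanged and total signal is conserved for symmetric traces.

`detect_activity_peaks()` picks local maxima by prominence (default
0.5 on the median-normalized scale, where the baseline sits near 1, and
a minimum base-to-base width of 2 fractions).  Peak bounds are the
crossings of the prominence-base level (height minus prominence)
nearest the apex, clipped at the valley toward an adjacent detected
peak: the classical prominence bases of the tallest peak would span the
whole trace and ruin both the AUC and the shape correlation.  The AUC
is the baseline-inclusive trapezoid between the bounds, the
semiquantitative activity measure.  The reference peak-picker's
parameters are unpublished; these defaults are this package's own and
are configurable.

### LC-MS features

`read_mzml()`/`write_mzml()` implement a minimal mzML 1.1 subset
(centroided MS1/MS2, 32/64-bit little-endian peak arrays, optional zlib
compression, scan times converted to minutes on read) because no mzML
reader is available in this R environment.  Feature detection is a
deliberately minimal mass-trace algorithm — `build_mass_traces()`
greedily chains centroids whose m/z stays within `ppm_tol` (10 ppm) of a
trace's running mean, tolerating `gap_scans` (1) missed scans, and
`detect_feature_peaks()` finds elution apexes by prominence (10% of the
trace apex) with bounds at the prominence-base crossings.  It replaces
the delegated external untargeted workflow used upstream of the original
correlation step; `read_feature_table()` imports features from any such
external tool instead, with profiles reconstructed from XICs
(`fill_feature_profiles()`), so the correlation logic is agnostic to the
feature source.  Adducts, isotope envelopes and charge states are not
modelled: features are (m/z, RT) entities.

### Gating, correlation, ranking, export

`correlation_config()` holds the decision parameters:

| parameter | default | meaning |
|---|---|---|
| `rt_bias` | 0 s | feature apex minus activity apex for a true co-elution; calibratable, may be negative |
| `rt_window` | 10 s | allowed deviation of the apex offset from the bias |
| `r_threshold` | 0.8 | retained results must be **strictly above** this Pearson r |
| `min_overlap_points` | 5 | minimum fraction samples under the peak |
| `mz_tol_ms2` | 0.01 | precursor matching tolerance for the MS2 export |

The split-flow path lengths to the spotter and to the ESI source
differ, so the bias is an instrument property the user calibrates; its
default of 0 and the 10-s window are this package's choices, not
published values.  The correlation grid is the activity chromatogram's
own fraction times inside the peak bounds (the coarser, fixed-rate
signal keeps its samples); the feature profile is shifted by the bias
and linearly interpolated onto that grid, zero outside its own support.
A constant vector makes the Pearson correlation undefined; such pairs
are excluded rather than scored 0.  Ties in $r$ rank by smaller
absolute RT offset, then lower m/z.  Because one compound may plausibly
explain several activity peaks, results are grouped and ranked per
activity peak, not globally.

`filter_ms2_for_networking()` writes an mzML holding exactly the MS2
scans whose precursor lies within `mz_tol_ms2` of a retained feature and
whose RT falls inside that feature's elution bounds — the
molecular-networking-ready output.  Networking itself is external.

## The synthetic world

All tests run on generated data; `generate_linked_dataset()` drives
both modalities from shared planted compounds.  Defaults mirror the
validation-mixture conditions: 200 fractions at 1 Hz from 1.00 min
(coverage to 4.33 min), imaged as two 10 x 10 blocks with 20 px pitch
and 5 px spot radius; compounds elute as Gaussians with
$\sigma \approx 0.04$--$0.05$ min (a few seconds, as expected for
UHPLC peaks sampled at 1 Hz); per-fraction activity is
$1 + g \int I(t)\,dt$ over the fraction's collection interval
(bioreporter response linear in deposited amount, baseline 1 on the
median-normalized scale), with 5% multiplicative assay noise;
luminescent spots are Gaussian blobs plus optional annular halos,
background gradient and additive image noise; decoy features get random
m/z (tolerance-disjoint) and random apexes kept at least 30 s away
from active compounds.  Saturation of the bioreporter response (the
plateau a real dose-response reaches) is deliberately not modelled —
it matters for limit-of-detection studies, which are out of scope.

What a green test therefore establishes: the pipeline recovers planted
truth under idealized Gaussian peaks, linear response and well-separated
decoys.  What it does not establish: robustness to chromatographic
tailing, detector saturation, droplet spreading, isotope structure or
co-eluting shape-correlated compounds, none of which the generator
emulates.

## Numerical choices and degenerate inputs

* Pixel origin is top-left; pixel $(i, j)$ sits at $x = j$, $y = i$;
  rows are lettered top-down, columns numbered left-right, serpentine
  starts at A1.
* RGB images collapse to luminance by channel mean; gray-value
  inversion is explicit (`invert = TRUE`), never auto-detected.
* A blank image (median activity 0) is a validation error, not a
  silent all-zero table; overlapping or gapped serpentine ranges refuse
  to merge.
* Boundary elution apexes (a trace still rising at its last scan)
  count as features, with the prominence taken from the one available
  side.
* All RT handling is in minutes internally; gate and bias arithmetic
  in seconds, converted exactly at the comparison.
* Generators are pure functions of (parameters, seed); the package
  never touches the caller's RNG state.

## Limitations

Densitometry assumes an approximately rigid lattice (rotation and
translation; no lens distortion or flat-field correction).  One
bioreporter strain per PAD is assumed; joint modelling across reporter
panels is out of scope.  The mass-trace finder is intentionally minimal
— for complex biological matrices, import features from a full
untargeted workflow via `read_feature_table()` and let biospot do the
gating, correlation and export.
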