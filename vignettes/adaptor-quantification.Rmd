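---
title: "Quantifying dynein-adaptor assays: models, parameters, and design choices"
author: "adaptorquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynein-adaptor assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptorquant)
```

# Scope

Characterizing a candidate dynein activating adaptor such as KASH5 rests on
four quantitative assays: single-molecule TIRF motility of dynein-dynactin-
adaptor complexes on microtubules, enrichment of dynein at the nuclear
envelope (NE) in cells co-expressing the adaptor and its SUN-domain partner,
intensity of dynein/dynactin foci at NE-tethered telomeres on spermatocyte
spreads, and direct binding measurements (ITC affinity, SEC-MALS
stoichiometry) between the adaptor and the dynein light-intermediate chain
(LIC). The raw movies and images behind such studies are rarely deposited,
so every analysis pipeline in this package is paired with a synthetic-data
generator that exports complete ground truth. That pairing is the package's
validation strategy: each pipeline must recover known generating parameters
end to end before it is trusted on real data.

# Single-molecule motility

## Model and procedure

A movie is a calibrated `H x W x T` intensity stack. For each user-supplied
microtubule polyline, `build_kymograph()` resamples the movie into a
time-by-arclength matrix: bin size equals the pixel size, and each cell is
the *maximum* intensity over an odd-width transect perpendicular to the
path, interpolated bilinearly at sub-pixel positions. The maximum (rather
than the mean) over the default 5-pixel transect preserves dim moving spots
that wander off the digitized path centerline by a pixel.

`trace_events()` is a conventional detect-then-link tracker. Per frame,
local maxima above a robust threshold (`median + 6 * mad` of the kymograph
by default) are detected with a minimum mutual separation; detections are
linked greedily to the nearest open track within `max_jump` bins per frame,
tolerating up to `max_gap` missed frames (interpolated linearly). Final
positions are intensity-weighted centroids over a +/- 3-bin window after
median-background subtraction, which gives sub-bin localization. Events
touching the first or last frame are flagged censored; they contribute to
counts but their run lengths are truncated observations, and downstream
summaries can exclude them.

Classification uses three thresholds that the source assays do not print,
so they are explicit, documented defaults here (`classify_params()`):
processive requires net displacement >= 0.4 um with >= 70% of
frame-to-frame steps in the net direction; immotile means total excursion
<= 0.2 um; anything else is diffusive. At 0.16 um pixels with sub-pixel
centroiding these separate the three generated behaviours cleanly; all
three are tunable and any re-analysis should report them.

Filtering mirrors the assay's stated rules: runs spanning <= 4 frames are
excluded (at the 300 ms interval this is exactly the 1.2 s duration
threshold, since a 5-frame event spans 4 intervals), and bright aggregates
are excluded as events brighter than 3x the median event intensity of the
field. The frame-count rule is primary; the seconds value is derived, so at
the 500 ms immunoprecipitate interval the same 4-frame rule corresponds to
2.0 s. Velocity is net displacement magnitude divided by duration; whether
the original analysis excluded pauses is not stated, and the net convention
is the declared choice here.

The landing rate divides the number of kept events by total microtubule
length (um) times movie duration (min), and additionally by motor
concentration (pM) when given; percent processive is the processive share
of kept events.

## What the generator emulates

`simulate_tirf_movie()` lands particles on paths as a Poisson process,
draws per-event class, speed (normal or lognormal), and exponential run
length, and renders 2-D Gaussian spots (sigma 0.13 um, typical for 1.49
NA/100x TIRF optics) over Gaussian camera background. Pixel size defaults
to 0.16 um — a typical EMCCD-at-100x value, declared rather than inferred,
and configurable everywhere. Diffusive particles random-walk along the path
with reflecting ends; photobleaching is exponential survival per frame and
off by default. The generator does not model EMCCD gain noise, spot shape
anisotropy, stage drift, or off-path landing, so pipeline recovery on these
movies demonstrates correctness of the measurement chain, not robustness to
every artifact of real data.

# Nuclear-envelope enrichment

Per cell, the nucleus ROI comes from Otsu thresholding of the DAPI channel
(largest filled components; threshold overridable), while cell boundaries
are accepted from provided masks, as in manual tracing. The NE value of a
channel is its mean gray value in a band extending 1 um on either side of
the nuclear boundary — morphologically, `dilate(nucleus, r) XOR
erode(nucleus, r)` with a disk of radius `r = 1 um / pixel_size`. The
cytoplasmic value is the mean over the cell mask minus the nucleus dilated
by 1 um, so band and cytoplasm are disjoint by construction. The enrichment
score is the NE/cytoplasm ratio, which is invariant to multiplicative gain
but *not* to additive offsets — background-subtracted or offset-shifted
images will change ratios, and the tests document this deliberately.

Cell inclusion follows fixed raw-gray-value rules per transfection
condition: full-length (or point-mutant) KASH5 cells require KASH5 mean
>= 250; SUN1-only and KASH5-dTM cells require SUN1 mean >= 200; KASH5-dTM
cells additionally require whole-cell KASH5 >= 220. Two details are
declared choices: the 250 rule is computed over the whole-cell mask
(matching the explicitly whole-cell 220 rule), and thresholds are strict
("less than" excludes), so boundary-value cells are included. The
synthetic cell field paints the perinuclear band with the same mask
algebra the measurement uses, which makes the noiseless ratio identity
exact and keeps the noisy-field recovery test meaningful.

# Telomeric focus quantification

Telomeric regions are the ends of the SYCP3 axis signals. With polyline
axis traces the endpoints are immediate; with an image the axes are
thresholded, thinned (Zhang-Suen), and skeleton endpoints are refined to
sub-pixel precision by walking outward along the local axis direction to
the half-maximum intensity crossing — the edge response of a PSF-convolved
line end. Closed-loop skeletons have no endpoints and are flagged, never
silently dropped.

Each focus is measured as the mean in a disk aperture (default radius
0.4 um) minus the mean in a local annulus (0.5–0.8 um), excluding annulus
pixels claimed by neighbouring apertures; the original inspector tool's ROI
geometry is unknown, so the disk aperture is a declared choice sized to
diffraction-limited foci. Background is per focus, corrected intensities
may be negative and are *not* clipped (clipping would bias means upward),
and normalization divides by the mean corrected intensity of a reference
set (GFP-negative cells, or the wild type), which therefore normalizes to
exactly 1.0. Corrected intensities are invariant to adding a constant to
the plane; normalized intensities are additionally invariant to gain.

# Binding

## ITC

`isotherm_heats()` implements the single-site independent-sites isotherm
with the perfusion (displacement-volume) convention: each injection of
volume `dV` into cell volume `V0` dilutes existing contents by
`1 - dV/V0` while delivering syringe ligand at `dV/V0`; bound complex
comes from the single-site quadratic at the running totals, and the heat of
injection *i* is `dH * V0 * (B_i - B_{i-1}(1 - dV/V0))` plus a constant
baseline. The instrument manuals do not fix the bookkeeping convention, so
it is validated against an independent stoichiometric-limit oracle in the
tests. The default protocol is 550 uM ligand into 50 uM macromolecule,
10 ul injections, 200 ul cell, 20 C. Simulated noise defaults used in the
recovery tests are 0.05 ucal per injection — conservative (larger) relative
to integrated power noise of a modern low-volume calorimeter. Fitting is
Levenberg-Marquardt over `(N, K_d, dH, baseline)` with positivity bounds on
N and K_d; flat thermograms raise an identifiability error instead of
returning a spurious K_d, and fits outside a c-value of 1–1000 warn.

## SEC-MALS

In the dilute low-angle limit, excess Rayleigh scattering is proportional
to `concentration x molar mass x (dn/dc)^2` with dn/dc = 0.185 ml/g for
protein; the instrument optical constant is folded into calibrated units
because only relative and round-trip accuracy are testable without the
physical instrument. `mals_mass()` inverts this per elution point and
returns the concentration-weighted mean over the peak window, ignoring
points below 5% of the peak concentration. `infer_stoichiometry()`
enumerates all copy-number combinations up to `max_copies`, ranks by
relative residual with ties broken toward fewer total copies, and flags
calls within tolerance as consistent. Monomer masses are external,
sequence-derived inputs; the package ships the values for the KASH5-NCC
construct (38.45 kDa) and full-length LIC1 (56.6 kDa), for which the 2:1
complex gives 133.5 kDa against a measured 139 kDa.

# Group statistics

`compare_groups()` fixes the procedure choices used across the assays
rather than new statistics: Kruskal-Wallis followed by Dunn's pairwise
z-tests (tie-corrected rank variance, Bonferroni adjustment) for
single-molecule velocity and run-length data, and Welch's heteroscedastic
ANOVA (with the Brown-Forsythe F reported alongside) followed by pairwise
Welch t-tests for landing-rate and percent-processive data. Dunnett's T3
proper uses the studentized maximum modulus distribution; the Sidak-on-
Welch-t form used here is a standard approximation and is slightly
conservative, which is documented rather than hidden. Significance tiers
are a pure function of the adjusted p-value and the 0.05/0.01/0.001/0.0001
cutoffs. Quantiles use type-7 linear interpolation so that medians and
IQRs are reproducible against mainstream plotting software.

# Numerical conventions and degenerate inputs

* Frames and arclength bins are 0-based; event frame spans are inclusive;
  kymograph bin `j` is sampled at arclength `j` pixels, so an emitter at
  arclength `s` falls in bin `floor(s / bin_size)`.
* Duration is `(end_frame - start_frame) * frame_interval` (span of
  intervals, not of frames).
* One top-level seed determines every generated output bit-for-bit; all
  stochastic draws happen in a fixed vectorized order before rendering.
* Empty inputs fail loudly (empty path lists, all-dark nucleus planes,
  empty references, occluded annuli) rather than returning NA.
* Classification order: the processive rule is tested first, then
  immotile; the two cannot both hold because net displacement never
  exceeds excursion.

# Problem sizes

The validation suite runs entirely on synthetic data generated at call
time. The velocity-recovery benchmarks use ten 48-um paths in a
220 x 320 px field over 3 min (about 350 landed events, of which roughly
250 survive tracing and filtering); ITC recovery uses 20 noise seeds on a
19-injection titration; the spermatocyte benchmark uses 7 mutant cells x
20 foci (140 foci) plus matched GFP-negative reference cells. These sizes
give Monte-Carlo error comfortably inside the recovery tolerances (5% on
median velocity, 15% on K_d, 5 percentage points on normalized focus
intensity) while keeping the whole suite to a couple of minutes.

# Known limitations

* The tracker links greedily; two particles crossing on the same
  microtubule within the linking radius can swap identities. At the
  simulated occupancies this is rare and does not move medians.
* NE quantification assumes convex, non-touching nuclei in the provided
  masks; densely packed fields need curated masks.
* The ITC model is strictly single-site; multi-site or cooperative
  isotherms are out of scope, as is band-broadening correction between
  MALS detectors.
* Gray-value inclusion filters are instrument-specific absolute
  thresholds; they only transfer to data acquired at matched gain and bit
  depth.
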