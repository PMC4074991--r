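---
title: "Methods: atlas-based activation mapping for awake-mouse BOLD fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atlas-based activation mapping for awake-mouse BOLD fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Awake-mouse BOLD fMRI provocation studies compare brain activity across
experimental groups — here, genotypes of a Huntington's-disease mouse model
(wild-type, heterozygous, homozygous mutant) — in response to a block-design
stimulus such as an odor or a CO~2~ challenge. A session is a 4D series of
whole-brain volumes: by default 70 acquisitions at 6 s each (420 s), with the
first 25 repetitions serving as the control window and repetitions 26–50 as
the stimulation window. Post-stimulation acquisitions (51–70) enter neither
window and are excluded from testing.

The pipeline implemented here covers, end to end:

1. **Motion QC** — per-frame 6-DOF rigid-body estimation relative to frame 1,
   reporting displacement as the Euclidean norm of the translations in µm
   (rotations are reported separately, since the field's QC criterion for
   acclimated animals — mean displacement below ~20 µm — is expressed as a
   length).
2. **Atlas registration** — a 9-parameter affine (translation, rotation and
   scaling independently in all three dimensions) mapping each subject's
   anatomy into the space of a segmented label atlas; the inverse transform
   is stored and used to carry atlas labels back into subject space.
3. **Voxel-wise activation** — per-voxel percent BOLD change between the
   stimulation- and control-window means; Welch (heteroscedastic, two-tailed)
   t-tests between the two windows; Benjamini–Hochberg FDR control at
   q = 0.05 over in-mask voxels; and a 2% baseline threshold on percent
   change, accounting for normal fluctuation of the BOLD signal in the awake
   rodent brain. A voxel is significant only if it passes *both* filters and
   the change is positive.
4. **ROI statistics** — per-region activated-voxel counts normalized to each
   subject's own region size (normalized volume of activation, in percent);
   Kruskal–Wallis omnibus tests with pairwise Mann–Whitney U follow-ups
   across genotypes; one-way ANOVA with Fisher's protected LSD for regional
   brain volumes; and mixed repeated-measures ANOVA for ROI time courses.
5. **Synthetic data** — phantom atlases and sessions with known ground truth,
   so every stage is testable without any external download.

Statistical testing is performed in each subject's original coordinate
system; the resulting maps (not the raw series) are resampled into atlas
space for composites and ROI aggregation.

# Models and formulas

**Percent change.** For a voxel time series $x_t$,
$\Delta\% = 100\,(\bar{x}_{\mathrm{stim}} - \bar{x}_{\mathrm{ctrl}})/\bar{x}_{\mathrm{ctrl}}$.
Voxels with non-positive control means cannot be expressed as a percent
change and are masked out (flagged, not an error).

**Voxel test.** Welch's two-sample t-test between the stimulation-window and
control-window samples, with the Satterthwaite degrees-of-freedom
approximation and two-tailed p-values. The per-voxel computation is
vectorised over the whole volume; tests verify it against `stats::t.test`
voxel by voxel. A voxel with zero variance in both windows and equal means
is assigned t = 0, p = 1 by convention.

**FDR filter.** Benjamini–Hochberg step-up over in-mask p-values (via
`stats::p.adjust`). The named cutoff of 0.05 is the target false discovery
rate; the suite checks the implementation against an exhaustively enumerated
step-up oracle and calibrates the realized false-discovery proportion on
null simulations.

**Volumetry.** Voxel volume = width × height × slice thickness; with the
default scanner geometry (FOV 25 mm, 256-matrix anatomical grid, 0.75 mm
slices) this is 0.097 × 0.097 × 0.750 ≈ 0.00706 mm³, and the functional
96-matrix grid gives a 260 µm in-plane dimension. Region volumes are exact
voxel counts times the voxel volume.

**Normalized volume of activation.** Per subject and region,
$\mathrm{VOA}_{\%} = 100 \times (\text{activated voxels}) / (\text{total voxels in ROI})$.
Normalization is per-subject — each subject's activated count over that same
subject's region total — and group statistics (median, max, min) are then
taken over subjects. This resolves an ambiguity between normalizing to a
group-level ROI volume and to the subject's own; the per-subject reading is
the one that makes cross-phenotype comparison meaningful when brain sizes
differ by genotype.

**Group comparisons.** Kruskal–Wallis across the three genotypes per region,
pairwise two-sided Mann–Whitney U tests, with output rows rank-ordered by
omnibus p (ties broken by region id, making the ordering deterministic).
Mann–Whitney uses the exact null distribution when the combined sample size
is ≤ 12 and there are no ties, and the normal approximation with tie and
continuity corrections otherwise. No multiplicity correction is applied
*across* regions; tables report raw omnibus p-values in rank order, and the
documentation flags this as a presentational convention, not an inferential
guarantee.

**Volume comparison.** One-way ANOVA per region on subject volumes, with
Fisher's protected LSD contrasts: pairwise t statistics using the pooled
MSE, computed only when the omnibus p < 0.05 ("protected").

**Time courses.** A region's trace is the mean over its voxels at each
acquisition, expressed as percent change from the baseline-window mean, so
the baseline acquisitions average to zero exactly. Group-level inference is
a two-way mixed ANOVA — genotype between subjects, acquisition within,
subject as the repeated unit — reporting the genotype main effect and the
genotype × time interaction, followed by per-acquisition protected LSD
contrasts. The design is described in parts of the field's literature as a
"repeated measures one-way ANOVA" while reporting an interaction; a one-way
design has no interaction term, so the two-way mixed model is the faithful
implementation, and the package reports its own (correct) degrees of
freedom. No sphericity correction is applied; this is a documented
limitation.

# Registration details

The cost function is 1 minus the Pearson correlation of intensities over the
voxel overlap (normalized cross-correlation), with a penalty when the
overlap falls below 25% of the fixed grid. The optimizer is a deterministic
cyclic pattern search: each parameter is probed at ± the current step,
improvements are kept, and all steps halve when a full sweep yields no
improvement. This was chosen over a Nelder–Mead simplex after observing that
the simplex converges prematurely on the nearly flat NCC landscapes that
arise when the two images are already highly correlated (sub-voxel motion
between frames); the pattern search is also trivially reproducible. A
3-level multiresolution pyramid (block-mean downsampling by 4, 2, 1;
degenerate coarse levels are dropped on small grids) provides capture range.

Conventions: world coordinates are RAS+ mm with the origin at the corner of
voxel (0,0,0); rotations are intrinsic about x, then y, then z; rotation and
scaling act about the physical centre of each grid, so zero parameters align
grid centres. Initial step sizes are 0.4 mm (translations) and 0.04
(radians / scale factors) for subject-to-atlas registration, 0.05 mm and
0.01 rad for frame-to-frame motion; the search refines steps down to 10^-4
of their initial size. Trilinear interpolation is used for intensity images;
nearest-neighbour is mandatory for label volumes (requesting linear on an
integer volume is a contract violation, not a silent cast). Transforms are
serialized as JSON with 17 significant digits, which round-trips doubles
bit-exactly.

Within-subject functional-to-anatomical alignment is assumed exact for
synthetic data; a rigid pre-step (`register_affine(..., rigid = TRUE)`) is
available but off by default.

# The synthetic generator

The generator emulates the study conditions, not MR physics:

- **Geometry** — ellipsoidal brain mask on a configurable grid (default
  48 × 48 × 16 voxels, 25 mm in-plane FOV, 0.75 mm slices), partitioned into
  a configurable number of contiguous regions (default 116) by nearest-seed
  assignment of seeded interior points; every region is non-empty by
  construction. Background (air) voxels are dark.
- **Timing** — 70 × 6 s with control 1–25 and stimulation 26–50 by default;
  a CO~2~-style 50-acquisition session is a timing override.
- **Activation** — a boxcar over the stimulation window smoothed by a
  2-acquisition exponential rise, scaled so its stimulation-window mean
  equals the requested amplitude exactly (this keeps the window-mean
  contrast interpretable and makes noise-free recovery exact by
  construction, rather than biased low by the rise). Amplitudes default to a
  gene-dose grading of 8 / 5 / 2 % BOLD for WT / HET / HOM; these, the 1%
  Gaussian noise SD, and the 0.5% per-session linear drift are engineering
  choices for testability — the source literature reports figure-level
  traces and a 2% fluctuation threshold, not effect-size magnitudes.
- **Noise** — additive Gaussian on intensities. Magnitude-MR Rician
  behaviour is ignored: at the modeled SNR (baseline ≈ 1000 a.u., noise 1%)
  the Rician distribution is indistinguishable from Gaussian.
- **Drift** — linear, random sign per session, ±0.25% about the session
  midpoint at the default amplitude. Small drifts produce genuinely nonzero
  window-mean differences with near-zero p-values; the 2% baseline threshold
  is what keeps them out of the significant set, which is exactly the role
  that threshold plays on real awake-animal data.
- **Motion** — optional per-frame rigid perturbations (off by default, since
  functional-anatomical alignment is assumed exact); an "acclimated" session
  uses a 0.008 mm per-frame translation SD, which keeps mean displacement
  under the 20 µm QC criterion.
- **Cohorts** — default 9 / 9 / 8 subjects for WT / HET / HOM; per-subject
  seeds derive from the master seed as
  `(seed * 1009 + k * 9973) mod (2^31 - 1)` so any subject can be
  regenerated alone. A per-genotype non-responder fraction forces the
  affected subjects' amplitude to zero (emulating animals with no activated
  voxels in the target ROI); they are the last subjects of their group, so
  the choice is deterministic.

What passing tests on this generator do **not** show: robustness to
physiological noise structure (respiration, cardiac cycles), susceptibility
artifacts, partial-volume effects at real anatomy's scale, non-affine
anatomical variability, or the behaviour of the registration on real
tissue-contrast images. The generator validates the statistical machinery
and the geometric bookkeeping, not scanner realism.

# Numerical choices and degenerate inputs

- 1-based inclusive scan windows in all user-facing configuration (matching
  "repetitions 1–25 / 26–50" phrasing), converted internally to index
  vectors; overlapping or out-of-range windows are configuration errors
  caught before any computation.
- Degenerate voxels: zero variance in both windows with equal means → t = 0,
  p = 1; unequal means with zero variance → p = 0 with signed infinite t.
- All-tied region data → Kruskal–Wallis p = 1 with a warning; all-tied
  Mann–Whitney samples → p = 1.
- Regions with zero atlas voxels are excluded from VOA tables with a
  warning; groups with a single subject give undefined SEs and a flagged
  row rather than an error.
- Registration records initial and final cost per pyramid level; the search
  is monotone within a level by construction, and a run that ends
  unconverged with cost above 0.5 raises a convergence error carrying the
  final cost.
- Table outputs round volumes to 3 significant figures only at the
  formatting layer; all internal computation is double precision.

# Problem sizes used in the test-suite simulations

The suite's simulations are sized for a single CPU: null FDR calibration
uses 200 sessions on 32 × 32 × 10 grids; affine-recovery properties use 20
seeded trials on a 32 × 32 × 16 phantom; gene-dose recovery uses 50 cohorts
of 9/9/8 subjects on 24 × 24 × 8 grids with 6 regions; ANOVA calibrations
use 200 replicates of 12 subjects × 8 acquisitions. These sizes were chosen
so each property is measured with usable Monte-Carlo error while the whole
suite stays fast enough to run routinely.

# Known limitations

- Window-mean contrasts, not GLM/HRF regression: appropriate for sustained
  block designs, not event-related ones.
- No cluster-extent or permutation-based multiplicity control; FDR is
  voxel-wise.
- No sphericity correction in the repeated-measures ANOVA.
- Affine (9-parameter) registration only; no nonlinear warping, slice-timing
  or distortion correction.
- Negative BOLD responses are computed but excluded from activation tables,
  which report positive changes only.
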