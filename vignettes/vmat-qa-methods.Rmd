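---
title: "Methods: detector resolution, coalescence and statistical QA monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detector resolution, coalescence and statistical QA monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vmatqa)
```

## The problem

Patient-specific VMAT QA compares a delivered planar dose, measured with a
2D ion-chamber array, against the TPS calculation using the γ index. The
arrays undersample: the 729-chamber model has 5×5 mm² apertures at 10 mm
pitch, so half of every row is dead space, and a 2.5 mm HD-MLC leaf pair
aligned with the inter-row gap is invisible to a single acquisition. The
coalescence procedure repeats the measurement with the couch shifted +5 mm
longitudinally and merges both acquisitions, doubling the sampling
frequency along that axis (0.1 → 0.2 mm⁻¹) and raising the point count
from 729 to 1458. This package simulates that entire chain and asks, with
statistical-process-control (SPC), process-capability (PCA) and ROC
machinery, what the extra resolution buys.

Because no clinical measurements ship with the package, every input is
synthetic and every claim a test can make is conditional on the synthetic
world described below.

## The synthetic world

**Dose model.** A plan is a set of aperture segments over 60 leaf pairs
(inner 32 pairs 2.5 mm wide, outer 2×14 pairs 5.0 mm). Each open pair
contributes its aperture rectangle convolved with an isotropic Gaussian
penumbra kernel — implemented analytically as a product of erf-edged
profiles — scaled by the segment weight, and the whole aperture rotates
with the collimator. This is deliberately the simplest model that exposes
leaf-width-scale structure to the detector-sampling argument; it is a
stand-in for a TPS dose engine, not a reproduction of one (no scatter, no
tongue-and-groove transport, no arc-time resolution). Adjacent strips
telescope exactly, so abutting leaves produce no seam artefacts.

`random_field_spec()` draws the cohort plans: two segments, ~120×140 mm
fields, per-pair tip positions following a smoothed random walk
(sd 12 mm, 5-pair window), weights U(0.5, 1.5), penumbra σ = 3 mm,
collimator 10° (the typical arc-delivery setting; 0° is the IMRT-style
alignment used in the missed-leaf demonstrations). These values were
chosen once as representative of modulated clinical apertures and are not
tuned against any outcome.

**Errors.** `MU_scale` multiplies delivered dose by 1+magnitude (+2%
default — a machine-output error). `DLG_shift` retracts every leaf bank by
magnitude/2, widening each aperture by the magnitude (+1 mm default over a
typical 1.092 mm dosimetric leaf gap), and the map is regenerated; dose is
linear in segment weights, so MU errors may equivalently scale the
rendered grid, which the sensitivity stage exploits.

**Measurement.** A chamber reads the mean ground-truth dose over its
square aperture (uniform top-hat response; the published lateral-response
fill factors, e.g. 0.86 for the checkerboard array, rely on a response
model that is out of scope — only geometric coverage is reported).
Optional measurement noise is additive Gaussian; the study default is
σ = 0.5% of the plateau dose, a typical array reproducibility figure. The
generator itself defaults to zero noise.

**Beam.** PDD is exponential attenuation (μ = 0.0046 mm⁻¹) with a 3.5 mm
build-up constant and point-source divergence, normalised at the 15 mm
reference depth — a 6 MV-like curve peaking near 15 mm. TPR follows the
Mayneord-type relation TPR(d) = PDD(d)·((SSD+d)/(SSD+d_ref))²,
renormalised at d_ref; `ssd = Inf` gives the parallel-beam limit used by
the closed-form tests (constant PDD ⇒ TPR ≡ 1).

## Reconstruction

Each measured point defines a divergent ray from the focus (SAD 1000 mm).
Rays are marched at a quarter-voxel step, accumulating electron density
from the contour entry point; the water-equivalent depth at any point is
the geometric depth times the mean relative density of the traversed
samples. Dose along the ray is the measured dose times
TPR(Z_CT)/TPR(Z_Det) times the inverse-square distance ratio; each voxel
layer is then filled by linear interpolation between rays in the
detector-plane parameterisation (voxels back-projected through the focus).
In-contour voxels outside the interpolation hull are zeroed and counted in
a coverage report. The measurement plane depth defaults to 97.5 mm so that
it coincides with a voxel-layer centre at the default 5 mm voxel size,
which makes the homogeneous-water identity (reconstructed = measured at
the detector's own depth) exact to machine precision.

DVHs use 1000 bins (0.1% of the maximum dose each) and D50 by linear
inverse interpolation of the cumulative curve; differences are reported as
|(D − D_ref)/D_ref|·100.

## γ analysis

For each reference point at or above the low-dose threshold (default 10%
of the maximum reference dose — or of a caller-supplied normalisation dose
when the reference is a subset of a larger volume), γ is the minimum of
√(dist²/DTA² + ΔD²/ΔD_abs²) over the evaluated distribution, linearly
interpolated on a sub-grid of DTA/10 within a search radius of 3·DTA
(profile mode uses the conventional 2 mm cap). ΔD_abs is dd%·max(ref)
globally or dd%·D_ref locally. The exact reference position is always
included as a candidate, so identical distributions give γ ≡ 0 and
refining the sub-grid is monotone non-increasing. The C++ kernel visits
candidates centre-out with distance-based early termination; a separate
brute-force oracle in the test helpers (own interpolation, no cap
shortcuts) pins the kernel down on random 20×20 maps. Measured maps are
interpolated in the frame in which their sample points form a regular
lattice — axis-aligned for the square array and coalesced maps, 45°
rotated for the checkerboard — mirroring how commercial software
linearly interpolates between adjacent detectors.

## SPC, capability, comparisons

Charts use the individuals/moving-range constants: CL = x̄,
LCL = x̄ − 2.66·mR̄, both from the first 20 in-control points (capped at
the series length); every point below the LCL is flagged. Action limits
are ΔA = β·√((x̄−T)² + σ²) with β = 4 and T = 100%, LAL = T − ΔA/2,
UAL = 100%. σ (process) and s (sample) are both estimated by the cohort
sample SD — the formulas distinguish the symbols but only one data source
exists; the choice is recorded in the output metadata.

Capability reports Cpl = (x̄−LAL)/(6(1−P_x)s) and
Cpu = (UAL−x̄)/(6·P_x·s) with P_x the empirical fraction of points ≤ x̄
(a normal-theory 0.5 is selectable). The reported Cpk equals **Cpl**, not
min(Cpl, Cpu): for a percent-γ characteristic the upper action limit
coincides with the target, so any good process sits close to 100% and the
upper index is structurally small — closeness to the target is the goal,
not a capability defect. `cpk_min` preserves the two-sided minimum for
completeness. Out-of-control points are removed in a single pass (no
re-estimation loop) before capability is computed, and the coalescence
cohort is assessed against the SA cohort's action limits, so Cpk > 1 reads
as "coalesced results live within the standard-acquisition tolerance".

Cohort comparisons check both cohorts with Shapiro–Wilk and
Kolmogorov–Smirnov tests; if all p > α = 0.05 the paired t-test is used,
otherwise the Wilcoxon signed-rank (also used when the paired differences
are constant, where the t statistic is undefined). Dispersion is the
type-7 (linear-interpolation) IQR, stated in every report.

## Sensitivity and ROC

Δγ = γ_NE − γ_IE per plan; Δγ > 0 counts as detection. ROC curves sweep
thresholds on the percent-γ score with *lower pass rate ⇒ more
error-like* (the score direction is recorded in the result); the
trapezoid AUC equals the rank statistic U/(n₁n₂) with half-credit ties,
and the p-value comes from the two-sample rank-sum test (a paired
alternative is selectable). The study defaults to 8 synthetic plans,
configurable upward for more stable AUCs.

## What a green test does and does not establish

The synthetic cohort reproduces the *structure* of the clinical findings:
coalescence yields higher pass rates with smaller spread, hence higher
LCL, smaller ΔA, higher LAL and higher Cpk; the checkerboard array
outperforms the square one; reconstruction error in D50 shrinks with
sampling density; a ±1 mm DLG error is essentially undetectable (AUC near
0.5 with case-specific Δγ signs); a gross MU error is always caught. None
of this certifies the magnitudes a clinic would observe — those depend on
real delivery, scatter, detector response and plan mix that the generator
does not model.

One stated-world behaviour deserves emphasis: because the evaluated
distribution is an aperture-averaged sparse sampling while the reference
is a 2.5 mm point grid, a no-error measurement already sits below 100%
pass, and a small +2% MU error can *raise* 3%/2 mm pass rates by partially
compensating the averaging bias (AUC near 0 in some scenarios). Detection
is restored at the strictest 1%/1 mm criterion and at larger magnitudes.
Real cohorts show milder, case-specific versions of the same sign
ambiguity for small errors; the exaggeration here is a known consequence
of comparing an unsmoothed fluence model against volume-averaging
detectors.

## Numerical choices and degenerate inputs

* Dose grids: 1 mm generation (≤ 1 mm enforced), bit-exact plain-text
  round trip (17 significant digits).
* Quadrature: chamber mean over pixels whose centres fall in the aperture;
  a step edge bisecting an aperture reads (high+low)/2 to within the 1 mm
  pixel tolerance.
* Duplicate-merge epsilon in coalescence: 0.1 mm, merged by averaging;
  any merged pair disagreeing by more than the tolerance aborts
  coalescence with the maximum discrepancy attached (clinically failed
  coalescences are logged and excluded, and the study continues).
* Ray marching: spacing/4 step, nearest-voxel density lookup; Eq-level
  depth examples are exact on constructed ray paths and within ~2%
  through the discretised phantom.
* γ ties: plain minimum (the value, not the argmin, is reported); empty
  masks produce a defined empty result with a warning; masked points with
  no evaluated data inside the cap are excluded from pass rates and
  counted.
* Reports round half away from zero to two decimals, matching the style
  of published QA limit tables.
* Seeding: one master seed; each pipeline stage derives a fixed-offset
  sub-seed (stable under stage reordering); summaries are byte-identical
  across reruns.

## Known limitations

* The dose generator is an acknowledged stand-in for a TPS dose engine;
  absolute pass rates, LCLs and Cpk magnitudes are not comparable to
  clinical values.
* DICOM RT Dose ingestion is not provided (no DICOM reader in the
  dependency budget); the documented plain-text grid format is the
  interchange format.
* Single-beam reconstruction geometry: the rotating-gantry compositing of
  a real cylindrical-phantom system is out of scope; one plane exercises
  the depth-scaling and divergence physics fully.
* The published response-function fill factors (0.86 → 1.00) are not
  reproduced; only geometric coverage is.
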