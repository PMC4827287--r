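---
title: "Methods: from compression traces and stained sections to structure-function estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from compression traces and stained sections to structure-function estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondroquant)
```

chondroquant implements the analysis chain used when cartilage-like
constructs are engineered under force-controlled cyclic compression: the
mechanics of the construct are measured by cyclic unconfined compression,
the strain actually delivered by the bioreactor is estimated from a
force-balance model of the loading station, glycosaminoglycan deposition is
quantified from Alcian-blue-stained sections, and the staining metrics are
related to the compressive modulus. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical choices; a set of
seeded generators provides synthetic inputs with known ground truth for
validation.

## 1. Tangent moduli from cyclic compression

A construct disk (diameter $d$, thickness $t$) is compressed between
platens at 1 Hz for 10 cycles to 20 % peak strain. Engineering stress over
the loading limbs of the last cycles rises exponentially with engineering
strain, so the package fits

$$\sigma(\varepsilon) = A\,(e^{B\varepsilon} - 1), \qquad A > 0,\; B > 0,$$

and reports tangent instantaneous moduli as the analytic derivative
$E_t(\varepsilon) = A B e^{B\varepsilon}$, by default at 10, 12, 15 and
18 % strain. The law is forced through the origin: a third offset
parameter would trade off against $A$ on noisy data and make the tangent
moduli unidentifiable, while the zero-load reading is handled explicitly
(below). The fit is nonlinear least squares (Levenberg–Marquardt via
minpack.lm) with the deterministic initialisation $B_0 = 15$,
$A_0 = \sigma_{\max} / (e^{B_0 \varepsilon_{\max}} - 1)$, so identical
inputs give bit-identical results. The last 4 of 10 cycles are pooled into
a single fit — by then the loading profile has reached a steady state, and
pooling matches how a single fitted curve is normally drawn through the
steady-state limbs.

**Thickness by tare load.** Thickness is defined operationally: the platen
descends at 50 µm/s and stops when a compressive tare load of 0.02 N is
read; the platen gap at that instant is the thickness. `detect_thickness()`
reproduces this definition on a recorded trace, with two robustness
measures that are exact in the noise-free limit:

* the crossing is searched only within the *constant-velocity approach
  prefix* of the record. The displacement channel is machine-controlled
  and clean, so the prefix is identified as the longest initial run whose
  per-sample velocity stays within 50 % of the starting velocity. This
  matters because the cyclic phase that follows can carry force noise far
  larger than the tare threshold (noise scales with the peak cyclic force,
  which can be three orders of magnitude above 0.02 N), and a crossing
  detector run over the whole record would trigger on noise;
* the force is smoothed with a running median (window 9 samples; the
  running median of a monotone segment is the segment itself, so this is
  exact on clean data) and the crossing is interpolated linearly between
  the bracketing samples. If the record stops at the tare reading — the
  protocol halts the platen the moment the threshold is read — the last
  fraction of a sample is extrapolated from the local force–displacement
  slope, with the extrapolation capped at 25 µm so a record that never
  approaches the tare still fails loudly with "no contact detected".

**The zero-load reading.** Strain is referenced to the tare-contact gap,
so in that frame the stress at zero strain *is* the tare stress
$0.02\,\mathrm{N} / (\pi d^2/4)$ by construction. The default offset rule
(`offset_rule = "tare"`) subtracts exactly that known constant. This choice
is both exact in the noiseless limit and free of estimation noise; the
alternatives — the median stress at the detected cycle troughs
(`"trough"`), or the median stress of the samples in the lowest 2 % of the
strain range (`"low_strain"`) — estimate the offset from data and inject
its sampling error into $A$, which is the weakly identified parameter of
the exponential law. They remain available for records with baseline drift,
where the tare reference may no longer hold. A useful identity supports the
tare-referenced frame: the law $A(e^{B\varepsilon}-1)$ is form-invariant
under an affine reparameterisation of strain followed by subtraction of the
new zero reading, so coefficients fitted in the measured frame are the
measured-frame truth, not an approximation of some other frame.

**Cycle segmentation** is peak detection on the displacement channel with a
minimum peak distance of half a period; each loading limb runs from a
trough to the following peak. Fewer detected cycles than the protocol's
count raises "incomplete test"; irregular peak spacing (deviation above
35 % of the median spacing) raises "cycle segmentation failed". Stress uses
the initial face area (engineering stress); compressive force and
displacement are stored positive-in-compression, and `read_trace()` flips
instrument conventions that export compression as negative.

Constructs are preselected by thickness (default window 1110–1250 µm,
inclusive) via `select_by_thickness()`, which also reports the discarded
fraction.

## 2. Strain delivered by the force-controlled bioreactor

In the loading station a plunger (7 mm diameter) presses with force $F$
(default 5 N) on a construct disk (5 mm) surrounded by a silicone ring
(thickness $t_r = 1$ mm, compressive modulus $E_r = 2.64$ MPa) acting as a
displacement limiter. Ring and construct are parallel springs: the plunger
settles at the height $h$ where

$$\underbrace{A_r E_r \frac{t_r - h}{t_r}}_{\text{ring, linear}} +
  \underbrace{A_c\, A\left(e^{B (t_c - h)/t_c} - 1\right)}_{\text{construct, exponential}} = F,$$

with each term clamped to zero once the respective component loses contact
($h \ge t_r$ or $h \ge t_c$). The construct's force law is the same
exponential law fitted from its own compression test, scaled by its face
area $A_c$; the ring is treated as linear elastic at all strains (a single
modulus is all that is known for it). The delivered construct strain is
$\max(0, (t_c - h)/t_c)$ — a construct that has atrophied below the settled
ring height carries no load and exactly zero strain.

The ring contact area $A_r$ is not directly measurable in the assembled
station; the default is the annulus between the plunger and the construct
footprint, $\pi(3.5^2 - 2.5^2) \approx 18.85$ mm², and it is an explicit
config parameter. Under the defaults a 5 N force compresses the bare ring
by $F/(A_r E_r) \approx 10.0\,\%$, settling at $h \approx 899.5$ µm. No
attempt is made to reverse-engineer a ring area from reported strain
windows: applied force, ring geometry and area stay configuration.

The combined reaction force is strictly decreasing in $h$, so the
equilibrium is unique and `solve_load_sharing()` brackets it by bisection
over $(0, \max(t_r, t_c))$, halving for 120 iterations (to machine
precision; the residual force imbalance is then far below the 1e-6 N
tolerance, and identical inputs give bit-identical output). The analysis is
quasi-static at peak load: the 1 Hz dynamics, friction and lateral
confinement are not modelled. `strain_trajectory()` maps the solver over a
time-ordered list of construct states independently — no state is carried
between time points, and a failure at one time point is flagged in the
output rather than aborting the rest.

## 3. Alcian-blue quantification

Brightfield RGB images of stained sections are converted to optical
density, $OD = -\log_{10}((I + 1)/I_0)$ with $I_0 = 256$, so stain
contributions add linearly (Beer–Lambert); the +1 offset keeps saturated
pixels finite and maps a pure white pixel to OD 0. Processing then runs:

1. **Automatic stain vectors** (`estimate_stain_basis()`): pixels with OD
   norm below `beta` (default 0.15) are discarded as background; the
   remaining pixel ODs are projected onto the plane of their two leading
   singular vectors; the `alpha`-th and (100−`alpha`)-th percentiles
   (default `alpha` = 1) of the angular distribution in that plane give the
   two extreme — i.e. purest — stain directions. These defaults are the
   conventional choices for this estimator; robustness to them can be
   checked directly on the generators. The two vectors are unit-normalised
   with non-negative components. Sections here carry three dyes
   (hematoxylin, Alcian blue, Sirius red), but the estimator returns the
   two dominant directions; the label `alcian_blue` is assigned to the
   vector that *appears* blue, i.e. absorbs most in the red channel
   relative to the blue channel (a blue stain transmits blue light, so its
   OD vector has a small blue component — ordering by blue-channel
   absorption would select the red dye). An angular spread below 1° means
   a single-stain image and raises "degenerate basis".
2. **Least-squares deconvolution** (`deconvolve()`): per pixel,
   $od = S c$ is solved by least squares with $S$ the stain matrix;
   negative coefficients are clipped to zero *after* the reconstruction
   residual is computed, so the residual reflects true fit quality.
3. **Whole-image Otsu threshold** (`otsu_threshold()`): a 256-bin histogram
   of the target-stain concentration over `[0, max]` is thresholded at the
   bin edge maximising the between-class variance; floating-point-level
   ties are broken toward the lowest threshold. The threshold is computed
   from *all* image pixels and then applied inside the ROI — deriving it
   per-ROI would make segmentation inconsistent across sections.
4. **ROI metrics** (`quantify_stain()`): within a manually demarcated ROI
   (polygon JSON rasterised by the even-odd rule at pixel centres, or a
   mask image), coverage is the percentage of ROI pixels above threshold
   and mean staining intensity is the mean deconvolved concentration over
   the *positive* pixels (an all-ROI mean is available behind
   `positive_only = FALSE`). Intensities are in deconvolved-OD units:
   they are arbitrary up to the basis normalisation, so only relative
   comparisons within a consistently processed batch are meaningful.

Polygon coordinates are 0-based pixel coordinates with x as column; pixel
$(r, c)$ (0-based) has centre $(c + 0.5, r + 0.5)$, so an axis-aligned
$10\times10$-unit square covers exactly 100 pixels. Whole-slide container
formats are out of scope; images arrive as plain PNG or TIFF tiles, and
stain normalisation across slides is not attempted.

## 4. Structure-function association

`regress_metric_on_log_modulus()` fits ordinary least squares of a staining
metric against $\log_{10}$ of the tangent modulus (at 18 % strain by
default, the strain at which the modulus separates experimental groups most
clearly) and reports slope, intercept and $R^2 = 1 - SS_{res}/SS_{tot}$.
Plain OLS, not robust or errors-in-variables, matches how such lines of
best fit are normally reported.

`compare_groups()` is a two-sided rank-sum (Mann–Whitney) test with the
study's significance bands (a/b/c for p < 0.05/0.01/0.001). For
$n_1 + n_2 \le 12$ the p-value is exact by full enumeration of all
$\binom{N}{n_1}$ rank assignments, with midranks under ties, defined as
$2\min(P(W \le w), P(W \ge w))$ capped at 1. Larger samples use a
continuity-corrected normal approximation augmented with Edgeworth skewness
and kurtosis terms. The cumulants of the rank-sum null are computed exactly
from the (mid)rank population — $W$ is the total of a simple random sample
drawn without replacement, so its moments follow from population power
sums; ties are thereby corrected for automatically. The Edgeworth terms
matter: at $n_1 = n_2 = 6$ a plain continuity-corrected normal misses
mid-range p-values by up to ~0.015, while the corrected version stays
within ~0.002 without ties (~0.01 under heavy ties, where the support
lattice coarsens; the continuity correction uses half the actual lattice
step, 0.25 for midranks). No multiple-testing correction is applied,
matching per-comparison reporting; this is a documented limitation.

`summarize_timecourse()` produces per-group, per-day mean ± SD tables
(n−1 denominator); a single-record cell reports SD 0 flagged by n = 1.

## 5. Synthetic data: what it emulates and what it does not

All generators are seed-deterministic (they restore the caller's RNG
state) and return their ground truth alongside the data.

**Mechanics traces** (`gen_mech_trace()`): a constant-speed approach to the
tare contact followed by sinusoidal strain cycles (defaults 1 Hz, 10
cycles, 20 % peak strain — the loading protocol), sampled at 100 Hz, with
force from the exponential law. Truth is defined in the tare-referenced
frame the measurement itself uses (cyclic force
$F = F_{tare} + A_c A (e^{B\varepsilon} - 1)$), so the noiseless round trip
through the full pipeline recovers $(A, B)$ to machine precision rather
than to the size of a frame mismatch. Noise is Gaussian on force: the
cyclic phase gets SD `noise_sd` × peak force (emulating a load cell whose
error scales with the measured range), while the quasi-static approach gets
an absolute floor (default 0.002 N, a tenth of the tare; zero in the ideal
noiseless case). The split reflects the physical protocol — thickness
detection is a separate slow acquisition whose noise floor is set by the
instrument, not by forces reached later in cycling; a 0.02 N threshold is
only measurable at all when approach noise is well below it. The generator
does not emulate viscoelastic hysteresis, drift, or cycle-to-cycle
transients: the "steady state" of the last cycles is exact by
construction, so passing tests show algorithmic correctness, not robustness
to unmodelled physics.

**Histology** (`gen_histology()`): a notched-ellipse silhouette (to
exercise ROI rasterisation beyond rectangles) carries a uniform random
counterstain; the target stain is painted on the top-$k$ pixels of a random
smooth blob field so that exactly `coverage_pct` of the ROI is positive and
the positive region is spatially coherent. OD is composed as $S c$ (plus
optional Gaussian OD noise) and exponentiated back to RGB. Because the
image is built in OD space, the deconvolution model is exactly the
data-generating model in the noiseless limit, isolating algorithmic error
from model error. Pixel values are continuous; quantisation to 8 bits is
applied only when writing image files. Positive-pixel concentrations are
normal (mean 0.7, SD 0.12, floored at 0.2 OD) over a counterstain uniform
on [0, 0.3]: strong, well-separated staining of the kind the estimator's
percentile step needs — real slides with weak or overlapping stains will
behave worse than the tests suggest. No texture, focus blur, illumination
gradients or stain variation between slides is synthesised.

**Cohorts** (`gen_cohort()`): $\log_{10}$ moduli are uniform on
[−0.9, 1.3] (the observed range of construct moduli at 18 % strain across
the culture time course); each metric is a linear function of log modulus
plus Gaussian noise with variance
$\sigma^2 = slope^2\,\sigma_x^2 (1 - R^2)/R^2$, so the population $R^2$
equals the target — default 0.84 for mean intensity and 0.64 for coverage,
the anchor values for this kind of cohort. The defaults for slope and
intercept (0.25 and 0.45 OD units per log10 MPa; 18 %/decade and 40 % for
coverage) are plausible magnitudes only; the calibrated quantity is $R^2$.

**Growth trajectories** (`gen_trajectory()`): thickness dips at the second
time point then rises (1180 → 1050 → 1250 → 1300 µm) while stiffness rises
monotonically. The stiffness path is anchored to the published
tangent-moduli tables for loaded constructs: with moduli at two strains,
$M_{18}/M_{10} = e^{0.08 B}$ gives $B$ (≈ 20 at day 0, ≈ 46–57 later) and
$M_{10} = A B e^{0.1 B}$ gives $A$. Fed through the force-balance solver,
these defaults reproduce the characteristic estimated-strain pattern: a
significant decrease to day 28 (initial compaction) followed by an
increase to day 56 (matrix deposition thickens and stiffens the construct,
which then takes a growing share of the plunger load), flattening by day
84. This is phenomenology, not a mechanistic growth model.

## 6. Problem sizes and reproducibility

The shipped test suite validates at sizes chosen to be statistically
informative while keeping a full run in seconds: 100 simulated compression
tests for parameter-recovery rates, 200 random histograms for the Otsu
oracle equivalence, 512×512-pixel slides for the stain round trip, 200
cohort replicates of n = 1000 for the $R^2$ calibration, and 1000 random
parameter draws for force-balance conservation. `scripts/acceptance.R`
recomputes all headline quantities from scratch at exactly these sizes with
a caller-supplied seed. The pipeline runner (`run_pipeline()`) writes a
manifest with input hashes and per-stage status; identical config and
inputs give byte-identical numeric outputs.

## 7. Known limitations

* Equilibrium (biphasic/poroelastic) moduli, stress-relaxation analysis
  and frequency sweeps are out of scope; the tangent moduli here are
  dynamic quantities at 1 Hz.
* The ring is linear elastic and the load-sharing analysis quasi-static;
  plunger weight is treated as part of the single applied force.
* Stain intensities are relative (deconvolved OD); cross-batch
  normalisation is not implemented.
* The rank-sum approximation is asymptotic; between 13 and roughly 20
  combined observations the exact branch can be preferred by raising
  `exact_max_n` at some computational cost.
* Generator realism bounds what green tests demonstrate (see section 5).
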