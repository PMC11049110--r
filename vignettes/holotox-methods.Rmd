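---
title: "Methods: quantitative phase imaging and multimodal cytotoxicity assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative phase imaging and multimodal cytotoxicity assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotox)
```

## The problem

Nanoparticles interfere with colorimetric cytotoxicity assays: they absorb
and scatter light, adsorb assay components and can produce misleading
readouts. Label-free quantitative phase imaging (QPI) by digital holographic
microscopy (DHM) measures the dry mass of a cell population without dyes and
without perturbing the sample, so the same wells can afterwards be analysed
with downstream biochemical assays - a metabolic viability readout (WST-8)
on the cells and a membrane-integrity readout (LDH release) on the
supernatant. `holotox` implements this multimodal design end to end:
hologram reconstruction to calibrated phase, dry-mass proliferation
quantification, both plate-assay normalizations, and four-parameter logistic
(4PL) dose-response modelling with EC50 comparison across the three
endpoints. Because raw laboratory data of this kind are rarely deposited,
the package ships a synthetic-data module that simulates every input with
known ground truth; all quantitative claims in the test suite are made
against that ground truth.

## Imaging model

An off-axis hologram is the interference of the object wave
$O = e^{i\varphi(x,y)}$ with a tilted plane reference $R$ whose tilt puts a
spatial carrier $f_c$ (cycles/pixel) on the fringes:

$$I = |O + R|^2 = |O|^2 + 1 + 2\,\mathrm{Re}(O R^{*}).$$

The cross term carries the object phase and sits at $\pm f_c$ in the
spectrum. Reconstruction multiplies the hologram by the reference ramp so
the object sideband moves to DC, isolates it with a soft-edged
(raised-cosine) circular mask of radius $0.45\,|f_c|$ by default, and
inverse-transforms to the complex field; the wrapped phase is its argument.
Residual tilt is removed from the mean complex phase gradient and the piston
offset from the circular mean over cell-free pixels (identified by low local
phase variability, with the image border as fallback).

Phase unwrapping is quality-guided: pixel reliabilities are the inverse
second-difference noise measure, and pixels are merged across the most
reliable edges first, so 2$\pi$ jumps cannot propagate out of noisy regions.
On wrap-free input the input is returned unchanged. The algorithm is
implemented in C++ for speed; a 512 x 512 frame unwraps in a few tens of
milliseconds.

Numerical refocusing uses the angular-spectrum (convolution) kernel
$H(f; z) = \exp\!\big(2\pi i z \sqrt{\lambda^{-2} - |f|^2}\big)$ with
evanescent components suppressed; propagation by zero is the identity and
$+z$ then $-z$ restores the field to numerical precision. Autofocus scans a
distance grid and maximizes a sharpness score. The default score is the
*negative* Tamura coefficient (sd/mean of the amplitude) evaluated **over
cell-free pixels**: adherent cells are phase-dominant objects, so amplitude
contrast is minimal in focus; restricting the statistic to the background
suppresses a bias that spectral-truncation ringing at cell edges otherwise
introduces. In the forward model the masked criterion recovers defocus
within one 5 µm search step across ±100 µm for weak-phase populations
(peak ~1 rad) and up to moderate defocus (±40 µm) for full-strength
(~3 rad) populations; beyond that, sideband truncation genuinely destroys
the focus signature of strong phase objects, and full-field Tamura is
worse still (up to ~35 µm bias). Full-field variants remain available via
`criterion=`. Note that autofocus needs adequate spatial sampling: at
the instrument's native ~0.8 µm pixel pitch the defocus signature inside
the sideband passband is strong, while on the coarse demonstration grids
(3.2 µm pitch) it is physically negligible, so the demo pipeline runs in
focus without autofocus.

Ten holograms are recorded per field of view with the illumination modulated
between frames; each frame therefore carries an independent coherence-noise
realization. Averaging the ten unwrapped phase maps (after per-frame piston
removal over cell-free pixels) reduces the coherence-noise standard
deviation by about $\sqrt{10}$, which the test suite verifies by Monte
Carlo.

## Background correction and dry mass

Residual slow background is removed with a rolling-ball filter: the
background is the grayscale opening (non-flat erosion then dilation) of the
phase image with a spherical-cap structuring element, computed exactly (no
shrink/scale approximation) and verified in the tests against a brute-force
pure-R opening. The cap spans a patch of radius 50 px at 512 x 512 (about
twice a cell diameter) with a default height of radius/100 radians. The
height matters: phase images span only a few radians, so a tall cap can
climb into cell-scale bumps and delete real dry mass, while the flat default
only removes structures wider than the patch. The residual bias that
remains - the opening rides the lower envelope of reconstruction ripple -
is below 2% of the population phase at realistic confluence (~30-45% cell
coverage, matching the study-scale seeding of 1.5-4.5 x 10^4 cells per
96-well).

Population dry mass follows the standard QPI relation

$$dm = \frac{\lambda}{2\pi\alpha}\,\bar{\Delta\varphi}\,S_{FOV},$$

with $\lambda$ = 532 nm, $S_{FOV}$ = 405 µm x 538 µm and the refractive
index increment $\alpha$. We use $\alpha$ = 0.19 mL/g (0.19 µm³/pg), the
standard value for cellular protein; $\alpha$ is a configuration field.
$\bar{\Delta\varphi}$ is the arithmetic mean of the corrected phase over
the *full* field of view - not a cell-masked mean - because the relation
multiplies by the full field-of-view area. The proliferation endpoint is
the dry-mass increment $DMI = dm_{t=24} - dm_{t=0}$; intermediate
time points are accepted by the data model but do not enter the endpoint.
Within each experiment, DMIs are normalized to the maximum per-condition
mean DMI (in practice the medium control), which maps the best-growing
condition to 100%; negative increments (net mass loss through death and
detachment) stay negative. The reference rule is configurable because the
choice of reference set is genuinely open; we prefer the per-condition mean
over the single largest measurement so one noisy field of view cannot
define the scale.

## Plate assays

WST-8 viability corrects each well's OD450 by its OD620 turbidity reference,
subtracts the mean cell-free background and scales by the medium control:

$$\text{viability\%} = 100\,\frac{OD_{450-620,\text{well}} - OD_{450-620,\text{bg}}}{OD_{450-620,\text{neg}} - OD_{450-620,\text{bg}}}.$$

LDH release is kinetic: OD492 is read every minute for 30 minutes, a
regression slope is fitted over the linear range, and slopes are scaled
between the medium control (0% release) and the digitonin full-lysis
control (100%):

$$\text{release\%} = 100\,\frac{m_{\text{well}} - m_{\text{neg}}}{m_{\text{pos}} - m_{\text{neg}}}.$$

The linear-range rule is a documented choice (the underlying protocol only
says a slope is fitted over the linear range): the longest contiguous
window with OLS $r^2 \ge$ 0.99 wins, ties broken by higher $r^2$ then by
earlier start, followed by a greedy end-trim that drops an endpoint
whenever doing so at least halves the residual misfit $1-r^2$. The trim is
what excludes a substrate-depletion plateau point exactly (a single flat
point dominates the residuals of an otherwise perfect line) while leaving
noisy-but-linear windows alone (no single point dominates random-noise
residuals). If no window reaches the threshold, the full-series slope is
returned with a `nonlinear_kinetics` flag. Release values are reported
unclamped; noisy wells may legitimately fall below 0% or above 100%. The
620 nm reference is applied to WST-8 only; LDH slopes use raw OD492, as in
the normalization formula above.

## Dose-response modelling

Each assay's per-experiment dose series is fitted with the 4PL on log10
dose,

$$y = \text{bottom} + \frac{\text{top} - \text{bottom}}{1 + 10^{\,h\,(\log_{10} x - \log_{10} EC_{50})}},$$

by Levenberg-Marquardt least squares with multi-start initialization (EC50
at the 25/50/75% dose quantiles, Hill slope in {±1, ±3}) to avoid local
minima. The Hill sign is unconstrained so the direction is inferred from
the data; the fitted object is normalized so `top` is always the zero-dose
asymptote. The zero-dose control is excluded from the fit (its logarithm is
undefined) and enters only through the normalization of the responses; top
and bottom are not pinned to 100/0, since whether the original analysis
constrained them is unknown and leaving them free is the safer default.

A fit is *accepted* only if: (a) the per-dose means are monotone within a
noise allowance - a rebound against the running extreme larger than
`k_sem` (default 3) pooled standard errors of a per-dose mean rejects the
fit as `non_monotonic` (the pooled SEM is used because individual per-dose
SEMs at n = 4 are too jittery to be a stable yardstick; with single
replicates an absolute allowance of 5 percentage points substitutes);
(b) $r^2 \ge$ 0.8; and (c) the EC50 lies inside the tested dose range.
Rejected conditions are reported as "not determined" rather than given a
number - this mirrors how non-monotonic dose-effect relationships (typical
for drug-loaded particles, where intermediate doses can transiently rescue
proliferation) preclude a meaningful EC50.

EC50s are summarized across independent experiments (mean ± SD of
per-experiment fits, not a pooled fit), and per-dose significance against
the medium control uses a one-way ANOVA gate followed by Welch t-tests with
Holm step-down adjustment, starred at p < 0.05 / 0.01 / 0.001. The
protocol family this follows names only "ANOVA" plus the star thresholds,
so we chose a standard gate-plus-step-down procedure and verify by
simulation (1000 global-null replicates) that its family-wise
false-positive rate stays at or below 0.05.

## The synthetic-data module

The generator emulates, with known truth:

* **Phase scenes** - cells are smooth compact bumps (quartic radial
  profiles) with peak phase ≤ ~3 rad, per-cell mass log-normal around
  300 pg (CV 0.25) and radius around 15 µm (CV 0.15), placed with an
  overlap budget; each cell's rendered integrated phase is normalized so
  its dry mass is exact, and the scene records the exact total of the
  rendered map. Default grids are 512 x 512 over the 405 x 538 µm field;
  acceptance scenarios use ~140 cells per field (≈ 30-45% coverage),
  consistent with seeding 1.5-4.5 x 10^4 cells per well.
* **24 h evolution** - the population dry-mass multiplier interpolates
  between the control growth factor (2.0x per 24 h) and a saturating-dose
  floor (0.4x, net loss) through the 4PL truth; strong effects render
  low-mass debris fragments. The multiplier identity is exact by
  construction (the rendered map is rescaled to the target mass).
* **Holograms** - 16-bit quantized frames `|O + R|²` with per-frame smooth
  coherence noise (Gaussian-filtered white noise, σ = 0.08 rad, 8 px
  correlation), additive detector noise (1% of mean intensity), and an
  optional dose-dependent static scatter background
  (σ = 0.02 rad x log2(1 + dose/32 µg/mL)) that reproduces the
  high-concentration background-noise effect: at 512 µg/mL the cell-free
  phase background is measurably noisier than at 0, which inflates
  dry-mass readings at the top doses exactly as observed in practice.
  The noise magnitudes are free parameters of the generator - the real
  instrument's noise floor is not characterized - chosen once at values
  that make 10-frame averaging meaningful.
* **Plates** - WST-8 wells with background offset 0.15 OD, full-viability
  signal 1.3 OD and 3% multiplicative noise; LDH kinetic series with
  negative/positive control slopes 0.002/0.020 OD/min, 1% per-reading
  noise, and an optional plateau minute. Digitonin is the 100%-lysis
  positive control (recorded at 75 µg/mL); four technical replicates per
  condition by default.

What the generator does **not** emulate: partial-coherence physics, Mie
scattering by particles, cell motility/morphology dynamics, segmentation-
relevant texture, plate edge effects, or pipetting errors. Passing tests
therefore demonstrate the correctness of the *analysis* chain against its
own forward model, not instrument-level validity on real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run imaging checks at the native
512 x 512, 10-frame configuration (round-trip RMSE, dry-mass recovery) with
5 seeds, and the full multimodal demonstration at 128 x 128 with 3 frames,
2 wells x 2 fields of view per dose, 8 doses plus control, and 3
experiments - sizes chosen so a complete run stays in the minutes range on
one CPU while every stage is exercised. Determinism: every stochastic
operation takes an explicit seed, child seeds are derived arithmetically,
and the global RNG stream of the caller is never disturbed; identical
configurations reproduce byte-identical tables.

Numerical details worth knowing: the spectral mask taper fraction is 0.3 of
the mask radius; carrier estimation refines the spectral peak with a 3 x 3
magnitude centroid (well under half a frequency bin of error); autofocus
tie-breaks prefer the smallest |distance| and flag the tie; the 4PL reports
`fit_failed` for constant responses (zero total sum of squares) rather than
an undefined $r^2$; degenerate two-group comparisons with zero variance are
resolved exactly (equal means give p = 1, different means give a vanishing
p-value); a plate whose negative control does not exceed background (WST-8)
or whose digitonin slope does not exceed the medium control (LDH) is
flagged invalid rather than normalized.

## Known limitations

* The dry-mass chain carries a small negative bias (≤ 2%) from sideband
  truncation and background-envelope effects; it cancels in relative
  proliferation but would matter for absolute mass comparisons across
  optical configurations.
* The rolling-ball background level is only meaningful at realistic cell
  densities; on nearly empty fields the opening tracks the noise envelope
  and inflates the mean phase by design of the operator, not by bug.
* Autofocus assumes a phase-dominant specimen; strongly absorbing samples
  should switch the criterion to `"tamura"`.
* The LDH linear-range rule and the post-hoc star procedure are documented
  choices among several defensible ones; both are configurable.
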