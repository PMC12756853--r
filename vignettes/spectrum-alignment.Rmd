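---
title: "Whole-spectrum registration of NMR spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-spectrum registration of NMR spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmralign)
```

## The problem and the model

Two processed frequency-domain NMR spectra of the same system often differ
by a small rigid translation in ppm: referencing conventions drift between
sessions, shim or lock faults displace the carrier, and temperature or
field differences move the whole pattern. `nmralign` models this as image
registration: the spectra are real-valued rasters on ppm grids, and the
quantity estimated is a single signed offset per spectral dimension.

The estimate is the peak of the circular cross-correlation
$\mathrm{CCF} = \mathcal{F}^{-1}\!\left(\mathcal{F}(I_1)\cdot
\mathcal{F}(I_2)^{*}\right)$ between the two conditioned rasters, refined
to sub-pixel precision and converted to ppm with the header geometry. The
model's assumptions are worth stating plainly:

* **The offset is rigid and global.** Per-peak or temperature-coefficient
  corrections (which move different resonances by different amounts) are
  out of scope; when they dominate, the single best rigid shift is still
  returned, with a correspondingly modest post-alignment score.
* **The spectra share content.** The CCF peak is driven by peaks present
  in both inputs. Partial overlap degrades precision gracefully (see
  *Known limitations*).
* **Rasters are real, processed, frequency-domain data.** Time-domain and
  complex-interleaved inputs are rejected at read time rather than
  silently mangled.

## Grid geometry

All conversions flow from two conventions:

* **Spectral sampling** (ppm per pixel): $SS = (sw/obs)/n$, with $sw$ the
  spectral width in Hz and $obs$ the observe frequency in MHz, so $sw/obs$
  is the axis span in ppm (ppm $=$ Hz/MHz).
* **Center-referenced origin.** File headers record the minimum-ppm edge
  (the NMRPipe origin), which changes under resampling and resizing. All
  offset arithmetic therefore re-references each axis to its center,
  $O + \frac{n+1}{2}\,SS$ (1-based pixel indexing; pixel $i$ sits at
  $O + i\,SS$, index increasing toward higher ppm). On a shared grid the
  center offset reduces to $O_1 - O_2$.

When samplings differ, the moving spectrum is resampled onto the reference
sampling by Fourier interpolation at the target size
$n_\mathrm{new} = n_2\,SS_2/SS_1$. Three numerical choices here:

* $n_\mathrm{new}$ is generally fractional; it is **rounded half-up**,
  which bounds the physical-span distortion by half a pixel and is
  deterministic. The residual sampling mismatch is carried into the
  alignment report as a warning when non-zero, and the center-offset
  computation accepts exactly that residual and nothing coarser.
* Fourier crop/pad handles the **Nyquist bin symmetrically**: cropping to
  an even size sums the two symmetric source bins; padding from an even
  size splits the bin's value evenly. This keeps the result real and makes
  upsample-then-downsample the identity for band-limited input. The DC bin
  is rescaled so the grid mean is preserved.
* Extent matching is a **symmetric real-space crop or zero-pad** about the
  center (ties toward the low-ppm side), preserving the center chemical
  shift to within half a pixel. Inside `align()`, cropping happens on the
  raw raster but zero-padding is applied *after* conditioning, so the pad
  value 0 coincides with the zero-floated baseline rather than biasing the
  mean.

## Conditioning

Both rasters pass through high-pass filter → zero-float → unit-variance
normalization, in that order.

* **High-pass filter**: multiply the Fourier transform by
  $H(f) = 1 - \exp(-|f|^2/2\sigma^2)$, where $|f|$ is the isotropic
  normalized spatial frequency in cycles/pixel (Nyquist $= 0.5$) and
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$. The default FWHM is 0.2355,
  i.e. $\sigma \approx 0.1$: DC is removed exactly, structure broader than
  roughly ten pixels is suppressed, and the Nyquist frequency is
  attenuated by less than $10^{-5}$. The FWHM is a config knob
  (`filter.fwhm`; `filter.enabled` turns the step off) because the "right"
  stop edge depends on how many pixels a linewidth spans: on coarse grids
  where peaks are only a few pixels wide, the default filter also removes
  a substantial part of the peak energy itself, which costs sub-pixel
  precision in noisy data (measurably so in the validation sweep — see
  *Known limitations*). It is kept as the default because removing broad
  baseline structure is the filter's purpose and the headline experiments
  pass with it enabled.
* "Inverse Gaussian" is implemented as $1 - \mathrm{Gaussian}$, a bounded
  high-pass; the reciprocal reading $1/\mathrm{Gaussian}$ diverges at high
  frequency and would amplify noise without bound.
* **Zero-float/normalize** subtracts the grid mean and divides by the
  population standard deviation (divisor $N$). Together with the filter's
  linearity this makes the whole chain — and hence the estimated shift and
  both scores — exactly invariant under $a\cdot I + b$, $a > 0$. A
  zero-variance (flat) raster is a hard error, not a silent NaN.

## Peak search and sub-pixel refinement

The CCF is evaluated by FFT (circular). No apodization window is applied;
instead the peak search is restricted to displacements at most
`max_shift_frac` (default 0.25, at most 0.5) of each axis extent, which
suppresses wrap-around false maxima while comfortably covering realistic
referencing errors. Exact ties are broken toward the smallest Euclidean
displacement, then lexicographically — the most conservative correction,
deterministically. If the global CCF maximum lies outside the window, the
in-window maximum is used and a warning is recorded.

Sub-pixel refinement fits, independently per axis, a parabola through the
peak value and its two neighbors (circular wrap at map edges):
$\delta = (c_{-1} - c_{+1}) / (2(c_{-1} - 2c_0 + c_{+1}))$, clamped to
$[-0.5, 0.5]$. At a discrete argmax the fit can in fact never point
farther than half a pixel (since $c_0 \ge c_{\pm 1}$), so the clamp only
matters for user-supplied peaks; zero curvature yields $\delta = 0$ with a
warning. The separable 1D scheme is the default deliberately — it is the
simplest scheme consistent with "fit a parabola to the CCF peak"; a full
2D quadratic-surface fit was considered and not adopted as default.

Scores are Pearson-type correlations on the conditioned surface by
default (`score_surface = "raw"` switches to the unfiltered rasters): the
moving raster is shifted by a Fourier phase ramp, both are re-standardized,
and the mean product is reported. `score_after` is guaranteed not to fall
below `score_before`; in the (pathological, never observed in the test
battery) case where the interpolated shift scores below zero shift, the
integer CCF peak is used instead and a warning recorded.

**Sign convention.** The reported shift is the correction for the moving
spectrum: positive components mean its features sit at lower ppm than the
reference's and must move toward higher ppm. `apply_shift()` uses the same
sign, absorbing the integer-pixel part into the header origin (lossless)
and applying the sub-pixel remainder by phase ramp.

Fractional phase-ramp shifts on even grids need a choice at the
self-conjugate Nyquist bin; the symmetric real ramp $\cos(\pi s)$ is used,
which keeps the output exactly real and integer shifts exact. A
shift/unshift round trip is consequently machine-exact only for
band-limited content; on white-noise-bearing rasters the residual
(confined to the Nyquist rows) is at the percent level. This does not
affect shift estimation — only `apply_shift()` and score evaluation at
fractional shifts — and is invisible for smooth spectra.

## 3D spectra

A 3D spectrum is aligned to a 2D plane by collapsing one axis with a
maximum-value (default) or sum projection and running the 2D chain on the
result. Maximum-value projection preserves peak visibility over the noise
floor better than summation when peaks are sparse along the collapsed
axis, which is why it is the default; both modes are exposed since dense
spectra can favor coherent summation. The two surviving axis headers are
carried over unchanged and the collapsed dimension's referencing is never
touched.

## The synthetic generator: what it emulates, and what it does not

`random_synthetic_spec()` emulates a modern solid-state ¹³C–¹³C-type
correlation plane: a 256 × 256 grid at 0.05 ppm/pixel (12.8 ppm span at
obs 150 MHz), 30 Gaussian peaks with linewidths uniform in 0.1–0.4 ppm
(the ~0.1 ppm regime of current fast-MAS data, spanning 2–8 pixels),
amplitudes uniform in 0.5–1, and additive white Gaussian noise. The
default noise level 0.05 (rms, relative to the strongest peak) corresponds
to S/N 10 under the NMR convention
$S/N = \text{peak amplitude}/(2\times\text{rms noise})$, and puts every
peak at S/N between 5 and 10. Peak positions are drawn over the central
80 % of each axis so controlled-offset experiments are free of
edge-truncation effects.

Ground-truth offsets in `make_offset_pair()` are applied to the *analytic
peak positions* before rendering, never by shifting a rendered raster, so
recovery error is attributable entirely to the aligner, even at sub-pixel
scale. Two noise modes are provided, and the distinction matters:

* **Shared noise** (default) emulates re-referencing one recorded data
  set: the noise raster travels with the data (circularly shifted by the
  nearest-integer pixel offset — white noise has no analytic translation).
  For integer-pixel offsets the two rasters are then identical up to
  translation, the regime in which the post-alignment score reaches 1.00.
  Shared noise is the wrong fixture for *sub-pixel* sweeps: the common
  noise's autocorrelation contributes a sharp CCF component at the integer
  lag that locks the estimate to whole pixels.
* **Independent noise** emulates separately recorded spectra and is used
  for the sub-pixel accuracy sweep and the peak-set-mismatch robustness
  battery.

What the generator does **not** emulate: t₁ noise ridges, baseline roll,
solvent bands, NUS reconstruction artifacts, lineshape anisotropy, or
correlated (non-white) noise. Passing tests on these fixtures therefore
demonstrate correctness of the geometry, conditioning, and estimator logic
and the achievable precision under sparse peaks + white noise — not
robustness to every artifact of real data. The published-data regime
(scores like 0.46 → 0.96 on real replicate spectra) involves data that no
synthetic fixture reproduces.

## Validation battery and problem sizes

The test suite (`tests/testthat/`) validates every stage against
independent oracles: a brute-force spatial-domain circular correlation on
16–32 px grids, a triple-loop projection oracle, explicit index
bookkeeping for crop/pad, analytically sampled cosines for Fourier
resizing, and closed-form filter attenuation values. End-to-end batteries
use 256 × 256 fixtures: a controlled 0.1 ppm offset experiment (recovered
within 0.01 ppm, post-alignment score ≥ 0.999), a 200-trial sub-pixel
sweep with offsets uniform in ±1 ppm, a 100-trial peak-set-mismatch
battery (60 % shared peaks, 40 % extra, independent noise), 1000-header
closed-form geometry properties, and the invariance suite (affine
intensity, antisymmetry under argument swap, apply-then-realign fixed
point, projection oracle equivalence). These sizes keep the full suite
under a minute on one CPU while leaving every property at full strength.

## Known limitations

* **Near-half-pixel offsets in noisy, partially overlapping spectra.** In
  the mismatch battery (S/N 10, 60 % peak overlap, default filter), a few
  trials per hundred land the integer CCF argmax one pixel past the true
  offset on one axis; the separable parabola can then at best return the
  adjacent half-pixel point, leaving errors slightly above 0.02 ppm
  (~half a pixel). This is a structural property of
  argmax-plus-three-point-interpolation at this noise level, not a
  tuning issue: the sweep passes its 95 % bound at ±0.01 ppm with full
  overlap, and the mismatch battery achieves ~97/100 at ±0.02 ppm rather
  than all trials.
* **The default filter trades precision for baseline immunity** on grids
  where linewidths span only a few pixels (see *Conditioning*); disabling
  it roughly halves sub-pixel jitter on clean-baseline synthetic data.
* **Circular correlation wraps content**; the windowed peak search
  suppresses, but cannot eliminate, pathological wrap maxima for spectra
  with strong edge intensity.
* Rigid, global shifts only; no weighted CCF variants, no direct
  3D-volume-to-3D-volume registration, no batch orchestration.
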