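# nmralign

Objective, whole-spectrum chemical-shift referencing for processed 2D and
3D NMR spectra.

Spectra of the same sample recorded months apart, on different
spectrometers, or by different users are routinely offset by small rigid
shifts in ppm — spectrometer drift, shim faults, or inconsistent
referencing. Offsets of ~0.1 ppm are easy to miss by eye yet large enough
to ruin co-addition and cross-spectrum peak matching, and fixing them by
hand ("slide spectrum B until it looks right") injects subjective bias.
`nmralign` removes that step: it treats two frequency-domain spectra as
images and estimates the global ppm offset between them by normalized FFT
cross-correlation, with sub-pixel refinement. It is aimed at solid-state
and solution NMR users who need reproducible referencing for co-addition,
longitudinal studies, or multi-user facility data.

## Method

Given a reference spectrum *I*₁ and a moving spectrum *I*₂:

1. **Grid geometry.** Each axis's spectral sampling is
   *SS* = (*sw*/*obs*)/*n* ppm per pixel (*sw* in Hz, *obs* in MHz). The
   moving spectrum is Fourier-interpolated onto the reference sampling,
   *n*ₙₑw = *n*₂·*SS*₂/*SS*₁, then symmetrically cropped or zero-padded to
   the reference extents while preserving its center chemical shift.
   Origins (minimum-ppm edges in the NMRPipe convention) are re-referenced
   to the grid center, *O* + ((*n*+1)/2)·*SS*, so the origin offset
   survives resampling and resizing.
2. **Conditioning.** Both rasters are high-pass filtered in Fourier space
   by 1 − exp(−|*f*|²/2σ²) with σ set by a FWHM of 0.2355 in normalized
   spatial frequency (suppressing baseline rolls and other low-resolution
   structure), zero-floated, and normalized to unit variance, making the
   result invariant to intensity scaling and baseline offsets.
3. **Registration.** The circular cross-correlation
   CCF = 𝓕⁻¹(𝓕(*I*₁)·𝓕(*I*₂)\*) is evaluated by FFT; its peak within a
   ±25 %-of-extent search window gives the integer pixel shift, refined to
   sub-pixel precision by a per-axis parabola fit through the peak and its
   two neighbors. Pixel shifts convert to ppm via
   shift·*SS* + *O*offset, and Pearson-type correlation scores are
   reported before and after alignment.

3D spectra are collapsed to 2D planes by maximum-value (default) or sum
projection and aligned against a matching 2D spectrum; the collapsed
dimension's referencing is untouched.

A deterministic synthetic-spectrum generator (Gaussian/Lorentzian peaks,
seeded white noise, offsets applied to the analytic peak positions so the
ground truth is exact even at sub-pixel scale) backs the test suite.

## Worked example

Induce a known 0.1 ppm referencing error in a synthetic ¹³C–¹³C-type
spectrum and recover it:

```r
library(nmralign)
spec <- random_synthetic_spec(seed = 42)          # 256x256, 30 peaks, S/N 10
pair <- make_offset_pair(spec, c(0.1, 0.1))       # exact ground truth
est  <- align(pair$s1, pair$s2)
est
#> <shift_estimate>
#>   shift: +2.000, +2.000 px = +0.1000, +0.1000 ppm (origin offset +0.0000, +0.0000 ppm)
#>   correlation score: -0.0077 -> 1.0000
```

The 0.1 ppm offset is two pixels at this sampling (0.05 ppm/px); the
aligner reports it exactly on both axes, and the correlation score rises
from −0.008 (uncorrelated at zero shift — the peaks are sparse) to 1.000
after correction. `apply_shift(pair$s2, est$shift_ppm)` returns the
re-referenced spectrum.

The same workflow from the shell:

```sh
nmralign simulate fix --seed 42 --offset 0.1,0.1   # writes fix_ref.ft2, fix_mov.ft2, fix_truth.json
nmralign align fix_ref.ft2 fix_mov.ft2
```

prints a JSON report with `"shift_ppm": [0.1, 0.1]`, `"score_after": 1`,
the per-axis sampling and origin offsets, and the full effective
configuration. Subcommands: `align`, `project`, `apply`, `simulate`,
`info`. Spectra are read and written as single-file NMRPipe (`.ft2`,
`.ft3`) or as a documented plain-text header+data pair (`.hdr`/`.dat`).

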