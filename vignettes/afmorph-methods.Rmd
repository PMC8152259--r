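---
title: "Quantifying aggregate morphology on nanopatterned surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aggregate morphology on nanopatterned surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmorph)
```

This vignette is the package's own account of the science behind its
estimators: what each quantity means physically, which numerical choices
were open and how they were settled, what the synthetic-data generator
does and does not emulate, and where the methods' limits are.

## The measurement problem

Amyloid-forming peptides deposited on a substrate grow into two
morphologies visible in AFM height maps: compact amorphous particles
(tens to ~200 nm tall, roughly isotropic) and worm-like fibrils (a few nm
tall, micron-scale long). Whether substrate nanotopography steers the
balance between these morphologies is read off three per-aggregate
numbers: the zero-basis volume, the projected boundary length, and their
ratio. Extracting them reproducibly requires flattening, background
removal, segmentation and contour measurement — each of which hides
conventions that change the numbers. This package states every convention
explicitly and tests each stage against synthetic surfaces with exact
ground truth.

All physical quantities are in nanometres. Rasters are row-major with the
origin at the top-left pixel centre; x runs along columns (the fast scan
axis), y down rows.

## Surface statistics

**RMS roughness.** $S_q = \sqrt{\langle (h - \bar h)^2\rangle}$ over all
pixels. For a sinusoid of peak-to-peak amplitude $A$,
$S_q = A/(2\sqrt2)$; for the study's ripple ($A = 1.5$ nm) that is
0.530 nm, and composed with long-range roughness of 1.08 nm rms the
quadrature sum gives the reported nanopatterned roughness of 1.2 nm.

**Height-difference correlation function.**
$g(r) = \langle [h(x+r) - h(x)]^2 \rangle$, averaged over all scan lines
along one raster axis. Two exact references anchor the estimator:
uncorrelated noise gives $g \equiv 2 S_q^2$, and a sinusoid of wavelength
$\lambda$ gives $g(r) = (A^2/4)\,(1 - \cos 2\pi r/\lambda)$. The first
interior maximum of $g$ at lag $r_1$ therefore yields the periodicity
$\lambda = 2 r_1$ and amplitude $A = \sqrt{2 g(r_1)}$ *exactly* for a
sinusoidal surface; $r_1$ is refined to sub-pixel accuracy by a parabola
through the three samples around the discrete maximum. On a 512-pixel,
1 µm raster this recovers the study's 29.3 nm / 1.5 nm ripple to 0.2%.

Detection is guarded twice. The *prominence* of the first maximum
(its rise above the preceding minimum, relative to its own value) rejects
flat, uncorrelated surfaces. A *dip* requirement — $g$ must fall again
after the maximum by the same relative amount within three times its lag —
rejects smoothly correlated surfaces, whose $g$ rises monotonically to a
plateau on which small sampling bumps would otherwise masquerade as very
prominent "first maxima". Both thresholds default to 0.2; the closed
forms above put genuine ripples near 1 on both measures, so the defaults
are not delicate.

Because the averaging direction must coincide with the ripple wave
vector, `rippleMetrics()` computes the HDCF along both axes and keeps the
more prominent detection. This auto-selection is intended for bare
substrate characterization; on aggregate-covered images, blob-scale
height correlations can dominate either axis, and the spectral route
below is the robust one.

**2D spectrum and anisotropy peaks.** The centred power spectrum (mean
removed, periodic Hann window) of a rippled surface shows a
point-symmetric peak pair at $\pm f_0$ along the wave vector; a flat
surface is isotropic. A candidate peak must (i) be an 8-neighbourhood
local maximum, (ii) exceed 30 times the median power of its own frequency
annulus — an orientation-free background reference that makes the test
scale-free, (iii) carry at least $10^{-4}$ of the strongest off-DC bin's
power (numerically empty bins can sit over an equally empty annulus), and
(iv) lie outside the DC neighbourhood (3 bins; long-range roughness lives
there) and away from the $f_x = 0$ column (2 bins; residual scan-line
offsets put genuine power exactly there). The annulus-prominence
threshold of 30 sits well above the largest power/median ratio an
isotropic spectrum of this size produces (~19 in expectation) and orders
of magnitude below a coherent ripple's peak.

## Ripple removal by Fourier notch subtraction

To keep a single height threshold from cutting aggregates on ripple
crests, the ripple's frequencies are subtracted before segmentation. One
notch is placed per detected peak pair, radius 0.25 |f₀| — wide enough to
cover the quasi-sinusoidal period jitter of real ripple patterns, far
from DC.

The notch has two realizations because two desirable properties conflict.
A ripple crossing the raster with a non-integer number of periods leaks
power across the whole frequency axis of the DFT (the leakage is the
spectral representation of the envelope truncation, not removable by any
boundary trick — mirror extension was measured *worse*, 14% residual
versus 6.5%, because the phase-reversed continuation still truncates the
coherent envelope). A masked inverse transform therefore leaves a border
band of ripple that no finite notch disk captures.

* `method = "demodulate"` (default): multiply by
  $e^{-2\pi i f_0 \cdot x}$, estimate the slowly varying complex envelope
  with a Gaussian smoother of frequency width radius/2 whose kernel is
  renormalized at the borders, subtract
  $2\,\mathrm{Re}(A e^{2\pi i f_0 \cdot x})$. Spectrally this is a
  Gaussian notch; spatially it has no wraparound artefacts. A pure
  sinusoid is removed to 0.96% of its amplitude everywhere including the
  borders; a 30 nm Gaussian blob riding on the ripple changes by
  2 × 10⁻⁶ of its height. It is not exactly idempotent (a smoother is not
  a projection); a second pass moves the field by ~2% of the ripple
  amplitude.
* `method = "mask"`: zero the tapered disk (raised cosine over the outer
  quarter of the radius) in the plain DFT. Exactly real, exactly
  mean-preserving, idempotent outside the taper band, and the removed
  variance equals the spectral power in the notch (Parseval; returned as
  an attribute). Retains the border leakage band.

The demodulation method removes a ripple with strong period jitter
(± 4.3 nm phase diffusion) only partially (~half), since the jittered
line is broader than the notch; this is a known limitation, not exercised
by the default presets.

## Flattening and the zero basis

The paper-trail for volume numbers runs through the flattening
conventions, so they are spelled out:

1. least-squares plane fit and subtraction;
2. a second plane fit restricted to background pixels (below the
   background median + 3 robust SD) — fitting through the aggregates
   would drag the zero plane up into the deposits and bias every
   zero-basis volume low (measured −10% on dense scenes);
3. median line levelling: per-row offsets estimated as cumulated medians
   of row-to-row differences, medians taken over background columns
   (a near-horizontal fibril spans most of a scan line and would
   otherwise corrupt every subsequent row's offset);
4. after ripple filtering, a direct per-row background-median polish:
   unlike the cumulative form its estimation errors do not integrate
   into a slow drift down the image. It must run after filtering —
   per-row medians over differing column subsets of a *rippled*
   background would sample the ripple unevenly and inject offsets;
5. the background median is placed at z = 0, which is the basis plane of
   all volumes.

Plane subtraction interacts weakly with periodic content: a centred
cosine of integer period count is exactly orthogonal to the plane basis,
while a sine phase projects onto the ramp with slope $-6A/(\pi n L)$ —
per-mille scale for realistic period counts, and reproduced exactly by
the fit (this is a property of least squares, not an artefact).

One trade-off is deliberate: line levelling also absorbs part of any
genuinely long-ranged *y*-variation of the surface. On the nanopatterned
preset the characterize pipeline reports S_q ≈ 0.95 nm against the
planted 1.20 nm for this reason; the composite-roughness acceptance
measurement therefore evaluates S_q on the composed field directly.

## Grain segmentation and morphometrics

**Mark by threshold.** Connected components of $\{h > t\}$ under
8-connectivity (thin diagonal fibrils fragment under 4-connectivity;
4 is available). Components are numbered in raster order of their
topmost-leftmost pixel; sub-`minAreaPx` components are dropped; grains
touching the border are kept but flagged. The threshold is per-image, as
in practice: either explicit (the study's example image used 8.2 nm) or
the reproducible rule median + k·MAD of the filtered image (default
k = 5) — robust statistics, because aggregates inflate the plain mean
and Sq.

**Zero-basis volume.** $V = \sum_{\text{grain}} h \cdot p_x p_y$,
integrated from z = 0, not from the threshold plane. The closed form for
a Gaussian blob ($H e^{-r^2/2\sigma^2}$ over $h > t$) is
$2\pi\sigma^2 (H - t)$, an independent oracle the estimator matches to
0.3% at 2 nm pixels.

**Projected boundary length.** Marching squares on each grain's mask.
When the height field is available (the default inside `grainSummary()`),
the contour crossing on each pixel edge is linearly interpolated from the
corner heights, so the contour of a smoothly sloped grain converges to
the continuum outline: a cone-profile disk of 100-pixel radius measures
2πR + 0.6%, a thresholded Gaussian blob +0.01%. On a bare mask the
crossings sit at edge midpoints; this degenerate form reproduces the
hand-derivable constants (isolated pixel $2\sqrt2\,p$, 2×2 square
$4p + 2\sqrt2\,p$) and is checked against a brute-force tracer on all
2×2 configurations — but its contour of a large *binary* disk converges
to ≈1.052 × 2πR, an intrinsic bias of mid-edge marching squares and the
reason the interpolating form is preferred. Checkerboard saddles are
resolved consistently with 8-connected foreground (both resolutions have
equal length; only topology differs). Border grains are closed along the
border by mirroring the edge pixel's height about the threshold, which
pins the crossing to the border mid-edge.

**Spreading coefficient.** $L/V$ (nm⁻²): large for frayed, star-like
aggregates, small for compact ones. Exact contracts: under lateral
magnification by $s$, $L \to sL$, $V \to s^2 V$, spreading $\to$
spreading/$s$; doubling heights halves it.

**Artefact rules.** The study excluded segmentation artefacts manually;
here the same step is a deterministic rule set (minimum area, minimum
peak height, exclusion rectangles, explicit keep/drop lists) with a
provenance record of which rule removed each grain. The aggregate-scene
analyses in the tests use `minMaxHeight = 2` nm and `minArea = 500` nm²,
which drop the few-pixel specks that barely clear a low threshold.

## Condition statistics

Per (surface, incubation time, metric): mean, SEM (sample SD over
$\sqrt n$; 0 for n = 1), n. Replicates are pooled. Condition ratios carry
a first-order (delta-method) standard error. A "morphological transition"
in a time course is declared at the largest consecutive increase of the
mean when it exceeds 2 × the pooled SEM of the two time points — a stated
rule in place of reading the jump off a figure. No hypothesis tests and
no multiple-testing machinery: these are descriptive summaries.

## The synthetic-scene generator

The generator is first-class code: it defines the conditions under which
every estimator is validated.

* **Flat substrate:** uncorrelated Gaussian roughness, σ = 0.2 nm — the
  untreated-wafer roughness.
* **Ripple:** $h = (A/2)\sin 2\pi\phi(x)$ with $\phi$ advancing by
  pixel/λ; λ = 29.3 nm, A = 1.5 nm peak-to-peak. Optional wavelength
  jitter is phase diffusion (a smoothly varying local wavelength),
  matching the quasi-sinusoidal character of real patterns. The presets
  use zero jitter: the printed period spread is an across-image spread,
  and a jitter-free preset anchors recovery tests to the central values.
* **Long-range roughness:** Gaussian autocorrelation
  $C(r) = \sigma^2 e^{-r^2/2\ell^2}$ with rms 1.08 nm and ℓ = 300 nm,
  synthesized by *constrained random-phase* spectral synthesis:
  deterministic amplitudes $\propto e^{-\pi^2 \ell^2 f^2}$, uniform
  antisymmetrized phases. With ℓ = 300 nm only ~3.5 independent patches
  fit on (1 µm)², so an unconstrained Gaussian sample's Sq would scatter
  by ±30% and the planted roughness would be a poor ground truth;
  constrained synthesis realizes the target Sq exactly in every sample
  (Parseval) while the height distribution remains asymptotically
  Gaussian. This is a deliberate generator design choice.
* **Aggregates:** isotropic Gaussian blobs (heights tens to ~200 nm),
  and fibrils as Gaussian-cross-section ridges along worm-like paths
  (random-walk heading; "radial" mode runs outward from a core with low
  curvature, "entangled" mode steers between two cores with high
  curvature). Fibril defaults — height 3 nm, cross-section σ 6 nm — are
  typical surface-bound amyloid dimensions, configurable, and not tied
  to any printed value. Aggregates combine by pointwise maximum before
  addition to the substrate, so crossing fibrils do not double in height.
* **Instrument layer:** white noise (0.05 nm) and per-scan-line offsets
  (0.2 nm), applied after the ground truth is recorded.
* **Determinism:** one seed per scene; the RNG consumption order
  (surface, then aggregates in list order, then noise, then offsets) is
  fixed, so scenes are bit-reproducible across runs.

The `radial` and `entangled` presets are volume-matched analytically
(core heights solved so total planted volume agrees), isolating shape:
across seeds the radial scenes measure a 3–4× larger mean spreading
coefficient — the direction of the study's flat-versus-nanopatterned
contrast — with total measured volumes agreeing within ~15%.

What the generator does *not* emulate: tip convolution (all widths are
sample-plane widths), feedback artefacts and streaks beyond constant
per-row offsets, ripple formation physics, aggregate growth kinetics, or
realistic aggregate number densities per field of view. Passing recovery
tests therefore demonstrates the correctness of the estimators under
controlled conditions — not that instrument data will be as kind.

## Problem sizes and numerical choices

Validation rasters are 512 × 512 over (1 µm)², the native scan geometry
of the study's figures; property tests use 256–512 pixel rasters. The
filter-fidelity suite runs 20 seeded scenes; the shape-contrast suite 10
seed pairs. Degenerate inputs fail loudly: coincident profile endpoints,
sub-Nyquist ripple wavelengths, thresholds ≤ 0, notches covering DC, and
contradictory keep/drop rules are all errors, not warnings. Ties in the
transition detector resolve to the earliest interval; saddle ties in
marching squares resolve toward connected foreground.

## Known limitations

* HDCF ripple metrics assume a substrate-dominated image; characterize
  bare reference areas, not aggregate fields (use the FFT peaks there).
* The demodulation notch under-removes strongly jittered ripples.
* Line levelling absorbs part of genuinely long-ranged y-variation
  (quantified above).
* Absolute boundary lengths depend on the contour convention; versus the
  original analysis software a convention-dependent offset of up to
  ~10% should be expected, which cancels in within-study comparisons.
* Ripples with wave vector along the slow-scan axis are excluded from
  spectral peak detection by default (they are confounded with scan-line
  artefacts); set `scanAxisExcludeBins = 0` knowingly.
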