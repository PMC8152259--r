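# afmorph

Quantitative morphometry of protein aggregates in atomic force microscopy
(AFM) height images, on flat and nanopatterned substrates.

When amyloid-forming peptides such as hIAPP (human islet amyloid
polypeptide) aggregate on a surface, time-lapse AFM yields height maps
h(x, y) containing compact amorphous deposits (tens to ~200 nm tall) and
worm-like fibrils (micron lengths, few-nm heights). Quantifying how
substrate nanotopography — here, self-organized ion-beam ripple patterns —
modulates aggregate morphology requires a reproducible chain of image
operations that this package implements end to end:

1. **Surface characterization.** RMS roughness
   S_q = sqrt(mean((h − mean(h))²)); the one-dimensional height-difference
   correlation function g(r) = ⟨[h(x + r) − h(x)]²⟩, whose first maximum at
   lag r₁ gives the ripple periodicity λ = 2 r₁ and peak-to-peak amplitude
   A_pp = sqrt(2 g(r₁)) (both exact for a sinusoidal modulation); and the
   centred 2D FFT power spectrum with detection of the point-symmetric
   anisotropy peaks a ripple produces along its wave vector.
2. **Fourier notch subtraction.** The ripple's spatial frequencies are
   removed around each detected peak (and its mirror) so that a single
   height threshold can segment aggregates without cutting them on the
   ripple crests. The default realization is a Gaussian notch via complex
   demodulation with border-renormalized envelope smoothing, which removes
   a pure sinusoid to below 1% everywhere in the image; a classic
   masked-DFT notch (tapered disk, exact Parseval bookkeeping) is also
   provided.
3. **Grain morphometrics.** Mark-by-threshold segmentation (8-connected),
   zero-basis volume V = Σ h · p_x p_y, projected boundary length L from a
   marching-squares contour with height-interpolated edge crossings, the
   spreading coefficient L/V (large = frayed, star-like; small = compact),
   and declarative artefact-exclusion rules.
4. **Condition statistics.** Per-(surface × incubation time) mean ± SEM
   tables, condition ratios with propagated errors, and a reproducible
   rule for flagging morphological transitions in a time course.
5. **Synthetic scenes.** A generator for flat and nanorippled substrates
   with planted blobs and fibrils and *exact* ground truth (component
   fields, masks, true volumes), so that every stage above has a recovery
   test and the repository needs no instrument data.

Input formats: Gwyddion Simple Field (.gsf) and plain-text ASCII height
grids, both readable and writable; profiles, HDCF curves and grain tables
export as CSV; reports as JSON.

## Worked example

Generate a nanopatterned scene with three planted amorphous aggregates and
two fibrils, then run the full analysis chain (level → detect peaks →
notch filter → threshold at 8.2 nm → grains):

```r
library(afmorph)

scene <- genScene(scenePreset("filterTest", seed = 42))
res   <- analyzeField(scene$field, threshold = 8.2)

res$peaks
#>      fx fy freqMag     power prominence
#> 1 0.034  0   0.034 580788000      88036

res$morphometrics[, c("grainId", "areaNm2", "volumeNm3", "boundaryNm",
                      "spreadingPerNm2", "maxHeightNm")]
#>   grainId areaNm2 volumeNm3 boundaryNm spreadingPerNm2 maxHeightNm
#> 1       1   33089   1321476      646.1       0.0004890      112.92
#> 2       2   12970    340430      403.7       0.0011860       60.73
#> 3       3   22552    829941      533.6       0.0006429      100.15

trueVolumesAbove(scene$truth, 8.2)
#> [1]  343277 1324540  830893       0       0
```

The single anisotropy peak sits at |f| = 0.034 nm⁻¹ = 1/29.3 nm, the
generating ripple wavelength. The three measured grain volumes recover the
planted ground truth to within 1% (the two zeros are the planted fibrils,
whose 3 nm ridges lie below the 8.2 nm threshold, as in the study's
images). Characterizing the bare substrate instead recovers the generating
surface parameters:

```r
sub <- genScene(scenePreset("nanopatterned", seed = 3))$field
rippleMetrics(levelField(sub))
#> RippleMetrics: periodicity 29.42 nm, peak-to-peak amplitude 1.504 nm (axis x, prominence 1.00)
```

A thin command-line front end over the same functions lives in
`inst/scripts/afmtool.R` (subcommands `simulate`, `characterize`,
`analyze`, YAML run configs, exit codes 0/1/2).

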