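---
title: "Quantifying autophagic flux from fluorescence images: methods and design"
author: "punctaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying autophagic flux from fluorescence images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Autophagy induction is scored in microscopy by counting cytoplasmic LC3
puncta — dots of lipidated LC3 on autophagosomal membranes — in the green
channel of fixed cells whose nuclei are DAPI-stained in the blue channel. Two
practical complications shape the whole pipeline. First, the readout must be
normalized per cell, so nuclei have to be counted even when they touch each
other or the image border. Second, in crowded fields individual puncta are
often too close to resolve as separate dots, so the pipeline uses total
**puncta area** per cell, not puncta number, as its headline statistic.

`punctaflux` implements this measurement end to end, together with a
seeded synthetic-image generator that renders images with exact ground truth,
so every stage can be validated quantitatively without microscopy data.

## Nuclei segmentation and fractional cell counting

The blue channel is Gaussian-smoothed (`smoothing_sigma`, default 2 px) and
binarized at an Otsu threshold. The threshold is found by exhaustive search
over a 256-bin histogram of the smoothed image (binned over its own min–max
range), maximizing the between-class variance
$\omega_1\omega_2(\mu_1-\mu_2)^2$. Class means are accumulated from the
actual pixel intensities per bin rather than bin midpoints; for integer-valued
(8- or 16-bit) data this makes the binned search identical to the classic
exhaustive search over gray levels, which is how the test suite validates it.
Ties are broken toward the lowest threshold; a constant image is an error
("degenerate histogram"), not a silent all-background mask.

Touching nuclei are separated by watershed on the negated Euclidean distance
transform. Rather than explicitly seeding at distance-map maxima with a
minimum separation, we use the equivalent merge-control formulation exposed
by `EBImage::watershed`: local maxima whose basins are shallower than
`watershed_tolerance` (default 1 px of distance) relative to their
neighbors are merged into them. This prevents over-segmentation of single
nuclei while reliably splitting discs overlapping by up to roughly half a
radius, and is deterministic for fixed input. Labels smaller than `min_area`
(default 200 px², well below any real nucleus at typical magnification)
are removed as staining debris, and surviving labels are renumbered 1..K.

Cell counting treats border-clipped nuclei fractionally: a nucleus touching
the image border contributes $\min(1, A/\bar{A})$ cells, where $A$ is its
visible area and $\bar{A}$ the mean area of *interior* nuclei measured over
the whole dataset (not per image — single images may have too few interior
nuclei for a stable mean). The cap at 1 encodes that a clipped nucleus
cannot represent more than one cell. Because magnification and pixel size
are acquisition-specific, all geometric parameters are expressed in pixels.

### Bright-cell exclusion

Transfected cells occasionally express so much diffuse reporter that puncta
cannot be resolved over them. These are detected as outliers of the
per-nucleus mean intensity using the Tukey fence $Q_3 + k\,\mathrm{IQR}$
(`bright_fence_k`, default 1.5), computed on the **green** channel by
default: the stated purpose of the exclusion is that the *puncta channel* is
unreadable there, so that is the channel whose brightness matters (blue is
available via `bright_channel` for DAPI-driven artifacts). Two guards make
the fence usable in practice: with fewer than four nuclei no cell is ever
flagged (quartiles of three values are meaningless), and a flagged nucleus
must also exceed `bright_min_ratio` (default 1.5) times the median nucleus
mean. Without the second guard, an image whose nuclei are all equally dim
has an IQR dominated by pixel noise and the fence trips on fluctuations of a
fraction of a percent; "abnormally bright" is intended to mean bright in
absolute terms, not merely the brightest of near-identical cells. Excluded
nuclei are removed from the cell count, and an exclusion mask — the flagged
labels dilated by a disc of `halo_radius` px (default 25, the "surrounding
area"; unquantified in the field, so configurable) — suppresses puncta
detections around them.

## Puncta detection and the area readout

Puncta are detected by scale-normalized Laplacian-of-Gaussian (LoG) blob
detection. The detection channel is filtered with negated LoG kernels
$-\sigma^2\nabla^2 G_\sigma$ at `n_scales` = 10 sigmas spaced linearly over
[`sigma_min`, `sigma_max`] = [1, 5] px — a range bracketing
diffraction-limited spots at common magnifications — and blobs are the local
maxima of the (row, col, scale) response volume above a threshold. The
threshold is expressed relative to the image maximum (default
`threshold_rel` = 0.1) so 8- and 16-bit inputs behave identically.
Overlapping detections are pruned greedily, keeping the stronger response,
when their disk overlap fraction exceeds `overlap_max` = 0.5; ordering is
fully deterministic (response, then row, col, sigma). For an ideal Gaussian
spot of width $\sigma_0$, the scale-normalized response peaks at
$\sigma = \sigma_0$, so the detecting scale estimates the spot size; the
linear 10-scale grid quantizes this estimate to within about 15%.

Blobs whose center pixel lies inside a nucleus label or a bright-cell halo
are discarded — membership is judged by the center, the simplest reading of
"blobs found in regions covered by nuclei" (a disk-overlap mode would also
discard legitimate perinuclear puncta whose centers are cytoplasmic).
Optionally, images with salt-type speckle noise are median-filtered first
(`despeckle_window`, odd, default off); edge pixels use the truncated
neighborhood.

Each surviving punctum is scored as a circle of radius $c\sigma$ and area
$\pi(c\sigma)^2$. The proportionality constant defaults to $c=\sqrt 2$
because the bright core of a Gaussian blob — the region above the
inflection of the LoG response — has radius $\sqrt2\sigma$; $c$ is
configurable and echoed into the run metadata since only proportionality,
not the constant, is inherent to the method. The per-sample statistic is
total puncta area divided by the effective (fractional) cell count.

## Tandem-reporter classification

With the tandem mCherry-GFP-LC3 reporter, GFP is quenched at lysosomal pH,
so green+red puncta are autophagosomes and red-only puncta are
autolysosomes. Detection runs on the **red** channel (mCherry persists in
both compartments, so red is the superset). Each red punctum is scored
green-positive iff its disk mean green exceeds
`green_positivity_factor` × background (default factor 2), where the
background is the median green intensity over pixels outside every punctum
disk and outside exclusion masks. A background-relative rule was chosen over
Otsu-on-punctum-intensities because it remains well-defined when one class
is absent (all-autophagosome or all-autolysosome fields), which bimodal
thresholding cannot handle; a fixed numeric background is also accepted.
The rule is monotone in the factor: raising it can only reclassify
autophagosomes as autolysosomes.

## Colocalization and statistics

Marker overlap is quantified by the pixelwise Pearson correlation over an
ROI (at least 2 pixels, error if either channel is constant there). The
default ROI is the whole image minus bright-cell halos; per-cell ROIs are
accepted where callers have them. Manders/Costes variants are out of scope —
Pearson is the statistic this pipeline reports.

Group comparisons use the unpaired, equal-variance Student's t-test
(`welch = TRUE` switches to the unequal-variance form), with the
conventions: zero pooled variance with equal means yields p = 1; with
unequal means it is an error rather than a spurious infinite t. Summaries
are mean ± SD with the n−1 denominator, reported over independent
experiments; the pipeline's statistics operate on per-experiment (or
per-image) means rather than pooled per-cell values, matching how replicate
experiments are normally summarized.

## The synthetic generator: what it emulates, and what it does not

The generator renders, from a `synthetic_spec` and a seed (identical spec +
seed gives bit-identical output):

* **Nuclei**: cosine-tapered discs (radius ~ N(18, 2²) px by default) with
  a 2 px soft edge, placed by rejection sampling with a minimum center
  separation of 2.2 radii; a chosen number are deliberately clipped by an
  image edge. The taper keeps the intensity histogram cleanly bimodal — the
  fixtures are designed to satisfy the segmentation method's own
  assumptions, not to defeat them.
* **Puncta**: isotropic Gaussian spots (σ uniform in [1.5, 3] px, amplitude
  0.5 over a 0.05 background) placed in the cytoplasmic annulus around
  their owner nucleus, never overlapping any nucleus disc, with a
  configurable minimum separation (default 8 px). Each punctum's class is
  Bernoulli(`autolysosome_fraction`); autophagosomes render in green and
  red, autolysosomes in red only.
* **Bright cells**: a high-amplitude diffuse green plateau (default 0.9)
  over the nucleus and a surrounding halo.
* **Noise**: Gaussian read noise (default sd 0.01, i.e. spot SNR 50),
  Poisson shot noise at a photon scale, or salt-impulse speckle (removable
  by the median filter), applied per channel and clamped to [0, 1].

The ground truth records every nucleus (center, radius, border flag, clip
fraction) and punctum (center, true σ, class, owner), and the true
effective cell count applies the pipeline's own counting rule to the true
geometry: border nuclei contribute
$\min(1, A_\text{visible}/\pi(\mu_r^2+\sigma_r^2))$, the denominator being
the expected full-nucleus area under the spec.

Colocalization fixtures are built from two smoothed Gaussian random fields
with the noise field orthogonalized exactly against the signal before
mixing $B=\rho A + \sqrt{1-\rho^2}E$, so the realized pixelwise correlation
equals the target to float precision — spatial autocorrelation from the
smoothing therefore cannot bias the fixture away from its nominal ρ.

What the generator does **not** emulate: real point-spread functions
(spots are ideal Gaussians, not Airy patterns), 3D defocus, uneven
illumination, cytoplasmic autofluorescence texture, chromatic
misregistration, or camera-specific noise. Passing the recovery tests
therefore demonstrates that the algorithms are implemented correctly and
behave as designed on data satisfying their assumptions — it does not by
itself certify performance on any particular microscope's output, where
threshold and scale-range defaults may need adjustment.

## Problem sizes and numerical choices

The validation suite runs entirely on synthetic data at sizes chosen to
exercise every code path with stable statistics: 512×512 px images with
8–15 nuclei and ~50–120 puncta for recovery and contrast experiments
(20 images for detection recovery; 2 conditions × 3 experiments × 7 images,
≥100 cells per experiment, for the twofold-contrast experiment); 320×320 px
with 2 of 7 nuclei border-clipped, 20 images, for fractional counting;
~650 tandem puncta for class-fraction recovery; 10,000 null replicates for
t-test calibration. Determinism is asserted at the byte level on rerun
CSVs. Degenerate inputs are handled explicitly throughout: empty masks
produce empty labelings (not errors), empty puncta lists produce zero
summaries, constant rasters fail Otsu and Pearson with named errors, and
placement that cannot satisfy its geometric constraints within the retry
budget reports the constraint rather than looping forever.

Coordinates are (row, col), 1-based and pixel-centered, matching R's matrix
indexing; all CSV outputs state this in a header comment.

## Known limitations

* No per-cell assignment of puncta: normalization is by cell count per
  image, not ownership, so cell-to-cell heterogeneity within an image is
  not resolved.
* The LoG scale grid bounds detectable spot sizes to [`sigma_min`,
  `sigma_max`]; spots outside it are found at the nearest grid scale or
  missed.
* Watershed merge control uses a single global tolerance; unusually
  elongated or dumbbell-shaped nuclei may still over- or under-split.
* The bright-cell fence assumes at most a minority of cells are
  pathologically bright; if most cells are, the median guard suppresses
  flagging entirely.
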