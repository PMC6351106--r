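# punctaflux

Automated quantification of autophagic flux from multi-channel fluorescence
microscopy images, for cell biologists measuring autophagy induction by
LC3-puncta imaging and for anyone who needs that measurement to be
reproducible, scripted, and testable.

## What it measures

Autophagy induction is read out as cytoplasmic LC3 puncta. Because nearby
puncta often cannot be resolved as separate dots, the headline statistic is
**total puncta area per cell**:

- **Cell counting** — nuclei are detected in the DAPI (blue) channel by
  Gaussian smoothing + Otsu thresholding, split by watershed on the distance
  transform, and area-filtered. Nuclei clipped by the image border count
  fractionally as `min(1, area / mean interior nucleus area)`, the mean
  being measured over the whole dataset. Abnormally bright cells (diffuse
  saturating reporter, puncta unreadable) are flagged by a Tukey outlier
  fence on per-nucleus mean intensity and excluded together with a
  surrounding halo.
- **Puncta detection** — scale-normalized Laplacian-of-Gaussian (LoG) blob
  detection over a grid of scales; each blob detected at scale σ is scored
  as a circle of radius √2·σ and area π(√2·σ)², and blobs whose centers lie
  in nuclei or excluded halos are discarded. An optional median filter
  removes salt-type speckle first.
- **Tandem flux classification** — with the mCherry-GFP-LC3 reporter,
  detection runs on the red channel and each punctum is classified
  autophagosome (green+red) or autolysosome (red only, GFP quenched at
  lysosomal pH) by comparing its disk mean green against a
  background-relative threshold.
- **Colocalization** — pixelwise Pearson correlation between two channels
  over an ROI, aggregated as mean ± SD per condition.
- **Statistics** — unpaired Student's t-test (pooled variance; Welch
  optional) and mean ± SD summaries.

A seeded synthetic-image generator renders DAPI-like nuclei (including
border-clipped and bright cells), Gaussian puncta of known position, size
and class, and noise — with exact ground truth — so the entire pipeline is
validated quantitatively without microscopy data. See
`vignettes/punctaflux-methods.Rmd` for the model, parameter meanings,
defaults, and design decisions.

## Worked example

The `analysis/` scripts run a complete study on synthetic data: two
conditions generated at a twofold difference in puncta load, a
tandem-reporter condition with a 40% autolysosome fraction, and a
colocalization contrast at ρ = 0.3 vs 0.6.

```sh
Rscript analysis/01_simulate.R        # writes results/dataset (9 images + truth)
Rscript analysis/02_quantify_puncta.R
Rscript analysis/03_tandem_flux.R
Rscript analysis/04_colocalization.R
Rscript analysis/05_statistics.R
```

Output of `02_quantify_puncta.R`:

```
          id condition effective_cell_count puncta_count puncta_area_per_cell
1 control_01   control             11.73639           75             185.9283
2 control_02   control             10.87953           49             146.8835
3 control_03   control             10.91060           52             174.6406
4 induced_01   induced             11.29763          106             297.9457
5 induced_02   induced             10.88894          123             357.4060
6 induced_03   induced             11.11495          107             309.3819
mean puncta area per cell: control 169.2 px^2, induced 321.6 px^2 (ratio 1.90)
```

The effective cell counts are fractional because two of twelve nuclei per
image touch the border; the recovered per-cell puncta-area ratio (1.90)
tracks the generated twofold contrast. `03_tandem_flux.R` then reports

```
classified 229 autophagosomes + 152 autolysosomes
autolysosome fraction: recovered 0.399 vs generated 0.399
```

and `05_statistics.R` declares the condition contrast significant:

```
control: 169.2 +/- 20.1 px^2 per cell (n = 3 images)
induced: 321.6 +/- 31.6 px^2 per cell (n = 3 images)
t = -7.0581, df = 4, p = 0.002125 (significant at alpha = 0.05)
```

Equivalent programmatic use:

```r
library(punctaflux)
gen <- generate_synthetic_image(synthetic_spec(seed = 1))
ln  <- segment_nuclei(gen$image)
cc  <- count_cells(list(ln))
p   <- quantify_image_puncta(gen$image, ln)
summarize_sample(p, cc[1, ])
```

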