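# MuellerTMA

Computational pipeline for **transmissive Mueller-matrix microscopy of
tissue microarrays (TMAs)**. Polarized-light microscopy is label-free:
instead of staining, it measures how a thin tissue section transforms the
polarization state of light. Birefringent collagen in normal stroma
introduces a large linear phase retardance; in cancerous tissue the
collagen is degraded and the retardance collapses. This package implements
the full computational chain that turns a polarimetric acquisition into
per-spot texture features that separate the two classes — and, because no
public Mueller-matrix TMA data exist, a synthetic phantom generator that
makes every stage testable end to end.

It is intended for researchers in tissue polarimetry and quantitative
pathology image analysis.

## The model

A polarization state generator prepares the illumination in one of four
states H, P, V, R (linear 0°, linear 45°, linear 90°, right circular); an
analyzer selects one of the same four states after the sample. The camera
records, for sample Mueller matrix **M**,

    I_XY = 1/2 · a_Y · (M p_X),   X, Y ∈ {H, P, V, R}

— 16 images per measurement. Each Mueller element m_ij is a fixed linear
combination of these intensities (`mm_element_formulas()`), validated by a
forward/reconstruct round trip to < 1e−10. The per-pixel matrix is
normalized by m11 and factored with the Lu–Chipman forward polar
decomposition

    M = M_Δ · M_R · M_D

into depolarizer, retarder and diattenuator. From the retarder factor the
pipeline maps the two tissue parameters:

* **δ** — linear phase retardance,
  `δ = acos( sqrt((mR22+mR33)² + (mR32−mR23)²) − 1 )` ∈ [0, π];
* **θ** — equivalent-waveplate fast-axis azimuth, from the Levi-Civita
  contraction of the linear-retarder block, `θ = ½·atan2(r2, r1)` ∈ [0, π).

Grayscale renderings of the δ and θ maps (fixed ranges [0, π] → [0, 1])
are then characterized per TMA spot by distribution statistics (raw
kurtosis and skewness), gray-level co-occurrence matrix features
(contrast, energy, homogeneity, correlation) and Tamura texture features
(coarseness, contrast, line-likeness).

## Worked example

Simulate a two-spot phantom (one normal, one cancerous core, radius
40 px), acquire the 16 images with read noise, and run the full pipeline:

```r
library(MuellerTMA)

spec <- phantom_spec(c(120, 220), rbind(c(60, 60), c(60, 160)),
                     spot_radius = 40, c("normal", "cancer"),
                     noise = noise_spec(gaussian_sd = 0.002), seed = 7)
truth <- generate_ground_truth(spec)
stack <- render_stack(truth)                      # 16 intensity images

res <- run_pipeline(pipeline_config(output_dir = "demo", seed = 7),
                    stack = stack,
                    spot_classes = data.frame(row = c(60, 60),
                                              col = c(60, 160),
                                              class = c("normal", "cancer")))

res$spots[, c("spot_id", "row", "col", "radius", "class")]
#>   spot_id row col radius  class
#> 1       1  60  60  39.99 normal
#> 2       2  60 160  39.99 cancer

res$features[res$features$param == "delta",
             c("class", "gray_median", "kurtosis", "skewness",
               "glcm_correlation", "tamura_contrast")]
#>   class gray_median kurtosis skewness glcm_correlation tamura_contrast
#>  normal      0.1591     2.86  -0.0764            0.763          0.0123
#>  cancer      0.0319     2.85   0.2096            0.546          0.0121
```

The spots are auto-detected on the m11 (total transmittance) image to
sub-pixel-accurate centers. The δ-grayscale median separates the classes
exactly as constructed — the normal spot's median δ is 0.500 rad
(grayscale 0.159 = 0.5/π) against the cancer spot's 0.102 rad — and the
GLCM correlation is higher for the normal spot, whose fiber texture is
spatially coherent. `run_pipeline()` also writes the element images,
δ/θ/Δ/D/R maps (float32 TIFF + JSON sidecars), the feature CSV, a summary
JSON with per-class medians and difference signs, and a structured log.

A command-line front end with `simulate`, `reconstruct`, `decompose`,
`features`, `run` and `fixtures` subcommands is installed at

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/muellertma", package = "MuellerTMA"))') --help
```

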