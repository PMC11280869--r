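---
title: "Mueller-matrix microscopy of tissue microarrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mueller-matrix microscopy of tissue microarrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MuellerTMA)
```

## The measurement model

A transmissive Mueller-matrix microscope prepares the illumination in one
of four polarization states — linear horizontal (H), linear at 45 degrees
(P), linear vertical (V) and right circular (R) — and analyzes the light
transmitted through the sample in the same four states. With generator
Stokes vector $p_X$ and analyzer state $a_Y$, the recorded intensity is

$$ I_{XY} = \tfrac12\, a_Y^\top M\, p_X, $$

where $M$ is the sample's per-pixel $4\times4$ Mueller matrix and the
factor $\tfrac12$ is the transmission of an ideal analyzer. A complete
measurement is therefore exactly 16 images, one per $(X, Y)$ pair.

`MuellerTMA` models the generator and analyzer at the level of their net
Stokes states rather than as explicit polarizer/waveplate pairs: the
hardware schedule only ever produces those four states, and every
reconstruction formula depends on the state-pair intensities alone.

### Element recovery

Each Mueller element is a fixed linear combination of the 16 intensities;
for example $2\,m_{11} = I_{HH}+I_{HV}+I_{VH}+I_{VV}$ and
$2\,m_{12} = I_{HH}+I_{HV}-I_{VH}-I_{VV}$. The full coefficient table is
exposed by `mm_element_formulas()`. The table was derived from the closed
form of $I_{XY}$ above, and every row is verified in the test suite by a
forward-simulate/reconstruct round trip on random physical matrices
(noiseless max element error below $10^{-10}$). The element-table variants
commonly printed for this protocol disagree among themselves in the
trailing sign patterns of the $m_{33}$, $m_{34}$ and $m_{44}$ rows; this
package treats the round-trip identity — not any printed table — as the
definition of the measurement algebra, and the coefficients here are the
minimal sign-consistent completion.

The sums return $2M$, so the global scale is meaningless; the
reconstruction keeps matrices unnormalized and `normalize_m11()` divides
by $m_{11}$ explicitly, masking background pixels (below 5% of the
99th-percentile $m_{11}$ by default) out of every downstream statistic.

## Polar decomposition and the two tissue parameters

Each normalized pixel matrix is factored (Lu–Chipman forward order) as

$$ M = M_\Delta\, M_R\, M_D , $$

diattenuator first, then retarder, then depolarizer. The scalar summaries
are the diattenuation $D = \lVert(m_{12}, m_{13}, m_{14})\rVert$,
the depolarization $\Delta = 1 - \tfrac13\lvert\mathrm{tr}\rvert$ of the
depolarizer block, and the total retardance
$R = \cos^{-1}(\mathrm{tr}(M_R)/2 - 1)$.

The two parameters used to separate tissue classes are derived from the
retarder factor:

* **linear phase retardance**
  $\delta = \cos^{-1}\!\big(\sqrt{(m_{R,22}+m_{R,33})^2 +
  (m_{R,32}-m_{R,23})^2} - 1\big)$.
  The *difference* of the off-diagonal elements is essential: it makes
  $\delta$ independent of any circular-retardance component, which the
  construct-and-recover tests pin to $10^{-10}$. A variant with the sum of
  those elements circulates in the applied literature; it fails the
  recovery property for any non-zero fast-axis azimuth and is not used.
* **fast-axis azimuth** $\theta$: the retarder is split into linear and
  circular factors ($\psi = \tfrac12\operatorname{atan2}(m_{R,23}-m_{R,32},\,
  m_{R,22}+m_{R,33})$, $M_{LR} = M_R M_{CR}^{-1}$), the retardance axis is
  assembled by the Levi-Civita contraction
  $r_i = \frac{1}{2\sin\delta}\sum_{jk}\epsilon_{ijk}\,m_{LR}(j,k)$ over
  the $3\times3$ block of $M_{LR}$, and
  $\theta = \tfrac12\operatorname{atan2}(r_2, r_1)$, wrapped to
  $[0, \pi)$. The fast axis is a director: only its value modulo
  180 degrees is meaningful.

Numerical choices: all $\cos^{-1}$ arguments are clamped to $[-1, 1]$ and
clamping events are counted per image; below `delta_cutoff` (default
0.01 rad) the $1/\sin\delta$ in the axis formula is unstable and $\theta$
is reported as undefined (`NA`) rather than noise; pixels whose
decomposition fails outright (ideal-polarizer diattenuation, singular
depolarizer block) are excluded via the quality mask, never clipped into
range. The depolarizer sign is taken from the determinant of the $3\times3$
block, per the standard algorithm. The per-image kernel is compiled
(RcppArmadillo) and is cross-checked against the pure-R single-matrix
implementation in the tests.

In normal cervical stroma, intact collagen fibers are birefringent and
produce large $\delta$; in cancerous tissue the collagen is degraded, so
$\delta$ drops. That direction (normal above cancer) is the one fixed
qualitative contrast the package's validation relies on.

## Texture features

Both parameter maps are rendered as grayscale on **fixed physical ranges**
($\delta: [0, \pi] \to [0, 1]$, $\theta: [0, \pi) \to [0, 1)$), never per
image min/max, so features are comparable across spots and classes.

* **Distribution statistics.** Kurtosis and skewness are the *raw*
  population moments $\mathrm{mean}(z^4)$ and $\mathrm{mean}(z^3)$ with
  $z$ standardized by the $1/n$ standard deviation — deliberately without
  the $-3$ excess correction, so a normal population scores kurtosis 3
  (verified on $10^6$ seeded draws).
* **Histogram summaries** are peak-normalized (tallest bin equals 1), and
  the high-gray fraction counts foreground pixels above 0.8. Peak
  normalization was chosen because the class comparison concerns peak
  heights within a fixed gray range; it is configurable.
* **GLCM.** The foreground is quantized to $N_g = 16$ levels over the
  fixed range; pairs at distance 1 are counted for the four standard
  angles (0, 45, 90, 135 degrees), symmetrically, each offset matrix
  normalized to sum 1 and averaged. Contrast, energy, homogeneity and
  correlation follow the standard definitions; the implementation is
  tested against a naive double-loop oracle ($<10^{-12}$) and against a
  hand-counted two-level checkerboard (contrast 1, energy 0.5,
  homogeneity 0.5, correlation $-1$). Pairs touching background are
  dropped, not zero-filled. None of these defaults is prescribed by the
  measurement itself; they are field-standard and all exposed in the
  configuration.
* **Tamura features.** Coarseness averages the best window scale
  $2^k$ ($k = 1\ldots5$) of the classic opposing-window difference
  criterion and requires at least a $64\times64$ image; contrast is
  $\sigma/\alpha_4^{1/4}$ (the original Tamura normalization; the exponent
  is configurable because abbreviated notations of this formula are
  ambiguous); line-likeness builds a direction co-occurrence matrix from
  Sobel gradient directions (mod $\pi$, 16 bins, edge threshold 10% of the
  maximum gradient, co-occurrence distance 4 px along the local edge
  direction) weighted by $\cos((i-j)\,2\pi/n)$.

## The synthetic TMA phantom

No public Mueller-matrix TMA data exist, so validation uses a phantom
generator whose defaults encode the study conditions:

* circular spots (default radius 40 px — a scaled-down 1.5 mm core; at
  the full-scale 2 µm pixel pitch a core would be about 375 px in radius,
  which is simply slower to process, not different in kind);
* per class, $\delta$ is a Gaussian field (normal: mean 0.5 rad; cancer:
  mean 0.1 rad; sd 0.05 rad) smoothed at a fiber correlation length —
  5 px for normal tissue, 1.5 px for cancer. The short cancer correlation
  length realizes the degradation mechanism: destroyed collagen loses its
  spatially coherent fiber texture, which is what the GLCM correlation
  feature responds to;
* $\theta$ is wrapped-normal on the doubled angle with concentration
  $\rho = \kappa$ (so the order parameter maps to a wrapped-normal sd
  $\sqrt{-2\log\kappa}$ on $2\theta$): $\kappa = 1$ is a perfectly
  aligned axis field, $\kappa = 0$ uniform. Defaults 0.9 (normal) / 0.3
  (cancer). Published descriptions of which tissue class has the more
  ordered axis field are contradictory, so the generator takes no side:
  both values are free parameters, and no test depends on their ordering —
  only the $\delta$ direction is treated as fixed;
* depolarization is kept small ($\Delta \le 0.05$), consistent with
  4 µm transmissive sections; diattenuation 0.01–0.05; each spot gets an
  overall transmittance 0.75–0.9 (tissue absorbs), which is what makes
  spots detectable on the $m_{11}$ image;
* detector noise is additive Gaussian read noise, optionally Poisson shot
  noise; an "SNR in dB" convenience computes
  $\sigma = \mathrm{rms}(I)\cdot10^{-\mathrm{SNR}/20}$ from the noiseless
  stack.

The phantom deliberately omits optical blur, registration error,
fixed-pattern noise, wavelength dependence and instrument polarization
calibration error. Passing the end-to-end tests therefore demonstrates
the correctness of the algebra and the qualitative class-contrast
mechanics, not robustness to every real-instrument systematic.

A single property transitively validates the forward model, the
reconstruction and the decomposition together: on a noiseless rendered
phantom, the recovered $\delta$ and $\theta$ maps equal the generated
ground truth to $10^{-6}$ over the whole foreground.

```{r end-to-end}
spec <- phantom_spec(c(120, 220), rbind(c(60, 60), c(60, 160)),
                     spot_radius = 40, c("normal", "cancer"), seed = 8)
truth <- generate_ground_truth(spec)
maps <- decompose_image(normalize_m11(mm_reconstruct(
  render_stack(truth, noise = NULL))))
fg <- truth$spot_id > 0
max(abs(maps$delta[fg] - truth$delta[fg]))
```

## Problem sizes used in the checks

The validation suite runs the scalar round trip on 1000 random physical
matrices, parameter recovery on 500 constructions, GLCM properties on 100
random images, and a 20-spot two-class phantom (radius 40 px,
$402\times502$ px field, 30 dB SNR) for the end-to-end class separation.
These sizes give stable statistics while keeping a full run in tens of
seconds; the generator scales to full-resolution cores by changing
`spot_radius` and `image_shape` only.

## Known limitations

* The decomposition assumes the forward (diattenuator-first) factor
  order; reverse and symmetric variants, and differential decomposition,
  are out of scope.
* No instrument calibration model: real acquisitions need their own
  systematic-error correction upstream of this package.
* `detect_spots()` assumes absorbing cores on a bright transmissive
  background; faint spots (transmittance within 5% of background) need
  manual ROI masks.
* The pipeline reports class-wise feature separations; it deliberately
  contains no classifier and performs no hypothesis testing.
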