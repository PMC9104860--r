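---
title: "Simulated high-NA phase microscopy and learned phase retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated high-NA phase microscopy and learned phase retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(canqpi)
```

## The problem

Quantitative phase imaging measures the optical phase a sample imprints on
reflected light — information a camera cannot record directly. Whether a
neural network that regresses phase maps from intensity images can be
*trusted* is best studied on samples whose phase response is known in
closed form. `canqpi` builds that study end to end for two uniform layered
samples on a BK7 coverslip (refractive index $n_0 = 1.52$) under an oil
immersion objective of numerical aperture 1.49:

* a **plasmonic gold film** (30–60 nm). Gold is absorbing, and p-polarized
  light beyond the critical angle excites a surface plasmon: a single deep
  dark band in the back focal plane (BFP) with a rapid $\sim 2\pi$ phase
  transit across it;
* a **lossless dielectric waveguide** (a micron of PMMA-like material).
  Beyond the critical angle all light is reflected ($|r| = 1$), so the BFP
  intensity is featureless and the information lives entirely in the phase
  of the guided-mode resonances.

## Optical model

Reflection coefficients $r_s(\theta_0)$, $r_p(\theta_0)$ of the
glass / layer / backing stack come from the Fresnel equations combined with
the $2\times2$ characteristic-matrix (transfer-matrix) method, with the
phase referenced at the glass–layer interface. Conventions, fixed once and
used everywhere:

* time dependence $e^{-i\omega t}$, so absorbing media have
  $\mathrm{Im}(n) > 0$ and evanescent waves carry $\mathrm{Im}(k_z) > 0$.
  The textbook characteristic matrix is written for the opposite
  convention; our matrix is its complex conjugate form. The choice affects
  only the sign of phase maps;
* angles beyond a critical angle are handled through complex transmitted
  cosines — never clamped;
* $r_p$ is defined so that it vanishes at the Brewster angle and equals
  $(n_2 - n_1)/(n_2 + n_1)$ at normal incidence.

Gold dispersion is linearly interpolated from the embedded
Johnson & Christy (1972) tabulation (548.6–756 nm); BK7 (1.52),
PMMA (1.489), water (1.33) and air (1.0) are fixed real indices. The
$\pm 10\%$ gold-index perturbation used in dataset draws scales the full
complex index by a single real factor; whether the real and imaginary
parts should be perturbed independently is not determined by the study
design, so joint scaling is the default and `scale_k` offers the
independent alternative.

The BFP is a $512\times512$ $k$-space grid spanning
$\pm 2\pi \mathrm{NA}/\lambda$, i.e. $\Delta\sin\theta_0 = 2(\mathrm{NA}/n_0)/512
= 0.0038$ per pixel, with the DC sample at pixel $(257, 257)$. Pixels whose
center lies at or outside the NA circle are excluded; the strict inequality
makes every masked-in pixel mirror-symmetric about both axes, which in turn
makes quadrant cropping exactly invertible. For x-polarized illumination
the vectorial pupil fields are

$$E_x = r_p\cos^2\phi + r_s\sin^2\phi,\qquad
  E_y = (r_p - r_s)\sin\phi\cos\phi,$$

with $\phi = \tan^{-1}(k_y/k_x)$. Illumination is uniform over the pupil
and no aplanatic $\sqrt{\cos\theta}$ apodization is applied — the model is
a plane-wave expansion in which only the sample shapes the field. The BFP
camera image is $|E_x|^2 + |E_y|^2$; the phase label is
$\arg E_x$ wrapped to $[-\pi, \pi)$.

Defocused image-plane fields apply the reflection-mode transfer function
$e^{2 i k_z z}$ (the factor 2 is the double pass) followed by a centered,
unitary inverse FFT; total energy is conserved to $10^{-10}$ at any
defocus because $k_z$ is real inside the mask. Positive $z$ moves the
sample away from the objective. $z$ is exposed in micrometres and converted
to nanometres once, internally.

## Datasets

A record stacks one quadrant (the upper-right, containing the center
row/column; any quadrant is information-equivalent by symmetry but the
choice is frozen) of:

| variant | channels |
|---|---|
| CAN1 | BFP |
| CAN2 | BFP, IMP($z{=}0$) |
| CAN3 | IMP($z{=}6\,\mu m$) |
| CAN4 | IMP(6), IMP(9) |
| CAN5 | IMP(6), IMP(7.5), IMP(9) |

IMP channels are z-score normalized. The BFP channel is left on its
natural $[0, \sim 1]$ reflectance scale — it is already normalized
physically — with a switch to z-score it as well. The image channels use
intensity ($|IMP_x|^2 + |IMP_y|^2$), which is what a camera records; a
configuration switch substitutes amplitude for users who prefer the
square root. Parameters are drawn independently and uniformly (gold:
thickness 30–60 nm, index scale 0.9–1.1, backing 1.0–1.4, wavelength
600–700 nm; waveguide: 0.95–1.05 µm, index 1.20–1.50, same backing and
wavelength), 1000 records per study, split 90/10 into training and
validation. The six test cases (30/40/50 nm gold, 0.95/1/1.05 µm PMMA,
each over air and water at 633 nm) are continuous-measure-zero points of
the sampling distribution and are additionally asserted never to collide
with a draw. Datasets serialize to RDS with a JSON sidecar; records
round-trip bit-equal.

## The network

A ten-level context aggregation network: nine $3\times3$ convolutions with
dilations $1, 2, 4, 8, 16, 32, 64, 128, 1$ (padding = dilation, stride 1,
spatial size preserved), each followed by adaptive normalization and a
leaky ReLU (slope 0.2; 0.01 at the ninth level), then a $1\times1$
convolution to one channel and a mean-squared-error head. After the
dilation-128 level the receptive field is $1 + 2(1+2+\dots+128) = 511$
pixels — full coverage of a 256-pixel input. Wrapped phase is regressed
directly; the $2\pi$ discontinuities are part of the label.

Adaptive normalization is implemented as
$\mathrm{AN}(x) = a\,x + b\,(\gamma_c \widehat{x} + \beta_c)$ with
learnable scalars $a, b$ per level and per-channel scale/offset
$\gamma_c, \beta_c$; $\widehat{x}$ is instance-normalized (per-channel
mean/variance of the single image). With a minibatch of one, batch and
instance statistics coincide up to running averages, and instance
statistics make inference independent of training-set bookkeeping.
Initialization is fan-in-scaled Gaussian for weights, $a = b = \gamma = 1$,
$\beta = 0$, biases 0, drawn from the run seed; training is Adam at the
reference recipe (learning rate $10^{-4}$, minibatch 1, 100 epochs) by
default. The forward/backward passes are exact (finite-difference checked
to $10^{-5}$ relative) and run through im2col + BLAS matrix products.

### Desk-scale profile

The reference configuration ($256\times256$, $M = 64$–512, 1000 records,
100 epochs) is a multi-hour GPU training. All learning claims in the test
suite therefore run a first-class scaled-down profile: $64\times64$
records (128-pixel pupil), $M = 8$, 200 records, 30 epochs. For this
$\sim$6000-step schedule the Adam step is raised to $10^{-3}$ — the
reference $10^{-4}$ belongs to a 90 000-step schedule — and the
overfitting oracle (5 records, 500 epochs, $32\times32$) uses $3\times
10^{-3}$. What the desk profile demonstrates is direction, not headline
numbers: the trained network beats the predict-the-mean baseline and an
untrained twin by wide margins, and the channel switch-off ordering
(plasmonic phase lives in the BFP channel, not the focal-plane image)
reproduces. What it does not demonstrate: the reference-scale average
SSIM values ($\approx 0.91$ for the plasmonic study), which require the
full training budget.

## Evaluation

Recovered and theoretical wrapped-phase maps are compared with a windowed
SSIM (Gaussian window, 11 px, $\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$,
dynamic range $2\pi$, half-window border cropped before averaging). A
recovered phase is physically defined only up to a constant, so the SSIM
is maximized over a uniform grid of 360 offsets in $[0, 2\pi)$ followed by
a bounded 1-D polish within one grid step; maximizing is the reading of
"best accounts for the arbitrary offset" consistent with 1 meaning
identical structure. SSIM on wrapped maps can in principle go below 0;
values are reported as computed. Finer grids never decrease the reported
value.

### V(z) validation

The confocal response $V(z) = \sum_{\text{pupil}} w\, E_x\, e^{2ik_z z}$
turns a phase map into a measurable curve: for plasmonic samples at
negative defocus, $|V(z)|$ ripples with period
$\lambda / (2 n_0 (1 - \cos\theta_{sp}))$ — 0.755 µm for 50 nm gold at
633 nm. A constant phase error cancels in $|V|$, which is what makes the
comparison offset-insensitive. The default pupil weight is unity; however,
with a hard-edged unit weight the aperture-rim diffraction beats against
the plasmon at 0.40 µm and dominates the minima of $|V|$. Every physical
confocal system apodizes the rim (illumination profile, pinhole), so the
package provides `vz_pupil_weight()` — a raised-cosine roll-off from 70%
of the pupil radius — under which the measured ripple period (detrended
running mean, median spacing of residual minima) is 0.75 µm, within one
z-step (0.05 µm) of the closed form. The ripple-period checks use this
weight.

## Numerical choices and degenerate inputs

* NA must be strictly below $n_0$ (otherwise $k_z$ would be complex inside
  the pupil) — enforced, not worked around.
* Zero-variance images cannot be z-scored and raise an error rather than
  returning NaN.
* Zero layers and zero-thickness layers reduce the transfer matrix exactly
  to the bare-interface Fresnel coefficient ($10^{-12}$), the main
  self-consistency anchor of the optics.
* The $k_z$ branch always takes $\mathrm{Im}(k_z) \ge 0$; reflectance
  magnitudes are invariant under conjugating the whole convention.
* SSIM offsets are compared on a uniform grid including $\delta$ and
  $2\pi - \delta$, which makes the metric symmetric in its arguments.
* Problem sizes in the test suite: unit-test optics run on 64–128-pixel
  pupils; the full 512-pixel pupil is used where the physics needs it
  (ring structure of defocused images, V(z) ripples). These sizes are the
  package's choices for a self-contained, reproducible suite.

## Known limitations

* The simulator models uniform (laterally invariant) samples only; the
  synthetic data contain no shot noise, aberrations, or camera effects, so
  passing tests certify the method's internal consistency, not robustness
  to experimental noise.
* Single deposited layer per sample; no dispersion-model fits (the gold
  table is interpolated, not fitted).
* The desk-scale network is a faithful miniature, not a reproduction of
  the reference-scale SSIM tables.
* `V(z)` agreement against recovered phases is assessed through curve
  overlays and ripple positions, not bit-wise.
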