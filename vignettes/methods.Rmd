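---
title: "Photoacoustic ground truth for needle tracking in ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photoacoustic ground truth for needle tracking in ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A needle advanced in-plane under B-mode ultrasound guidance is often barely
visible: its specular echo weakens with insertion angle and depth, parts of
the shaft drop out, and reverberation produces ghost lines parallel to the
true shaft. Supervised segmentation networks can enhance the needle, but they
need per-pixel ground truth, and manual annotation of ultrasound frames is
slow and subjective. Photoacoustic (PA) imaging offers a way out: a metal
needle absorbs laser light far more strongly than tissue, so in a dual-modal
US/PA acquisition the PA frame shows the needle with very high contrast.
Thresholding and keeping the large connected component of the PA frame
yields a binary needle map that can supervise a network operating on the
co-registered US frame — no human annotation involved.

`usneedle` implements this whole chain as a testable desk-scale pipeline:
acquisition geometry and its derived quantities, US/PA image formation from
beamformed RF, automated PA ground-truth extraction, native implementations
of a nested-U segmentation network and three reference U-Net variants with
their training recipe, the four evaluation metrics with success-only
aggregation, and a synthetic US/PA simulator so that every stage runs and is
verified without any external data.

## Acquisition geometry

`acquisition_geometry()` holds the system parameters (128-element 8 MHz
linear array, 0.03 cm pitch, 2 cm depth, 10 Hz laser, 64 parallel receive
channels, ~100 mJ pulses at 25 % coupling over ~3 cm²) and derives:

* frame rate = PRF / ceil(channels / parallel receivers). 128 channels
  filled 64 at a time need two pulses, so a 10 Hz laser yields 5 frames/s.
  The ceiling generalises the two-pulse case.
* surface fluence = E·η / A ≈ 8.33 mJ/cm², reported only (no safety-limit
  logic).
* maximum recording = frame buffer / frame rate = 500 / 5 = 100 s.
* lateral field of view = (N−1)·pitch = 3.81 cm. This is a convention, not
  physics: N·pitch would give 3.84 cm, and we deliberately adopt the
  element-centre span that reproduces the system's printed value. The
  axial extent of the displayed image (1.89 cm for a 2 cm depth setting)
  is presumably cropped by the scanner; no operation derives it.

## Image formation

The scanner stores beamformed RF, so no reconstruction is performed here.
For B-mode display, each RF line is quadrature-demodulated: mixed with
in-phase/quadrature references at the carrier, low-pass filtered, and the
complex-baseband magnitude doubled to recover the modulation amplitude. The
filter is a zero-phase 4th-order Butterworth with default cutoff at half the
carrier; the source system's filter is unknown, so fidelity to that exact
system is not claimed, and the Butterworth design is cross-checked against
an independent reference implementation in the tests. PA envelopes use the
per-line analytic-signal (Hilbert) magnitude. Both envelope routes agree
within 2 % RMS on narrowband signals away from edges, which the test suite
enforces.

Log compression maps the envelope to `20*log10(env/max)` clipped at a
dynamic range (default 50 dB — the display default is not documented by the
system, this is a standard choice) and rescaled to [0, 1]. It is monotone
and scale-invariant; an all-zero envelope maps to an all-zero image rather
than erroring.

## PA ground-truth extraction

`preprocess_pa()` composes thresholding, binarization, connected-component
labeling and large-component selection. Defaults and the reasoning behind
them:

* Threshold: Otsu (no reference threshold value is documented); a fixed-fraction
  alternative (`f · max`) is available. Whether the original acquisition chain
  thresholded the linear envelope or the log-compressed image is unstated —
  both are accepted as input.
* Connectivity 8, because needles are thin, oblique structures whose
  diagonal pixels must connect.
* Selection policy `largest` keeps the single biggest component ("the
  large area" is ambiguous between largest-only and an area filter, so an
  `area_fraction` policy exists too). Ties break to the first label in
  raster (column-major) discovery order, which is deterministic.
* Frames with no foreground (no visible needle) are flagged, never raised,
  and the pipeline excludes flagged frames from training pairs.

The chain never creates pixels (its output is a subset of the thresholded
support) and is idempotent on its own binary output; both are enforced as
property tests.

## The synthetic world

No public data ships with the package, so `simulate_pair()` emulates what
the dual-modal acquisition produces. The generator is a *stated world*: its
defaults are fixed choices, not tuning knobs, and the tests are read as
"under this world, the pipeline recovers what it should".

US frame: Rayleigh-distributed speckle envelope (scale 0.12) plus an
anti-aliased needle band whose amplitude falls off as `cos(angle)^1.5` and
exponentially with depth (rate 0.5 per image height) — encoding the angular
dependence and depth attenuation that make clinical needles hard to see —
with Bernoulli per-segment dropout (p = 0.25, 12 px segments, dropped
segments keep 10 % echo) and up to two ghost lines at 35 % amplitude,
7/13 px below the shaft, mimicking reverberation. The sum is log-compressed
at 50 dB. Insertion angle is drawn from 10–45°, tip depth from 0.35–0.8 of
the image height, length from 0.35–0.75 of the width; gauge 18 G maps to a
3 px band, 23 G to 2 px. Geometry that cannot be placed within an 8 px
margin is resampled a bounded number of times, then rejected.

PA frame: the needle band at unit amplitude with a hard profile (metallic
absorption saturates the band) plus a small sub-threshold point-spread
shoulder, a Rayleigh noise floor (0.02), and three Gaussian absorber blobs
(amplitude 0.3–0.7, radius 4 px) kept at least `radius + 8 px` away from the
shaft — the chromophore artifacts that contaminate real PA frames sit in
surrounding tissue, not on the needle. The ground-truth mask is exactly the
hard band; it is independent of every US-side nuisance parameter by
construction, which mirrors why PA supervision is attractive in the first
place.

What the simulator does **not** model: coherent speckle correlation,
beam-width-dependent blurring, k-space/acoustic propagation, optical fluence
heterogeneity, or the intensity statistics of any real scanner. A green
test therefore establishes that the pipeline is self-consistent and can
recover a known world — not that any real-tissue benchmark numbers are
reproduced. A real-tissue evaluation would require the original ex vivo /
in vivo data and trained weights, which are out of scope by design.

All randomness flows from one integer seed per pair (dataset seeds are
derived from the master seed), so every artifact is bit-reproducible.

## Networks

No deep-learning framework exists in the target environment, so the
networks are implemented natively: a small reverse-mode autodiff engine on
dense arrays with compiled (RcppArmadillo) kernels for convolution,
transposed convolution, pooling, batch normalisation and channel pooling.
Gradients of every operator and of all four assembled architectures are
verified against finite differences.

The flagship variant (`"uiu"`) nests small U-blocks inside a U-shaped
backbone: each encoder scale is a residual U-block (RSU) whose internal
encoder/decoder pools and re-expands with a dilated bottom convolution; the
bottom two scales replace the internal U with a dilation ladder (rates
1/2/4) so resolution is preserved where feature maps are smallest; 2×2
max-pooling separates scales; decoder scales upsample with 2×2 stride-2
transposed convolutions; and the skip connections are replaced by an
interactive-cross attention fusion in which the decoder feature gates the
encoder channels (squeeze/excite-style) and a spatial map computed from
channel-pooled statistics of both streams re-weights the result. Each
decoder level plus the bottom scale emits a side output; a 1×1 convolution
fuses the side logits into the final map. Where the cited architecture
leaves freedom (exact attention arithmetic, channel schedules), the smallest
faithful variant is used and documented in the code. Reference variants
`"unet"` (double-conv blocks), `"attention_unet"` (additive attention
gates) and `"r2u"` (recurrent-residual blocks, two unrolled steps with
shared weights) share the identical input/output contract so the four are
drop-in comparable.

Training follows the reference recipe: AdamW, learning rate 0.001, batch
size 2, multi-BCE (sum of per-map binary cross-entropies over all side
outputs plus the fused output, equal weights) for the nested variant and
plain BCE otherwise, checkpoint at the lowest validation loss. The
reference recipe prescribes 20000 iterations on a data-centre GPU; the desk-scale default (4
scales, 8 base channels, ≤2000 iterations, 128×128 inputs) trains on one
CPU in minutes. The validation schedule is every `val_every` iterations
(the original cadence is unstated). Prediction thresholds the fused
probability map at 0.5 (no documented value).

Numerical choices: normalisation always uses current-batch statistics
(instance-style at single-image inference). This keeps a checkpoint fully
described by its parameter list — reloading reproduces the recorded
validation loss exactly, which is asserted in the tests — at the cost of a
small train/inference statistics shift that is irrelevant at these widths.
Weight init is He-normal from the caller's RNG; training is bit-deterministic
given the seed. Segmentation-head biases are initialised at the background
prior (logit ≈ −4) and the fusion convolution starts as the mean of its side
logits: needle masks are ~1–2 % foreground, and without this the first
~1500 iterations are spent learning the class prior alone.

## Metrics

Given ground-truth pixel set S_G and predicted set S_H:

* **Localization success**: the total-least-squares line fitted to S_H must
  pass within 1 px of at least one ground-truth pixel, and
  |S_G ∩ S_H| ≥ 0.3·|S_G|. The reference rule names both criteria but gives
  neither the overlap threshold nor the pass tolerance; 0.3 and 1 px are
  declared defaults, not inferred values. **NLSR** is the percentage of
  successful images.
* **MHD** = max of the two directed mean nearest-neighbour distances
  between point sets, in pixels. It is computed on full foreground sets by
  default ("edge maps" in the source description; for 2–3 px-thick bands
  the distinction is minor, and an `"edge"` option exists). The vectorised
  implementation is required to match a brute-force double loop to 1e-9 —
  exactness, not approximation.
* **Targeting error** = |d_true − d_seg| where each d is the perpendicular
  distance from the image centre ((H−1)/2, (W−1)/2), 0-based) to the
  infinite needle line. The printed definition is a signed difference but
  only non-negative summaries are reported, so the absolute value is
  adopted; TE is then symmetric under argument swap.
* **Needle length ratio** = predicted tip-to-base length / true tip-to-base
  length, from the fitted lines' extreme projections.

MHD, TE and the length ratio are computed **only over successful images**
(success-only aggregation), with mean ± sample (n−1) standard deviation;
NLSR is over all images. The line-fitting procedure behind reported
numbers is unstated; total least squares on mask pixels is this package's
declared choice.

## Tolerances and degenerate inputs

Envelope plateau recovery is asserted within 1 % (filter transients are
excluded by testing the interior 80 % of samples); cross-method envelope
agreement within 2 % RMS; MHD against brute force at 1e-9; Otsu against an
exhaustive candidate search exactly (on images quantised to bin centres so
both formulations coincide). Empty masks yield flags, not errors; empty
point sets are rejected; a single-pixel or empty mask has no line and counts
as a localization failure upstream.

## Desk-scale recovery experiment

The self-contained analogue of a real-tissue evaluation protocol: simulate
300 pairs at 128×128 (240/30/30 split, fixed seeds), train the desk-scale
nested-U network, and score the held-out 30 images. Under the stated world
this must reach NLSR ≥ 95 %, mean length ratio ≥ 0.85 and mean MHD ≤ 3 px.
The run lives in `tests/testthat/test-acceptance.R` and is recomputed from
scratch by `scripts/acceptance.R`; the README shows an actual run's output.

## Known limitations

* The simulator is phenomenological; none of its parameters are calibrated
  to any scanner's needle statistics (none are published).
* The desk-scale capacity (≈50k parameters) is far below the original
  networks; conclusions about *relative* variant performance at full scale
  do not transfer.
* JSON is the only config format (no YAML parser in the supported
  dependency set); images are PGM/CSV rather than PNG/TIFF for the same
  reason.
* The CPU implementation favours clarity and determinism over speed;
  there is no GPU path, data parallelism, or real-time inference target.
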