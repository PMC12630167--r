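---
title: "Methods: synthetic pollen monitoring, two-branch classification and season-aware metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic pollen monitoring, two-branch classification and season-aware metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

holopollen is a desk-scale re-creation of an operational automatic pollen
monitoring stack of the kind run on airflow cytometers that record, for every
detected particle, a pair of greyscale holograms and a 13-channel induced
fluorescence spectrum. The package covers the whole chain: a parametric
synthetic event generator, a deterministic morphological prefilter, a
two-branch convolutional classifier that degrades gracefully when the
fluorescence modality is missing, confidence-threshold abstention, and the
season-aware statistics used to judge such monitors against manual
(Hirst-type trap) reference counts. This vignette documents the models and
the choices behind them; everything quantitative it mentions is computed by
the test suite or by `scripts/acceptance.R`, never asserted from memory.

## The synthetic event model

Real instruments produce, per event, two 200 x 200 greyscale holograms and
13 fluorescence intensities. The generator reproduces that *statistical
structure*, not the optics:

* **Silhouette.** A particle of diameter $d$ (micrometres) is drawn as a
  bright disc of radius $d / (2 \cdot \text{pixel\_scale})$ on a dark noisy
  background (background $\mathcal N(0.08, 0.02)$ clipped to $[0,1]$, disc
  base intensity 0.75, soft 1-px edge).
* **Texture.** Inside the silhouette the intensity is multiplied by
  $1 + a\,T(\rho, \theta)$, where $T$ is a band-limited random field (six
  radial--angular cosine harmonics, normalised to unit standard deviation)
  and $a$ is the profile's `texture_amplitude`. Water droplets have $a = 0$:
  they are perfectly smooth, which is exactly the property that makes them
  confusable with smooth round grass pollen.
* **Boundary spikes.** `spike_count` protrusions modulate the disc edge
  (amplitude 12 % of the radius), giving ornamented taxa such as oak or
  beech a distinct outline.
* **Two planes.** The second hologram is the same particle re-rendered with
  an independent small jitter of centre, texture phase and background noise,
  emulating the instrument's two reconstruction planes.
* **Fluorescence.** Each profile has 13 channel means and spreads; a draw is
  $\max(0, \mathcal N(\mu_i, \sigma_i))$ per channel, and with probability
  `fluor_missing_prob` the whole vector is absent (no fluorescence module,
  or signal below the noise floor). Droplets are non-fluorescent
  ($\mu \approx 0$). The 13 channels are treated as anonymous: their
  excitation/emission structure is not modelled.

This appearance model is a *classifiable proxy*: it preserves the contrasts
an operational classifier exploits (droplet smoothness vs pollen texture,
morphological ambiguity inside the birch family, fluorescence separability)
without attempting holographic reconstruction physics. Passing tests on it
therefore demonstrate that the pipeline's machinery works end to end, not
that any particular accuracy would be reached on real holograms.

Default profiles cover the main allergenic taxa monitored in Switzerland
(Poaceae, *Betula*, *Alnus*, *Corylus*, *Fraxinus*, *Quercus*,
*Fagus sylvatica*) plus water droplets. Two constructions are deliberate:

* The three Betulaceae profiles share identical diameter and texture
  parameters and differ only in fluorescence means (peaks at channels 6, 9
  and 12, spread 0.12) — holography alone cannot separate them, so the
  fluorescence branch has measurable value.
* The droplet profile has diameters supported on 10--100 um, the size range
  in which droplets occur under saturated conditions. The
  `fog_confusion_profiles()` scenario narrows the droplet diameters to
  grass-like values and lowers the grass texture to 0.06, reproducing the
  documented operational failure mode (fog-borne droplets counted as grass)
  in a form a fluorescence-blind model demonstrably falls for.

**Arrival process.** A campaign is a set of piecewise-constant per-taxon
rates (events/hour); hourly counts are Poisson, timestamps uniform within
the hour. Fog episodes inject droplet-class events only inside their
intervals. The manual reference trap is emulated as
`manual = efficiency x truth` with negative-binomial counting noise on an
equivalent sampled volume (default 14.4 m^3/day, a typical Hirst pump
volume); `noise_dispersion = 0` is the exact deterministic limit. The
`efficiency` factor is what the scaling factor S recovers. Counts convert to
concentrations by dividing by sampled volume; the default instrument flow
(2.4 m^3/h) is a configurable placeholder — any error in it is absorbed
into S by construction.

All randomness flows from explicit per-call seeds; there is no hidden global
state, and identical seeds reproduce events bit for bit.

## The morphological prefilter

Non-biological particles are removed before classification by a
deterministic filter: Otsu thresholding of the first hologram, largest
connected component with holes filled (EBImage), then

* equivalent diameter $= \text{pixel\_scale} \cdot 2\sqrt{A/\pi}$ within
  [5, 150] um,
* solidity (component area over convex-hull area, with a half-pixel
  perimeter correction so a digitised disc scores ~1) at least 0.8,
* moment eccentricity at most 0.95.

Rejections carry a reason code (`empty`, `size`, `solidity`,
`eccentricity`). The specific bounds are this package's defaults, not a
reproduction of any operational filter.

## The two-branch classifier

The image branch is a compact VGG-style network built from scratch — no
pre-trained weights anywhere: per block, two 3 x 3 convolutions (ReLU)
followed by 2 x 2 max-pooling; default blocks of 16/32/64 feature maps at
200 px. The two holograms enter as two stacked input channels (a siamese
arrangement is the untested alternative). The fluorescence branch is a
single dense layer of few units (default 8) over the 13 channels plus a
presence flag — kept deliberately small to avoid over-complex fluorescence
features. The branches fuse by concatenation into a linear softmax head.

Two design rules make the model robust to the missing modality:

* **Encoding.** Absent fluorescence is a zero vector with presence flag 0 —
  by construction, an event without the modality and one with explicit
  zeros + flag 0 are the same input.
* **Fluorescence dropout.** During training, each event's fluorescence is
  discarded with probability 0.2 (the `fluor_mask_prob` default). The mask
  is re-drawn every epoch rather than fixed per dataset; whether the
  discard should be per-epoch or a fixed subset is genuinely open, and the
  per-epoch reading was chosen as the stronger augmentation.

Training minimises cross-entropy with minibatch Adam (default learning rate
1e-3, batch 32), single-threaded, fully deterministic given the seed. The
engine (im2col convolutions, backprop, Adam) is implemented in
RcppArmadillo; its gradients are verified against numerical differentiation
in the test suite. One caveat worth recording: at a ReLU kink (exactly-zero
pre-activation, which zero-initialised biases can produce systematically)
the analytic subgradient and a central difference legitimately disagree, so
the gradient check runs on a configuration with live activations.

**Confidence and abstention.** Confidence is the maximum softmax
probability; no calibration is applied. At threshold $c$ an event is
labelled iff its confidence is $\ge c$ and the argmax is unique; ties
abstain (conservative). This makes classified-event sets nested as $c$
rises, which is what drives the monotonicity of the metric curves.

**Export.** Models serialise to the ONNX interchange format
(Conv/Relu/MaxPool/Flatten/Gemm/Concat/Softmax graph, class list and full
configuration in the model metadata). The writer and reader implement the
protobuf wire format directly for this fixed graph family; weights are
stored as double-precision tensors so the export-load round trip reproduces
logits to well below the 1e-5 contract (in practice exactly).

## Evaluation metrics

All metrics are computed on daily series (the season rule is daily); hourly
aggregation exists for display and conservation checks. The resolution used
operationally for correlation statistics is not prescribed, so daily — the
resolution the season definition forces — was chosen for all three.

* **Kendall's tau-b** between paired manual and automatic daily values, with
  tie corrections: $(C - D)/\sqrt{(n_0 - t_x)(n_0 - t_y)}$. The tie-corrected
  variant matters because zero-concentration days dominate pollen series.
  Chosen over Pearson for outlier robustness. If either series is constant
  the metric is undefined and reported as an `NA` sentinel.
* **Scaling factor** $S = \sum \text{manual} / \sum \text{automatic}$ over
  the common period — a ratio of sums, robust to zero days, rather than a
  mean of daily ratios. Lower is better sampling. Undefined (sentinel, not
  infinity) when the automatic total is zero. The reading "manual over
  automatic" follows from "the lower the scaling factor, the better the
  sampling".
* **Off-season noise ratio** $R$: mean automatic concentration over
  out-of-season days divided by the in-season mean — a false-positive
  indicator. A day is out of season iff it belongs to *any* sliding window
  of 7 consecutive days in which at least 4 days are below 20 particles/m^3
  in the manual series (T = 20, W = 7, k = 4, all configurable). The
  window-membership semantics ("lies in any qualifying window") is tested
  against an exhaustive brute-force enumeration; the rejected alternative
  (labelling only window starts) provably disagrees with it. One
  consequence worth knowing: the rule erodes roughly k-1 days at each season
  edge, because a boundary high day always sits in windows reaching into
  the off period. For this reason the end-to-end recovery checks compare R
  against the truth-series ratio *under the same mask*, which is the
  quantity the metric actually estimates.

Sweeping the confidence threshold yields a `metric_curve` (tau, S, R and
retained counts per threshold); `cross_site_envelope()` gives pointwise
mean/min/max across sites, excluding undefined sentinels but reporting how
many sites contributed at each point (sentinels are never silently
dropped). `autoplot()` methods reproduce the standard three-panel layout
with min/max shading.

## Problem sizes and numerical choices

The defaults mirror the instrument (200 px, 13 channels); tests and the
acceptance script run the same code at reduced scale, chosen as the smallest
sizes at which each property is meaningfully exercised:

* oracle equivalence: 1000 random series / 1000 tied vectors;
* noiseless campaign: 40 days, in-season rate 18 events/h at 0.6 m^3/h
  (about 8000 events at 16 px — image content is irrelevant to a
  perfect-information classifier, so frames are small);
* classifier recovery: 4 classes, 600 train / 200 test at 64 px, 8 epochs,
  two blocks (8, 16 maps);
* fluorescence-value experiments: 32 px, one block, 5 paired seeds, with
  majority-of-seeds assertions since individual runs of small nets on small
  samples are noisy;
* manual-trap recovery: 5000 days.

Degenerate inputs have defined behaviour throughout: empty frames are a
prefilter sentinel, all-tied series and zero totals are `NA` metric
sentinels, empty event lists round-trip as valid empty datasets, and
thresholds/probabilities are validated at the boundary.

## Known limitations

* The hologram model is a proxy; no claim transfers to real holographic
  reconstructions, reconstruction artefacts, aggregates or debris.
* Fluorescence channels are anonymous Gaussians; real spectra are
  correlated across channels and vary with humidity and particle age.
* The manual-trap emulation reduces a Hirst trap to one efficiency factor
  plus counting noise; real traps have flow- and wind-dependent biases.
* Confidence is uncalibrated softmax; operational systems may calibrate.
* Whether operational events can carry a single hologram is unknown here;
  the data model requires exactly two.
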