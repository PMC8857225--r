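---
title: "Classifying myocardial ischemia from stress-perfusion polar maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying myocardial ischemia from stress-perfusion polar maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative cardiac PET perfusion studies summarise stress myocardial blood
flow (MBF, ml/g/min) as a *polar map*: a circular bullseye projection of the
left ventricle with the apex at the centre and the basal segments at the rim,
divided among the three coronary territories (LAD, LCx, RCA) plus the apex,
and colored with a rainbow scale over a fixed display range of 0–3.5
ml/g/min. In clinical reading, a region with stress MBF below 2.3 ml/g/min
indicates ischemia. `polarcnn` implements an image-only classifier of such
polar maps — a compact four-layer 2D convolutional network that sees nothing
but the exported RGB image — together with the full surrounding pipeline:
a synthetic polar-map generator, preprocessing, a repeated-training
stability protocol, a quantitative threshold comparator standing in for the
clinical read, and the evaluation stack (confusion metrics, two-point ROC
AUC, decision-curve net benefit, Cohen's kappa).

Clinical polar-map datasets of this kind are not publicly deposited, so the
package ships a synthetic generator whose defaults emulate the published
study conditions: 138 cases with an ischemic fraction of 56/138, 1024×1024
JPEG exports reduced to 256×256 inputs, and a 61/31/46
train/validation/test split.

## The classifier

The network is deliberately small (124,289 parameters):

* four blocks of [3×3 convolution, stride 2×2, ReLU, same padding] →
  [2×2 max pooling], with 12, 16, 32 and 64 filters — for a 256×256×3 input
  the spatial size halves twice per block:
  256 → 128 → 64 → 32 → 16 → 8 → 4 → 2 → 1, ending at 1×1×64;
* flatten (64), dense 512 (ReLU), dense 128 (ReLU), dense 1 (sigmoid);
* L2 kernel regularization (penalty 0.1) on the output layer only.

"Same" padding is the only choice consistent with this shape ledger: with
valid padding the cascade cannot reach 1×1 from 256×256.

Training minimises class-weighted binary cross-entropy (weight 1 for
non-ischemic, 3 for ischemic, compensating the class imbalance) by
stochastic gradient descent with learning rate 0.005, momentum 0.9 and
time-based decay 1e-8 (effective rate `lr / (1 + decay * t)` at update
`t`), batch size 20, for exactly 35 epochs with reshuffling before each
epoch. The monitored metric (AUC by default, accuracy via
`monitored_metric = "ACC"`) is recorded in the history but never drives
early stopping or checkpoint selection: the final model is the weights
after the last epoch. Predictions are hard labels: sigmoid output strictly
above 0.5 is ischemic; a tie predicts non-ischemic (a conservative,
measure-zero rule).

There is no deep-learning framework behind this: the forward and backward
passes (im2col convolution, pooling, dense layers) are implemented in
C++ via Rcpp/RcppArmadillo in single precision. All randomness — Glorot
uniform initialization and the per-epoch shuffle schedule — is drawn from
R's seeded RNG, so a `(data, config, seed)` triple reproduces training
bit-for-bit.

Weight initialization is Glorot uniform (the common framework default;
the repeated-run protocol averages over initializations anyway).

## The synthetic generator

`synth_config()` defaults define the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_cases` | 138 | cohort size |
| `ischemic_fraction` | 56/138 | prevalence of obstructive disease |
| `normal_mbf_range` | 2.4–3.4 ml/g/min | base stress MBF of healthy myocardium |
| `defect_mbf_range` | 0.8–2.2 ml/g/min | stress MBF inside a perfusion defect |
| `ischemia_threshold` | 2.3 ml/g/min | label rule: any segment strictly below |
| `display_scale` | 0–3.5 ml/g/min | rainbow color scale limits |
| `defect_extent_range` | 0.3–1.0 | defect arc as a fraction of one 120° territory |
| `borderline_fraction` | 0.05 | cases with extreme MBF within ±0.2 of the threshold |
| `noise_sd` | 0.15 ml/g/min | smooth within-myocardium variation |

Each case draws a per-case base MBF, adds a smooth low-frequency field
(low-order circular harmonics plus a radial trend, standardized and scaled
to `noise_sd` — perfusion varies smoothly over the myocardium, so i.i.d.
pixel noise would be wrong), and, for ischemic cases, lowers one contiguous
angular arc (all rings, apex excluded) to a defect level. Clipping enforces
the label rule by construction: normal segments never drop below the
threshold, defect segments never reach it, so the generated label always
equals `min(segmental MBF) < 2.3`. A small borderline fraction places the
case's extreme MBF within ±0.2 ml/g/min of the cut-off, emulating the
visually ambiguous cases that drive clinical false negatives. The normal
range caps at 3.4 rather than the display maximum so that healthy tissue
renders in the red-orange band with a little headroom, as clinical maps do.

Rendering maps each pixel of the unit disc through the segment grid to the
rainbow LUT — a piecewise-linear HSV sweep from hue 240° (blue, scale
minimum) to 0° (red, scale maximum) at full saturation and value, with
1024 quantization levels. The vendor software's exact palette is
unpublished; what matters for a self-contained benchmark is that the
renderer, the inverter ([invert_colormap()]) and the image-based
comparator share one documented formula. Segment boundaries are blended
with a ~5° sigmoid ramp so color steps look like clinical maps rather than
pie charts; boundary geometry (apex disc radius 0.25, three rings, twelve
30° sectors, territories as fixed 120° arcs) is one explicit convention
among several defensible ones — nothing downstream depends on the specific
choice, only on its being fixed.

What the generator does *not* emulate: kinetic-modelling artifacts,
attenuation or reconstruction effects, anatomical variation in territory
boundaries, and the case mix of a real referral population. Passing tests
on synthetic data therefore demonstrate that the pipeline's mechanics are
correct and that the network can learn the color-pattern→label mapping;
they do not certify clinical performance. On these synthetic conditions
the classifier scores well above the published clinical accuracy — real
maps are harder than the emulation.

## Splits and independence

`split_dataset()` draws the test set first (`floor(n/3)` cases), then
floors the *training* share of the remainder (`floor(n_rest * 2/3)`),
giving validation the rest — with 138 cases: 61/31/46. Label independence
between splits is checked pairwise with Pearson's chi-squared test on the
2×2 membership×label table, without continuity correction; pairs with
p ≤ 0.05 are flagged.

## The stability protocol

`run_protocol()` repeats the whole train→predict cycle `n_runs` times
(default 100), varying only the seed: run *i* uses `base_seed + i`, an
arithmetic schedule that makes the entire ensemble reproducible from one
integer. The hold-out test set is frozen across runs; by default the
train/validation membership is frozen too and only initialization and
shuffling vary (`resample_split = TRUE` re-draws the train/validation
partition per run, since published protocols are often ambiguous on this
point). `assign_categories()` then applies the majority rule: a subject is
assigned to the confusion category (TP/TN/FP/FN) it lands in strictly more
than half the runs — at exactly 50 of 100 it stays unassigned.

## Evaluation

All metrics derive from the 2×2 confusion counts with ischemic = positive:
sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
accuracy, F1. Because predictions are hard labels the ROC has a single
interior operating point, and the trapezoidal AUC reduces to
(SEN + SPE)/2 — the form used throughout. Zero-denominator metrics report
`NA` rather than 0, so degenerate runs cannot silently distort aggregates.
Multi-run aggregation reports median and IQR with type-7 (linear
interpolation) quartiles, the standard convention.

Decision-curve net benefit is `NB(pt) = TP/N − (FP/N)·pt/(1−pt)` over a
threshold-probability grid in [0, 1); negative values are retained and only
clipped for plotting. Cohen's kappa uses marginal-product expected
agreement; `category_agreement()` compares two raters' category
assignments by the per-subject membership indicator of each category
("is this subject a TP under rater A / rater B"), the natural binary
operand when only category assignments are available.

## The clinical-threshold comparator

`classify_by_threshold()` operationalises the quantitative part of the
clinical read: ischemic iff at least `min_defect_segments` angularly
contiguous segments fall strictly below 2.3 ml/g/min (default 1 segment —
the bare cut-off; contiguity matters only for stricter settings). A
segment exactly at the threshold is normal. The image-based variant
inverts pixel colors to MBF, aggregates to a per-segment *median* (robust
to JPEG edge artifacts and boundary blending), and applies the same rule.
On lossless renders the round-trip error is bounded by LUT quantization
(≤ 0.02 ml/g/min on a dense grid, typically ~0.001); at JPEG quality 95
the image-based label agrees with the truth-based label on ≥ 99% of cases
whose extreme MBF keeps a ≥ 0.1 ml/g/min margin from the threshold —
zero-margin cases are strict-inequality coin flips by construction, for
any reader.

## Numerical choices and problem sizes

* Single-precision arithmetic in the CNN core (the usual choice for
  convolutional nets); deterministic given the seed.
* Downscaling (1024 → 256) uses coverage-weighted area averaging — the
  antialiased limit of bilinear resampling at large reduction factors;
  plain stride-sampled bilinear would drop three quarters of the pixels.
  Upscaling uses half-pixel-centre bilinear.
* The colormap inverter is exact nearest-neighbour over the 1024-entry
  LUT, implemented as a hue-guided candidate plus a ±8-index window scan;
  ties resolve to the lower index so inversion of a monotone color
  sequence is monotone.
* The test suite and the acceptance script run scaled problem sizes chosen
  to exercise every code path at full fidelity: 35-epoch single runs on
  150-case datasets, a 10-run stability protocol on the 138-case study
  conditions, and a 100-run protocol at one epoch to validate ensemble
  plumbing. The full 100-run × 35-epoch protocol is a single
  `run_protocol(..., n_runs = 100)` call.

## Limitations

Synthetic maps are cleaner than clinical ones: defects are single
contiguous arcs, noise is smooth and stationary, and the palette is known
exactly. Results on them upper-bound, not estimate, clinical performance.
The comparator models only the quantitative threshold component of a
clinical read, not visual judgement or inter-reader variability. Rest
perfusion and myocardial flow reserve are out of scope, as is per-vessel
classification.
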