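---
title: "Methods: temporal segmentation, frame selection and landmarking of deck-camera crustacean video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal segmentation, frame selection and landmarking of deck-camera crustacean video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deckpipe)
```

## The processing model

`deckpipe` targets electronic monitoring of crab and lobster catches
from a deck-mounted camera driven by a very small onboard computer.
The hardware constraint shapes every design choice: no model that
cannot run in a few hundred megabytes of memory, no stage that touches
more frames than it must, and no image resampling anywhere that feeds a
measurement.

The device alternates between two states decided from GPS
(`operating_state()`): below 4 knots the boat is assumed to be hauling
and sorting, and the device only records; at or above 4 knots, or
inside a configured port radius, it processes the stored video. The
boundary case — exactly 4 knots — maps to processing. Speeds are
great-circle distances over elapsed time (1 knot = 1852 m/h), medianed
over a short window (default 3 fix pairs) because raw GPS fixes jitter.

Processing converts a video into one record per presented animal in
five stages: greyscale conversion, presence classification into a
confidence signal, contig extraction, per-view representative-frame
selection, and detection/cropping/keypoint regression on the selected
full-resolution frames. The cheap stages run on downscaled copies; the
measurement stages run on untouched originals.

## Contig extraction

The presence classifier emits one confidence in $[0,1]$ per frame.
Over continuous video this stream is volatile — an animal held steadily
in view still produces deep dips — so the signal is smoothed with a
rectangular (box) window and hard-thresholded, twice:

$$f(n) = \frac{1}{m}\sum_{i=n-\lfloor m/2\rfloor}^{n+\lceil m/2\rceil-1} S_i$$

with out-of-range indices taken as zero, followed by a step function
($x \ge \tau \mapsto 1$), with the chain
smooth(20) → step(0.01) → smooth(10) → step(0.5). Maximal runs of 1s
are the contigs. The first, permissive threshold keeps any sustained
activity; the second pass with the round-half-up threshold of 0.5
cleans the boundaries. Two box passes cheaply approximate triangular
smoothing while allowing different window sizes per pass.

Three numerical conventions deserve note, since the operator is the
package's core:

* **Window semantics.** A symmetric window written as
  $n - m/2 \ldots n + m/2$ spans $m+1$ samples while dividing by $m$,
  which would scale constant signals by $(m+1)/m$. We take exactly $m$
  samples, $n-\lfloor m/2\rfloor \ldots n+\lceil m/2\rceil-1$, so the
  operator is a true mean and constants are preserved; for even $m$
  the window sits half a sample early.
* **Threshold boundary.** A value exactly equal to the threshold maps
  to 1 (closed lower set), which makes step(0.5) equal to
  round-half-up.
* **Composition at the edges.** Each pass zero-pads independently, so
  two passes equal a single convolution with the box self-convolution
  (triangular) kernel only away from the signal boundary; the tests
  verify the identity on the interior and the zero-padding behaviour
  directly at the edges.

Contigs and event schedules are 0-based, half-open `[start, end)`
frame intervals throughout, so detection output composes directly with
ground truth. Contigs are deliberately slightly oversized (a window
effect): the cost of a few extra scored frames is far lower than the
cost of losing the best frame of an animal.

Evaluation (`evaluate_contigs()`) counts a *success* when a contig
overlaps exactly one ground-truth event and that event is overlapped by
no other contig; overlap means any shared frame, since no tolerance is
otherwise defined. The success rate divides by the number of true
events. Merged contigs (two animals presented back-to-back), missed
events, and spurious contigs are reported separately.

The chain parameters are exposed (`smoothing_chain_config()`) but not
learned: with four scalars, manual tuning against signal visualisations
is more time-efficient than building a tuner, and learning them is
explicitly out of scope.

## Preprocessing and augmentation

All frames are converted to greyscale on entry (BT.601 luminance
weights), cutting input size by exactly 3 with no measurable effect on
these models. The classifier/scorer path additionally downscales by
exact area averaging — the deployed reduction is 1280×720 → 320×180 —
and refuses any target that changes the aspect ratio. Measurement-path
images are never resized at all.

Training images (never test images) pass through a stochastic chain
applied sequentially in a fixed order: horizontal flip (p = 0.5),
vertical flip (p = 0.5), blur (p = 0.3), ±20% intensity shift
(p = 0.3); all four fire together with probability
0.5·0.5·0.3·0.3 = 2.25%. Two points were genuinely open and decided
here: the chain order follows the listing order above (the source
describes the chain only as "sequential"), and the ±20% intensity
shift is implemented *multiplicatively* (uniform factor in
[0.8, 1.2], then clipping) rather than additively, since a gain change
is the better model of varied lighting. The blur is a small Gaussian
(default 5×5, σ = width/4) as only "blur" is specified. All four
draws flow through one code path (`draw_augmentation_ops()`), which is
also what Monte Carlo estimates of chain probabilities sample.

## Frame selection

Each view (top, underside) has its own scorer with an identical
architecture: stacked 3×3 convolution + 2×2 max-pool blocks (widths
8/16/32), one dense layer, one sigmoid unit emitting a
"representativeness" score in $[0,1]$. Training is plain scalar
regression of quality labels under squared error. Pairwise
relative-quality training — standard in the frame-selection literature
— is deliberately rejected: it needs deeper networks than the target
hardware can hold. At inference the scorer sees only in-contig frames,
and the per-contig, per-view argmax is shortlisted; ties break to the
earliest frame (the source is silent; earliest is deterministic and
favours the animal's first steady presentation). Selection is
invariant under any strictly increasing transform of the scores.

Scorers are evaluated by *pairwise preference accuracy*: present two
frames of strictly different true quality and count whether the better
one scores higher. Ties count as failures — a tie gives the selector
no usable preference — which makes a constant scorer score 0, an
oracle 1, and an independent random scorer 0.5 in expectation.

## Detection, cropping and keypoints

The object detector is an injected component, not a re-implementation:
production systems use an unmodified off-the-shelf detector, so the
package's value is the contract (`f(image, frame_index) → detection or
NULL`) plus two reference backends — a ground-truth-backed mock with
optional corner jitter, and a heuristic blob detector that thresholds
the bright foreground and classifies by second-moment elongation.
A missed detection is logged and the contig is kept as a record with
class `"undetected"`, preserving count integrity for stock statistics.

Crops are cut at one dataset-wide fixed size — the mean detected box
width/height, rounded to the nearest even integer (ties up; even sizes
keep pooling arithmetic clean) — centred on the box and *translated*,
never scaled or padded, to stay inside the frame. Every crop pixel is
a bit-identical copy of a source pixel, and the frame↔crop coordinate
transform is an exact, invertible integer translation. Padding was
rejected because it would fabricate pixels on the measurement path.

The keypoint regressor has six alternating convolutional and max-pool
layers (read as 3 conv + 3 pool; widths 16/32/64), one dense layer and
a 14-unit linear head — x,y for each of the 7 named landmarks, in
absolute crop pixels (no normalisation, since the error metric is
pixel-space). It trains with Adam under RMSE loss. Errors are
summarised as Mean Euclidean Error — the mean over samples *and*
keypoints of the point distance (per-point averaging, the more common
convention) — and relative error, MEE over the mean ground-truth box
diagonal, as a percentage. The species→measurement-keypoint map is
inferred from the landmark names, which the source never enumerates:
crabs use `crab_left`/`crab_right` (carapace width); lobsters use the
eye, carapace and tail landmarks. All 7 points are always predicted.

Because no deep-learning framework is available in the target
environment, both reference networks run on a minimal self-contained
CNN engine (im2col convolution, per-sample Adam, analytic gradients
verified against finite differences in the test suite). It is sized
for these two models, not generality.

## The synthetic world

`generate_video()` emulates a sorting session: per the ground-truth
schedule, one animal per event moves into frame, dwells near the
centre, flips from top to underside view midway, and leaves. The
animal is an elongated two-tone blob — ellipse body, triangular tail,
bright head disc — whose pose fully determines the 7 landmarks; views
are texture-coded (top solid, underside banded) so view-specific
scorers have a learnable cue; species differ by aspect ratio. Each
frame's quality label is centrality × scale-fitness × (1 − blur) ×
visible fraction, mirroring the criteria a human labeller applies
(subject central, well-sized, sharp, fully in frame). The generator
emits the matching noisy classifier signal: in-event frames at a high
confidence with dropout, out-of-event frames at a low level with
occasional spikes, optional Gaussian jitter, all clipped to $[0,1]$.
One integer seed drives everything, so fixtures are bit-reproducible.

Defaults state the modelled world: presentations of 50–150 frames
(2–6 s at 25 fps) separated by at least 60 frames; in-event confidence
1.0 with 30% dropout; 5% spurious spikes at amplitude 0.1. The
desk-scale acceptance world uses exactly those enumerated noise
sources and nothing else (`jitter_sd = 0`); the package default adds
mild jitter (sd 0.02) as a calibration knob, and it is worth knowing
that clipped zero-mean jitter raises the empty-deck baseline to
≈ 0.008 — adjacent to the first threshold of 0.01 — which is exactly
the kind of classifier pathology the first smoothing pass exists to
absorb, and at sustained levels it can merge events.

What a green test does **not** establish: the blobs have no water,
gear, hands, shadows or parallax; the presence signal's noise is
parametric, not a real classifier's failure modes; species differ only
in silhouette. Synthetic results validate the *machinery* (signal
algebra, selection logic, geometry, training dynamics), not at-sea
accuracy. Published headline numbers from the original study (detector
mAP, 28.09 px MEE, 76/78% selector accuracy) depend on unreleased
footage and weights and are replaced here by property-based checks at
desk scale: the scorer trained on 950 synthetic labelled frames must
beat the random pairwise baseline (≥ 0.65 vs ≈ 0.5), and the keypoint
model must at least halve its initial held-out MEE on 200 synthetic
crops.

## Desk-scale configuration

The deployed training recipes (scorer: 200 epochs at learning rate
1e-5 on 320×180 input; keypoints: 4000 epochs at 1e-3) are impractical
for a test suite on one CPU, so the tested configuration scales the
*size* down while keeping the procedures identical: scorer input
48×27 (16:9 preserved; three pool levels still fit), 10 epochs at
1e-3; keypoint crops 48×48, 20 epochs at 1e-3. Training runs
per-sample Adam with a seeded shuffle, so results are reproducible to
the bit. Image I/O uses ASCII NetPBM (PGM/PPM) rather than PNG: the
environment provides no R image codec, and a dependency-free
plain-text format keeps the package self-contained.

## Known limitations

* A contig merging two back-to-back presentations yields one record,
  and nothing guarantees the two selected views show the same animal —
  a limitation inherited from the design, not solved here.
* Underside frames are selected but not keypointed by default; they
  are reserved for future sex classification.
* The blob detector's species call (elongation threshold) is a
  heuristic for synthetic silhouettes only.
* Timing numbers in `profile_run()` are reported but never asserted:
  they are hardware-dependent.
* Physical measurements from keypoints (photogrammetry) and sex
  classification are out of scope.
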