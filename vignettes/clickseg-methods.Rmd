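---
title: "Interactive segmentation with semantic priors: models, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactive segmentation with semantic priors: models, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickseg)
```

## The procedure

Interactive object segmentation predicts a binary mask of one object
from an image plus user annotations: positive clicks inside the object
and negative clicks outside it. `clickseg` models the complete loop —
how clicks are encoded, how a semantic prior is attached, how a
simulated user places and corrects clicks, how a backend is trained on
its own mistakes, and how performance is scored as clicks-to-IoU — and
ships a synthetic scene generator so the loop is testable end to end
on one CPU.

### Click guidance

A click set \(P = \{(i, j)\}\) of one polarity becomes a real-valued
guidance map. Two encodings are implemented:

* distance: \(u_{x,y} = \min_{(i,j) \in P} \sqrt{(i-x)^2 + (j-y)^2}\),
  clipped at `clip` (default 255) and scaled to \([0,1]\) before the
  backend;
* Gaussian: \(u_{x,y} = \max_{(i,j) \in P} \exp(-d^2 / 2\sigma^2)\)
  with \(\sigma\) in pixels (default 10).

Both are kept because the field uses both; the Gaussian is the session
default because it makes the blank map semantically consistent — no
clicks means no peaks, whereas an all-zero *distance* map would read
as "clicks everywhere". The distance formula takes the square root:
the quantity encoded is the minimum *Euclidean* distance. An empty
click set of either polarity always yields the blank (all-zero) map
with an explicit empty flag.

### Semantic priors and channel selection

A semantic prior is a \((C+1)\)-channel map (background plus \(C\)
tissue classes) of per-class values in \([0,1]\). The backend receives
exactly one channel: for each tissue class the channel values at the
positive-click pixels are summed, and the class with the maximal sum
wins; ties break toward the lowest class index and the background
channel is never selectable, since positive clicks by definition mark
a tissue object. Summation is the simplest order-invariant aggregate
over clicks (the convention could equally be mean — identical for a
fixed click count — or max; sum was chosen and is frozen). With a
single click the selection is invariant to any strictly monotone
transform applied to all channels, so it does not matter whether a
prior is stored as probabilities or logits; the package's own storage
convention is values in \([0,1]\).

When no prior exists the backend receives a blank channel, defined to
behave exactly like a prior of all zeros; this is asserted, not
assumed.

### The simulated user

*Initial sampling.* A budget of `cap` clicks (default 20) is split
into \(n \ge 1\) positives and \(m = \mathrm{cap} - n\) negatives with
\(n\) uniform on \(1..\mathrm{cap}\) — the split is random by design
and no distribution is prescribed elsewhere, so uniform is the
package's choice. The first positive click is a maximum of the
object's interior distance transform (the parameter-free reading of
"the centre of the object"); later positives are uniform over object
pixels at least `d_step` (default 10 px) from all earlier positives.
Negatives go first onto other objects within `d_near` (default 10 px)
of the target — "close to or touching" — and the rest into a ring
between 5 and 30 px of distance from the object. All three radii are
package choices; no reference values exist. When one polarity runs out
of feasible pixels its shortfall is reallocated to the other, so the
budget is spent exactly whenever the scene allows it.

*Corrective sampling.* Mispredicted pixels are split into false
negatives and false positives and each is partitioned into 4-connected
components. \(R\) components are drawn without replacement with
probability proportional to component size (rather than always the
largest), with \(R\) capped by `R_max`, the number of components and
the remaining budget. One click is placed per selected component
(\(K = R\); only \(K \ge R\) is prescribed) at the component's most
interior unclicked pixel, ties broken at random — robust for thin,
ragged regions where a uniform draw often lands on a boundary pixel.
Polarity follows the error kind: missed object pixels get positive
clicks, spurious predictions get negative ones. This mapping is the
only sensible one but is a package decision; it is not prescribed.
The total click count never exceeds the cap.

*Sessions.* Evaluation sessions start from a single positive click at
the object centre, then alternate prediction and correction with one
click per round (`R_max = 1`), stopping at IoU ≥ `iou_target` (default
0.85) or at the cap; the first click count reaching the target is the
session's score, with failures scored as the cap. 4-connectivity is
used for every component operation in the package — one convention
everywhere.

### Backends and training

Backends honour one contract: inputs are the RGB image, the two scaled
guidance maps and the selected (possibly blank) prior channel, all of
one spatial shape; output is a per-pixel probability, thresholded at
0.5 (no threshold is prescribed; 0.5 is the package default). The
ground-truth oracle and the constant-empty backend pin down the two
ends of the protocol (1 click and the cap, respectively). The
component baseline thresholds the prior channel at 0.5, keeps the
4-connected components holding positive clicks, discards components
holding only negative clicks, and falls back to colour-based seeded
region growing (tolerance 0.12 in RGB after a 1-px Gaussian smooth)
for clicks the prior route does not explain; growth from negative
clicks is subtracted. The conservative growing tolerance is
deliberate: under-coverage is correctable by further clicks, leakage
is not.

The trainable reference backend is a small fully convolutional model
whose learned layers are 1×1 — a per-pixel MLP (one tanh hidden layer,
12 units) over nine channels: RGB smoothed at σ = 1 and σ = 4 px, the
two guidance maps and the prior channel. The architecture is
deliberately not the point; it sits behind a registry
(`register_backend()`) so larger models can implement the same
contract.

Training is iterative: per sample an object is drawn, initial clicks
are simulated, and for `correction_iterations` (default 3) rounds the
current model's prediction is corrected and the encodings refreshed;
with probability `prior_reset_prob` (default 0.3) the sample's prior
is replaced by a blank mask so the model stays usable without semantic
information. The loss is the bootstrapped binary cross-entropy: the
mean over the hardest `bootstrap_fraction` (default 0.25) of pixels,
probabilities clamped at 1e-7. Gradients are accumulated over
`batch_size` (default 5) samples and applied with Adam at a learning
rate decaying by 0.9 every 5 epochs from `initial_lr`, floored at
5e-7. The config defaults (50 epochs, batch 5, lr 1e-4) mirror the
full-scale recipe for GPU-sized models; the pixel-MLP itself is
trained at `initial_lr = 0.03` — a model with nine inputs needs
order-one weights, which a 1e-4 schedule cannot reach in a short run —
and for 10 epochs on 200 scenes of 96×96 px, which converges in about
90 s on one CPU. During training the initial budget per sample is
drawn from 2–6 clicks rather than the full 20: spending the entire
interactive cap up front would leave the corrective rounds, which are
the point of iterative training, no budget at all.

### Evaluation

IoU is \(|P \cap G| / |P \cup G|\), computed at full frame even when
prediction ran in a window (windowing is an acceleration, not a metric
change). Two conventions are fixed where the definition is silent:
IoU of two empty masks is 1, of exactly one empty mask 0. The headline
statistic is the mean over objects of the first click count reaching
IoU ≥ 85 %, failures capped at 20. Mean-IoU-versus-clicks curves carry
a session's last IoU forward once it stops adding clicks — sessions
that hit the target at \(k\) clicks contribute that IoU to all larger
click counts; whether published curves do the same is not stated
anywhere, so carry-forward is this package's fixed rule. Prior-mode
comparisons run both arms with identical derived seeds (common random
numbers) so the difference in means isolates the prior's effect.

### Phenotype statistics

From a semantic mask: \(\mathrm{Area}_c = \sum_{x,y} 1_c(I_{x,y})\)
and \(\mathrm{RArea}_c = \mathrm{Area}_c / \sum_c \mathrm{Area}_c\)
with the sum over tissue classes only — background is excluded from
numerator and denominator, and the fraction of all image pixels is
emitted alongside as a second statistic. "Isolated clusters" are
4-connected components of one class. An optional grouping column
yields replicate means, the form consumed by downstream association
studies (which are out of scope here).

## The synthetic scene generator

Scenes emulate in vitro tissue-culture imagery structurally, not
photorealistically: 3 objects from 3 classes (assigned round-robin, so
default scenes have one object per class) on a 96×96 canvas, each a
single 4-connected region of ≥ 64 px. Shapes are star-convex outlines
with low-order Fourier modulation ("blob"), optional higher-frequency
lobes (callus-like) or anisotropic stretch (stem-like) — curved
boundaries that simple geometric primitives cannot express, which is
the regime interactive segmentation exists for. Each class renders
with a distinct base colour plus additive Gaussian noise (sd 0.08), so
a trainable backend can learn class appearance.

Priors are corrupted ground truth, emulating an offline model's
errors with three orthogonal knobs: `softness` (softmax temperature;
argmax-preserving), `jitter` (per-pixel displacement up to a radius,
moving class boundaries), and `confusion` (per-pixel label flips).
The "moderate" setting used in evaluations and training is softness
0.5, jitter 2 px, confusion 2 % — chosen once as a plausible error
profile for a fine-tuned semantic model: largely right, uncertain at
boundaries, occasionally wrong outright.

What passing tests on these scenes shows — and does not. The scenes
have clean class colours, no illumination gradients, no occlusion, no
touching same-class objects under the defaults, and no texture. Tests
passing here establish that the protocol, samplers, losses and
metrics behave as specified and that priors reduce clicks *in this
regime*; they do not establish segmentation quality on real imagery,
which depends on backbone capacity and training data far beyond desk
scale.

## Numerical and representation choices

* One RNG stream per operation, seeded explicitly; derived child seeds
  stay inside 32-bit range. Fixed seed + fixed inputs give
  byte-identical scenes, sessions and reports.
* Click coordinates are 1-based `(row, col)` in memory (the R matrix
  convention) and 0-based in exported JSON/CSV, converted at the
  boundary.
* Corrective clicks avoid already-clicked pixels; a region whose every
  pixel is already clicked is skipped. This guarantees sessions make
  progress and terminate.
* Adjacent duplicate clicks collapse; order is otherwise preserved.
* Label masks are written as colour PNGs with a deterministic palette
  snapped to the 8-bit grid (this R stack cannot write indexed or
  16-bit PNGs); instance ids up to 65535 are split across two 8-bit
  channels. Priors are written as multi-channel 32-bit TIFF samples of
  values in \([0,1]\) (resolution \(2^{-32}\)) with channel names in a
  JSON sidecar.
* The bootstrapped-CE gradient treats the top-\(k\) selection as
  fixed per step (the standard subgradient).
* Degenerate inputs are defined, not left to chance: empty click sets
  encode to blank maps; all-background masks give zero areas and zero
  relative areas; both-empty IoU is 1.

## Problem sizes

The test suite and the acceptance script use: 96×96 scenes; 50-scene
(150-object) sets for the paired prior-mode comparison and the
clean-prior single-click property; 200 training scenes, 10 epochs and
20 held-out scenes for the trainable backend; and 50–100 random
instances per brute-force oracle comparison. These sizes were chosen
so that every property is exercised with comfortable margins while a
full run stays in the minutes range on a single CPU core.

## Known limitations

* The pixel-MLP backend has no genuine spatial receptive field beyond
  its two smoothing scales; it cannot separate touching same-class
  objects, mirroring (in miniature) the known limitation that a
  class-level prior carries no instance information.
* The colour-growing baseline assumes class-correlated colour; on
  textured or illumination-varying imagery its blank-prior arm would
  degrade first.
* Boundary jitter in the prior corruptor is independent per pixel;
  real model errors are spatially correlated, so the corruptor is
  conservative about large coherent mistakes (the confusion knob adds
  only speckle).
* Strokes are represented as their rasterised pixel sets (each stroke
  pixel an example), so pen geometry is out of scope.
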