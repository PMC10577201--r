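---
title: "Open-world plant disease detection: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-world plant disease detection: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owdet)
```

## The problem

Conventional plant-disease detectors are trained once, on a closed set of
annotated disease classes, and silently misclassify anything they have never
seen. In the open-world setting the detector must instead (i) localize
objects of classes absent from its training data and label them `unknown`,
(ii) hand those unknowns to an annotator, and (iii) absorb the newly labeled
classes in a further training task without forgetting the classes it already
knows. `owdet` implements this full cycle -- class schedule, unknown
pseudo-labeling, energy-based unknown identification, balanced replay, and
the open-world evaluation metrics -- at desk scale, on seeded synthetic
imagery, so every stage of the paradigm can be exercised and tested on one
CPU in minutes.

## Task protocol

A `TaskProtocol` is an ordered list of tasks with pairwise-disjoint class
sets. After task $t$ the known set is the union of tasks $1..t$; everything
else in the registry is unknown at $t$. The default schedule is 4 tasks of
5 classes (cumulative known 5/10/15/20, residual unknown 15/10/5/0), the
first three tagged as one species and the last as a second species to stand
for a cross-species increment. The task order is a constructor argument, so
order-sensitivity experiments are configuration, not code.

Splits are drawn at the image level: one shared validation set and one
shared test set (20% each by default) are fixed once and reused across all
tasks, and the remaining training pool is partitioned by *collection task*
-- each image belongs to the training view of the latest task among its
annotated classes. Annotations of classes not yet known at a task never
appear in its training view; in validation and test, all annotations remain,
because unknown ground truth is exactly what Unknown Recall, A-OSE and the
energy fit need.

## Synthetic scenes

The generator stands in for a non-public greenhouse dataset. It renders
elliptical "lesions" on a leaf-green background: each class has a hue on a
10-step wheel and a texture frequency; the second half of a 20-class
registry reuses the hues of the first half at a different frequency, which
deliberately creates the disease-with-similar-symptoms confusability that
makes open-set errors realistic. The second species gets a different
background tone and leaf silhouette. Each image is "collected" for one task:
all its lesions come from that task's classes. Boxes tightly bound the
rendered ellipses, generation is deterministic under a seed, and a
configurable per-class minimum instance count is guaranteed.

What the generator does *not* emulate: photorealistic texture, occlusion,
scale extremes, annotation ambiguity, label noise, and the
within-class appearance drift of real disease progression. Passing tests on
these scenes therefore validates the *protocol machinery and learning
dynamics*, not field performance on real imagery.

A companion `DetectionNoiseModel` simulates a detector directly from ground
truth -- per-instance miss rate, open-set leak rate (an unknown object
emitted under a known label), confusion matrix, box jitter, Poisson false
positives. Every evaluation metric has a closed-form expectation under this
model ($E[\mathrm{U\!-\!R}] = (1-m)(1-\ell)$,
$E[\mathrm{A\text{-}OSE}] = n_U (1-m)\ell$), which is how the metric stack
is calibrated by Monte-Carlo in the test suite.

## Unknown pseudo-labeling and the class-agnostic codec

During training, proposals with high objectness that overlap no ground-truth
object (max IoU below `bgIouMax`) are relabeled as pseudo-ground-truth of
the `unknown` class; the top `k` such proposals per image are taken, with
`k = 1` by default (one unknown instance per image). "Does not overlap" is
not quantified in the source setting; we use 0.3, the conventional
negative-assignment bound of two-stage detectors, and expose it. Objectness
ties break toward the lower proposal index for determinism. Pseudo-labels
are training targets only and are never written into persistent ground
truth.

Box regression uses a single class-agnostic delta per proposal,
$(\Delta x, \Delta y, \Delta w, \Delta h) = ((g_x - p_x)/p_w,\,
(g_y - p_y)/p_h,\, \log g_w/p_w,\, \log g_h/p_h)$. The codec's signature
admits no class id -- the class-agnosticism is structural -- and
`decodeBoxDelta(p, encodeBoxDelta(p, g))` recovers `g` to floating
precision.

## Energy-based unknown identification

Each detection carries its known-class logits, scored by
$E = -T\,\log \sum_c e^{l_c/T}$ (temperature $T = 1$ by default; lower
energy means a more confident in-distribution prediction). On the validation
split -- the only place unknown annotations exist -- energies of
known-labeled detections matched (IoU $\ge$ 0.5) to known versus unknown
ground truth are collected and fitted by maximum likelihood, by default with
a three-parameter (location-shifted) Weibull, alternatively a Gaussian. The
shifted-Weibull likelihood is maximized over
$(\log k, \log \lambda, \log(\min x - \mathrm{loc}))$ so the support
constraint holds throughout the optimization; fits with fewer than 20
samples per side, or zero-variance samples, are refused and the pipeline
proceeds without relabeling.

Relabeling flips a known-labeled detection to `unknown` iff the
prior-weighted unknown likelihood exceeds the known likelihood at its
energy. We default to equal priors (the source setting does not state a
ratio) and keep the known label on ties. Relabeling never alters geometry or
scores and never moves a label in the unknown-to-known direction.

## Balanced replay

After each incremental task, a balanced exemplar set is drawn uniformly
without replacement: at least $N_{samples} = 25$ instances per known class
whenever that many exist, with a reported shortfall otherwise. The exemplar
unit is the instance with its host image retained; fine-tuning runs on the
union of exemplar images and the current task's view, with every known
annotation on those images kept as a target so that co-hosted instances are
never presented as background. Store growth is at most linear in the number
of known classes, which is the argument against retraining on the full
accumulated archive.

## Evaluation

Matching is greedy per class at IoU 0.5: detections in descending score
order (ties by input index) each claim the highest-IoU unmatched same-class
ground-truth instance. AP is the 11-point interpolated form
$\mathrm{AP} = \frac{1}{11}\sum_{r \in \{0, 0.1, \dots, 1\}} \max_{\tilde r
\ge r} p(\tilde r)$, and reports carry P/C/K -- mean AP over previous-task,
current-task and all known classes, on the 0--100 scale. Unknown Recall is
$TP_U / A_U$ over `unknown`-labeled detections versus unknown ground truth;
A-OSE counts unknown ground-truth objects claimed by a known-labeled
detection that is a false positive for its claimed class, each object at
most once. Both are reported as not-applicable when no unknown ground truth
exists (the final task of a complete schedule). Known classes with no
ground truth in the evaluated split are excluded from the means with a
warning, never silently.

One interpretation was genuinely open: whether unknown ground-truth regions
should be "ignore" regions for known-class AP. We count known-labeled
detections on unknown objects as false positives for their claimed class
(and tally them in A-OSE); `unknown`-labeled detections are never false
positives against known classes. This keeps the unknown-handling penalty in
one place without double-counting.

## The toy detector

The CPU-scale detector is a deliberate miniature of the two-stage
architecture the paradigm normally runs on. A fixed 13-dimensional window
descriptor (channel means and SDs, gradient texture, center--surround
contrast, half-window asymmetries, window size) replaces the deep backbone;
it is untrained by design, which keeps each task's training a sequence of
linear-model updates. On top of it sit a linear objectness scorer over a
dense multi-scale window grid (sides 12/15/19/24, strides 3/3/4/5 on a
64-px image -- chosen so some window reaches IoU 0.5 with every renderable
lesion), a linear projection to a 10-dimensional embedding, a multinomial
head over known classes + `unknown` + background, and a single
class-agnostic 4-output box regressor that head extension never touches.

Two couplings give the embedding open-world structure. The contrastive
clustering term $d(f, p_c) + \sum_{j \ne c}\max(0, \Delta - d(f, p_j))$
(margin $\Delta = 1$, weight 0.05) pulls features toward their class
prototype -- a running mean -- and pushes them past the margin from the
others. And each known-class logit carries a prototype-distance penalty
$l_c = w_c \cdot z + b_c - \gamma\, d(z, p_c)$ ($\gamma = 1$): a region far
from every prototype depresses all known logits at once, which is what
makes the energy score genuinely rise on out-of-distribution regions
instead of extrapolating to over-confidence, as purely linear logits do.

Training per task runs seeded mini-batch SGD (batch 4) in two phases: a
warm-up on annotated classes, then -- once the objectness scorer is
informative -- pseudo-labeling of the top background proposal per image as
`unknown` and continued training with the unknown slot active. The schedule
defaults, 300 task iterations and 100 fine-tune iterations at batch 4, are
a desk-scale stand-in for the full-scale 18,000/4,000/4; the test suite and
the acceptance script run their end-to-end experiments at 800/300 on
80-image benchmarks of 3 tasks x 2 classes, sizes at which a full
replay-versus-naive comparison completes in about a minute. At inference,
detection confidence is the class posterior weighted by proposal
objectness, the score floor is 0.05, and per-class NMS runs at IoU 0.5 on
the refined boxes.

## Numerical choices and degenerate inputs

Boxes must have strictly positive extent; degenerate proposals are errors,
not warnings. All tie-breaks (objectness, matching scores, NMS) resolve by
input index so every stage is deterministic. AP with zero ground truth is a
not-applicable marker, never a division. The energy score uses the max-shift
log-sum-exp. Every source of randomness flows from one root seed through a
per-stage splitter kept inside the 32-bit integer range, and the run
manifest records the derived seeds plus digests of the generated data.

## Known limitations

The descriptor's color/texture bias matches the generator; on real imagery
both the separability margin and the energy separation would shrink, and
unknown recall here (as in the full-scale setting) stays well below known
mAP. Energies of newly learned classes overlap the unknown mode early in a
task, so relabeling immediately after an increment can be noisy. The
simulator draws detections independently per instance and cannot mimic
correlated failures. None of the metric code attempts the 101-point COCO
integral -- the 11-point interpolated AP is the protocol's definition.
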