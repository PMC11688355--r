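---
title: "Motion-based sequence selection for infant GMA: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based sequence selection for infant GMA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmaselect)
```

## The problem

General Movement Assessment (GMA) is a qualitative clinical evaluation of an
infant's spontaneous movements, used to assess neurological maturation in
preterm and writhing-age infants. Assessors do not score whole recordings;
they review a handful of short sequences in which the infant moves freely.
Picking those sequences from recordings that may run for hours is tedious
— experienced raters need tens of minutes per video — and it is exactly the
kind of screening a motion measure can automate.

`gmaselect` implements that screening step on top of any 2D pose estimator.
It consumes per-frame tables of 17 body keypoints (COCO-17 order) with
confidences, and emits time intervals, not video clips: cutting the clips is
downstream tooling, which keeps the package free of codec dependencies.

## The motion quantity

Let $P_i = (p_{i,1}, \dots, p_{i,17})$ be the pose sampled at time step $i$,
each $p_{i,k} \in \mathbb{R}^2$ in pixel coordinates. The motion quantity is

$$S_i = \sum_{k=1}^{17} \lVert p_{i+1,k} - p_{i,k} \rVert_2 ,$$

the summed Euclidean displacement of all keypoints between consecutive
sampled poses. A series of $F$ poses gives $F-1$ values; value $i$ is
attached to the timestamp of its leading frame. Units are pixels; no
normalisation by image size or infant scale is applied, because selection
only ever compares windows *within* one video, where the scale is constant.

Properties worth knowing (all property-tested):

* translating every keypoint by a constant leaves $S$ unchanged — camera
  framing does not matter;
* scaling coordinates by $s$ scales $S$ by $s$ — zoom changes magnitudes but
  not the argmax of any window;
* reversing time reverses $S$.

$S_i$ contains no confidence term. Because real estimators emit
low-confidence garbage for occluded landmarks, `confidence_policy()` offers
two opt-in gates: `drop_keypoint` (a keypoint counts only when its
confidence clears a threshold in both frames) and `normalize` (additionally
rescales by $17/\text{retained}$ so values stay comparable; a pair retaining
nothing scores 0 by convention). The default, `include_all`, is the literal
definition and is what every reported result here uses.

## The selector

For a window of $W$ samples, the summing-window objective is
$G(j) = \sum_{i=j}^{j+W-1} S_i$, and the selected sequence starts at the
smallest $j$ maximising $G(j)$. With the default 60 s window at the default
1 Hz sampling rate, $W = 60$: an interval spanning 60 seconds contains
exactly 60 inter-frame displacements, so the window is half-open in sample
space. All ties — here and everywhere downstream — resolve to the smallest
start index, which makes every result deterministic.

Several sequences are usually wanted (five per video is the conventional
operating point). `select_top_k()` generalises the argmax greedily: take the
best window, discard every window overlapping it in sample-index space,
repeat. Greedy disjoint selection is the default because reviewers want
distinct episodes of movement; a `free` mode (the $k$ largest scores,
overlaps allowed) exists for sensitivity analysis. If fewer than $k$
disjoint windows fit, the result is truncated with a warning, and the
evaluation denominator follows the sequences actually returned.

Window durations that are not a whole number of samples are rounded to the
nearest sample. Any such rounding changes the selected duration, so the
package warns whenever `window_s * rate` is not an integer rather than
applying a larger, never-reachable "half-sample" trigger.

`window_scores()` runs in $O(n)$ via a cumulative sum; the test suite pins
it, and the greedy rule, to an $O(nW)$ brute-force enumeration with the same
tie rule on a thousand randomised series.

## Scoring agreement with experts

Let $x$ be a software-selected interval and $y_{j,e}$ rater $e$'s $j$-th
interval, all half-open in seconds. The machinery is:

* **intersection** $I(x, y) = \max(0, \min(x_{end}, y_{end}) -
  \max(x_{start}, y_{start}))$;
* **matching**: for each rater, $c = \arg\max_j I(x, y_{j,e})$, minimum
  index on ties. Matching is per software sequence, with replacement — no
  bipartite assignment is imposed;
* **dice similarity** $DS(x, y) = 2 I(x, y) / (|x| + |y|)$, which handles
  unequal durations;
* **maximum dice similarity** $MDS(x) = \max_e DS(x, y_{c,e})$: did *some*
  rater pick essentially this sequence?
* **precision** $\text{Precision}(\tau) = \frac{1}{N} \sum_{l,i}
  \delta\!\left(MDS(x_{l,i}) > \tau\right)$ over all $N$ selected sequences
  in all videos.

The inequality is strict, so a perfect selector scores 0 at $\tau = 1$; this
is a documented property of the definition, not a defect, and the curves
should be read on $\tau \in [0, 1)$.

Two families of curves put the software number in context:
`leave_one_out_precision()` recomputes the curve with each rater excluded
from the MDS maximum in turn, and `inter_rater_precision()` lets each
rater's intervals play the role of the selections against the remaining
raters (denominator: that rater's own sequences). `average_curves()`
summarises either family by its pointwise mean and population standard
deviation, which is how the software band is compared against the
human-agreement band.

## The synthetic generator

No clinical recordings ship with the package, so validation rests on
simulation with known ground truth. `generate_pose_series()` places the 17
keypoints on a fixed supine-infant template centred in a 1280 × 720 frame
(the common capture resolution for such recordings) and adds, per frame and
keypoint, Gaussian position jitter with sd `baseline_jitter_px`. Inside a
planted burst each keypoint is additionally displaced in a uniform random
direction by a magnitude drawn from $|\mathcal{N}(a, a/4)|$, where $a$ is the
burst amplitude in pixels. Coordinates are clamped to the frame.

The template is static apart from noise — no kinematic chain, no anatomy.
That is deliberate: the motion quantity is pose-agnostic, so anatomical
realism buys no additional test power. Raters are modelled as *jittered
oracles*: each selects the largest-amplitude bursts and perturbs every start
by $\mathcal{N}(0, \sigma_{exp})$. This is the minimal rater model that
exercises the full matching/dice/precision machinery nontrivially; it does
**not** model genuinely independent human judgement, disagreement about
what counts as a good sequence, or artefacts like crying, fussing and
caregiver hands in frame. Passing the simulated study therefore shows the
algorithmic chain is correct and robust to coordinate noise and annotation
jitter — it does not certify clinical performance on real video.

One root seed drives everything, split into per-rater sub-seeds
(`seed * 1000 + 7919 e` modulo $2^{31}-1$) so that adding a rater never
perturbs existing streams; runs are bit-reproducible.

A boundary effect is worth knowing: a burst planted at time $t$ already
moves the frame pair $(t-1, t)$, so the motion series is elevated over
$W+1$ samples and the selector may start one sample before the planted
onset, tying with the exact window. Against a jitter-free oracle annotation
this costs at most one sample of overlap (dice $59/60$ for a 60 s window).

## The reference study

`validation_study_configs()` fixes the package's standard end-to-end
scenario, chosen once to mirror the operating point at which automatic and
expert selections are typically compared:

| parameter | value | why |
|---|---|---|
| videos | 6 × 600 s at 1 Hz | six ten-minute recordings, the scale of a small clinical comparison set |
| bursts per video | 5 × 60 s, starts 30/150/270/390/510 s | well separated (≥ 60 s) so five disjoint windows exist |
| burst amplitudes | 25, 22, 19, 17, 15 px | distinct, so the raters' amplitude ranking is well defined; ≥ 10× jitter |
| baseline jitter | 1 px | typical keypoint localisation noise at this resolution |
| raters | 4, jitter σ = 5 s, 5 sequences each | a four-assessor panel marking starts to within a few seconds |

Under this study (seeded), the mean leave-one-out software-experts
precision and the mean inter-rater precision at $\tau = 0.5$ both exceed
0.9, the planted-burst recovery rate (every onset within ±2 samples, 100
runs, 3 bursts each) is ≥ 99 %, and `scripts/acceptance.R` recomputes these
quantities from scratch at any seed. Problem sizes throughout the test
suite (series of 100–1000 samples, 1000 random selector instances, 100
round-trip files) were chosen as the smallest sizes at which the properties
are meaningfully exercised.

## Numerical and design choices

* **Half-open everything.** Intervals are $[start, end)$ and windows sum
  exactly $W$ samples; touching intervals intersect in 0 s.
* **Ties.** Minimum index, in selection and in matching, making all outputs
  deterministic functions of their inputs.
* **Degenerate inputs.** Parsers reject rather than repair: frames out of
  time order, keypoint counts other than 17, non-finite coordinates,
  confidences outside $[0,1]$, non-uniform sampling beyond $10^{-6}$ s and
  intervals with $end \le start$ all raise classed errors
  (`gmaselect_parse_error`, `gmaselect_schema_error`, ...), never partial
  objects. Missing detections are confidence 0, never `NaN`.
* **Resampling** is integer decimation only (ratio within $10^{-9}$ of an
  integer), keeping every timestamp exact; interpolating upsampling is out
  of scope.
* **`inter_rater_precision()`** takes no per-video sequence count: the
  denominator is determined by the rater's own annotations, so a separate
  parameter would only invite inconsistency.
* **Round trips.** CSV writes coordinates at 6 decimal places (sub-micron
  at pixel scale); JSON writes full doubles.

## Known limitations

* The motion quantity cannot distinguish infant movement from caregiver
  intervention, crying or fussing — high-motion segments of any origin are
  selected alike. Screening the selected timestamps remains a human step.
* Pixel units mean scores are not comparable across videos with different
  zoom; only within-video ranking is meaningful.
* The simulated rater model is an oracle with timing noise; real
  inter-rater disagreement is richer, so simulated inter-rater curves are
  optimistic relative to human panels.
* At $\tau = 1$ the precision is 0 by the strict inequality in its
  definition.
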