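---
title: "Effort-aware active learning for stack segmentation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effort-aware active learning for stack segmentation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Manually delineating every structure on every section of a histological
stack is the dominant cost of building segmentation ground truth. This
package implements a suggestive-annotation loop that spends the
annotator's tracing time where it buys the most segmentation accuracy: at
each iteration it proposes one (section, structure) pair, receives the
traced mask, and retrains. Three ingredients make the loop effective, and
this vignette documents how each is modelled, which parameters matter,
and where we made design choices the problem left open.

## The probabilistic model of partial annotation

A stack is a sequence of $N$ 2D sections with pixel domains $\Omega_n$ and
a label set $\{0,\dots,C-1\}$ (0 = background). At any time the pixels of
section $n$ split into a labelled set $L_n$ (inside traced masks) and an
unlabelled set $U_n$. Two sources constrain the unlabelled pixels:

* **Weak bounds.** For every structure $c$ the annotator supplies the
  first and last section where it appears ($n_{c1}, n_{c2}$ — two clicks,
  no tracing, optionally widened by a safety margin). Outside that
  interval the class is impossible.
* **Annotated exclusion.** Once $c$ has been traced in section $n$, no
  unlabelled pixel of that section can be $c$.

Together these define the *compatible set* $\mathcal{C}_n$: the classes an
unlabelled pixel may still take (`compatible_classes()`).

Training uses a **mixed cross-entropy**: labelled pixels contribute the
usual $-\log f_{l(x)}(x)$, and each unlabelled pixel contributes
$-\log \sum_{c \in \mathcal{C}_n} f_c(x)$, i.e. the model is only asked
to put its mass *somewhere* in the compatible set. On a fully labelled
section this is exactly the classical cross-entropy (a property the
test-suite asserts to 1e-10). At inference the raw network output is
combined with the constraints by Bayes' rule (`constrained_posterior()`):
labelled pixels become one-hot, unlabelled pixels are renormalised over
$\mathcal{C}_n$, and the hard segmentation is the per-pixel argmax with
ties resolved toward the lower class id.

Degenerate cases are pinned down explicitly: log arguments are floored at
$10^{-12}$; if the renormalising mass of a pixel is below $10^{-12}$ the
posterior falls back to uniform over $\mathcal{C}_n$; an unlabelled pixel
with an empty compatible set is an inconsistent state and raises an
error. When only one compatible class remains in a section, the remaining
pixels are *implied* to carry it — we flag the section
(`state$implied`) but do not promote the implication to a hard
annotation, since it was never traced and should not enter the effort
statistics.

## Effort: boundary length in crack edges

Tracing time grows with the length and convolutedness of a structure's
outline, not its area, and shrinks when neighbouring structures have
already been traced (a shared boundary is traced once). We therefore
measure effort as boundary length and account for sharing.

Boundary length is counted in **crack edges**: the cut edges of the
4-adjacency pixel grid, plus the grid edges of mask pixels on the image
border. The alternative reading, counting boundary *pixels*, was
rejected because it breaks an identity the effort subtraction silently
relies on: with crack edges, on a fully labelled section
$\ell(M_c) = \sum_{c'\neq c}\ell(M_c, M_{c'}) + \text{border edges}(M_c)$
holds *exactly* (asserted against a brute-force pair enumerator on random
label maps), so crediting shared boundaries can never overshoot. The
choice is isolated in two functions (`crack_length()`,
`shared_crack_length()`) should a different metric ever be needed.

A $C\times C$ matrix $B$ holds running averages: $B_{cc}$ the mean
boundary length of $c$ over its annotated instances, $B_{cc'}$ the mean
shared length over sections where $c$ and $c'$ were co-annotated, both
with a weak prior constant $\varepsilon$ (default 0.01) in the
denominator. The prior's only practical role is to keep a pair's
estimate at exactly zero until the pair has actually been observed
together; a positive prior would lure the query strategy into exploring
the (numerous) untested pairs. $B$ is recomputed from scratch each
iteration — at stack scale this costs microseconds and removes a class
of incremental-update bugs.

The predicted remaining effort of querying $(n, c)$ is
$R_{nc} = \max(0,\; B_{cc} - \sum_{c'} A_{nc'} B_{cc'})$, zero when the
class is not compatible. Because $B$ holds averages the raw difference
can be negative; it is clamped, and a non-positive $R_{nc}$ is treated
as a *free* annotation that any effort-normalised strategy queries first
(an $+\infty$ score sentinel rather than a division by zero).

The *actual* cost charged when the simulated annotator answers a query
is computed from the ground-truth masks with the same geometry: full
crack length minus every stretch already traced by previously annotated
classes of that section. Summed over any complete annotation order this
equals the number of distinct cut edges of the stack
(`total_annotation_cost()`), which makes the effort axis of all curves
order-invariant and lets cost fractions be compared across strategies.
Effort fractions include background tracing in the denominator (every
edge once); the background is a first-class, queryable label with bounds
spanning the stack.

## Predicting accuracy: the smoothed Dice

Entropy-based querying optimises a surrogate; this framework tracks the
metric of interest directly. After each retraining, the per-class Dice
$D_c$ is measured against the *available annotations* and smoothed as
$\tilde D_c(T) = \alpha D_c(T-1) + (1-\alpha) D_c(T-2)$, with
$\alpha = 0.5$ throughout (the loop's single hyper-parameter); at the
first iteration both terms are the post-bootstrap value. The history is
recorded for every class at every iteration, not only the queried one.

Measuring $D_c$ against annotations has a subtlety: under the full
constrained posterior the annotated pixels are one-hot by construction,
so the hard segmentation would reproduce the annotations exactly and
$D_c \equiv 1$. We therefore score the classifier with the annotation
constraints removed: the raw posterior renormalised over the classes the
*weak bounds alone* allow (`constrained_posterior(...,
constraints = "bounds_only")`), compared per annotated section and
averaged. Evaluation-mode Dice (the reported curves) is different and
uses everything the user would use: the full constrained posterior
against complete ground truth, with intersections pooled across the
stack and the mean taken over foreground classes (configurable).

The proposed criterion queries
$\arg\max_{n,c}\,(1-\tilde D_c)/R_{nc}$ — room for improvement per unit
of predicted effort. Ties break deterministically: larger
$1-\tilde D_c$, then lower class id, then lower section id. Ablations
(`Dalpha`, `BDalpha_CE`, `HBDalpha`, `HDalpha`, `HB`) and baselines
(`H`, `H_dropout`, `rand`, `uniform`) share the same loop and differ
only in the score (or, for `BDalpha_CE`, in the training loss, which
drops the unlabelled term). Entropy scores use the *constrained*
posterior and the natural logarithm — the problem statement is silent on
both; the constrained choice follows from the entropy being defined over
the same posterior the user would read, and the log base only rescales
all scores. `H_dropout` averages 20 Monte Carlo forward passes with
dropout 0.5 at test time. The slice-wise `uniform` baseline finishes its
current section in random class order, then opens the section minimising
the longest run of consecutive untouched sections, re-planning after
every section (ties random).

## The backbone

The framework is contract-first about its classifier: anything providing
softmax-normalised full-resolution class probabilities, a seeded
stochastic (dropout) variant that degenerates to the deterministic one
at rate 0, and an SGD-trainable fit honours the loop. The default
backbone is a compact per-pixel multilayer perceptron over multiscale
features — raw intensity, Gaussian-smoothed intensity at two scales
(1.5 and 3 px), and normalised $(x, y)$ coordinates — with one hidden
ReLU layer (width 16) and a $C$-way softmax, about $10^2$–$10^3$
parameters. For intensity-rendered stacks of the size used here this
model is near-Bayes-optimal when fully trained, trains in seconds on one
CPU, and leaves the active-learning dynamics (which are the object of
study) untouched; a convolutional encoder–decoder is a drop-in
replacement wherever textures rather than intensities carry the classes.
Dropout is applied at test time only (for the Monte Carlo entropy
baseline); the tiny model is regularised by weight decay alone.

Training minimises the mixed loss averaged per pixel (sums would couple
the learning rate to the crop size) plus an L2 penalty of $10^{-4}$,
with minibatch SGD over sections: batch size 8, momentum 0.9, initial
training 200 epochs at learning rate 0.2, fine-tuning 10 epochs per
iteration at a tenth of that (the 10:1 ratio mirrors standard practice
for fine-tuning schedules). Divergence (non-finite loss) aborts with
diagnostics rather than continuing silently. All shuffling is seeded;
two runs with equal seeds produce bit-identical loss trajectories.

Augmentation (`sample_augmentation()`) implements the usual geometric
and photometric perturbations: rotation, translation, shear and
log-uniform scaling within $\pm 10°$/$\pm 10$ px/$[0.8, 1.2]$,
brightness $\pm 20$ (on the 0–255 scale) and contrast $[0.8, 1.25]$,
plus a nonlinear field built from Gaussian control-point shifts
($\sigma = 4$ px on a 5-px grid, bilinearly upsampled) and a random
crop (128 px default). Intensities are interpolated bilinearly, labels
nearest-neighbour with `NA` (unlabelled) preserved. At the desk-scale
problem sizes used in the tests the per-pixel backbone gains nothing
from geometric augmentation, so training runs with `augment = FALSE` by
default; the machinery is exercised by its own tests and available via
`train_config(augment = TRUE)`.

## The synthetic study system

Real stacks of serial coronal sections are emulated procedurally so that
every component is testable without external data. A base label map
grows $C-1$ blobs from centroids on a ring (radius-scaled
nearest-centroid labelling, varied blob radii), guaranteeing adjacent
structures with genuinely shared boundaries. Each class is given a
contiguous section-support interval (background spans the stack);
restriction to the eligible classes happens *before* deformation, so
the configured supports are the true presence intervals and the weak
bounds are exact by construction. Every section is then deformed with
an independent similarity transform — rotation, translation and
log-scale drawn from zero-mean Gaussians with sd 10°, 10 px and 0.1 —
composed with the same control-grid nonlinear field as the augmentation
(σ = 4 px, 5-px spacing). Intensities are rendered as class mean +
smooth bias field + i.i.d. Gaussian noise, clipped to [0, 1].

The default conditions are 12 sections of 64 × 64 with 6 classes, means
evenly spaced in [0.12, 0.92], noise sd 0.02 and bias amplitude 0.015.
The noise level is set by a solvability requirement rather than taste:
the background outnumbers the smallest blob by a factor of ~20, so at
noise levels where a plug-in Bayes classifier still misassigns a few
percent of background pixels, the false positives alone would drown the
small classes' Dice. The chosen values keep the plug-in Bayes
classifier above 0.9 Dice for every class (asserted in the tests),
which is the premise under which Dice-versus-effort dynamics — not raw
classifier capacity — drive the benchmark. A rare deformation draw can
push a class entirely out of frame; that section's transform is
redrawn from a deterministic sub-seed sequence so supports stay exact
and generation stays reproducible.

The simulated annotator answers queries with exact ground-truth masks.
Bootstrapping annotates, for every class, the central section of its
presence interval shifted uniformly within ±3 sections; the draw is
clipped to the interval (supports can be shorter than 7 sections) and
moved to the nearest section where the class is non-empty. Queries
inside a safety margin may legitimately return an empty mask, which
costs nothing but still marks the pair resolved.

What the generator does *not* emulate: histological texture, staining
variability, tissue folds and tears, registration artefacts, or
section-to-section intensity drift. Passing benchmarks here show the
query strategies do what they claim under a controllable, solvable
system; they do not certify performance on real histology, where the
classifier, not the query logic, is usually the binding constraint.

## The loop, its determinism, and problem sizes

`run_active_learning()` wires everything together: bootstrap → initial
training → {update $B$ → predict → record Dice → score pool → query →
charge actual cost → fine-tune} until a target Dice, an effort budget, an
iteration cap, or pool exhaustion. The bootstrap cost is charged on the
effort axis (its first curve point), since tracing one instance of every
class is real work. Every stochastic component draws from a sub-seed
derived from the master seed and the iteration index, so runs are
bit-reproducible and — because a snapshot carries the full loop state —
resumable mid-run with identical results (asserted in the tests). At
exhaustion the constrained posterior is one-hot everywhere, so the mean
Dice is exactly 1 and the charged cost exactly equals the stack's total:
two conservation checks tying the loop to the geometry module.

Reported problem sizes were chosen to exercise the full loop while
keeping a complete multi-seed comparison comfortably runnable on a
single CPU: the benchmark runs BDalpha, rand and H on the default
synthetic stack over five seeds to a 50% effort budget, summarising the
median effort to reach mean Dice 0.80 and the mean Dice at matched
mid-range budgets (25%, 35%, 45% — midway between the ~13% bootstrap
cost and saturation). Evaluation runs every iteration (cheap at this
scale; configurable thinning for larger stacks).

## Known limitations

* The effort model predicts with *global* per-pair averages; it has no
  notion of how the specific section's geometry deviates from the class
  average, and shared-boundary credit only begins once a pair has been
  co-annotated somewhere.
* The Dice predictor lags one iteration behind and treats classes
  independently; annotating one class also changes its neighbours'
  constraints, which the prediction ignores.
* Query-mode Dice is measured against annotations on annotated sections
  only — early in a run this is one section per class.
* The default backbone cannot separate classes with equal intensity
  statistics; such stacks need a convolutional backbone behind the same
  contract.
* Queries are single pairs; batch-mode querying and
  diversity/representativeness terms are out of scope.
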