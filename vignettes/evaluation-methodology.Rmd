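---
title: "Grouped cross-validation and multi-expert agreement for patch classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouped cross-validation and multi-expert agreement for patch classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Patch-based classification of digitized histopathology turns one patient
into hundreds of correlated observations: a tissue core is tiled into small
patches, and every patch from the same core shares staining, sectioning and
biological idiosyncrasies of that patient. If patches are shuffled freely
into cross-validation (CV) folds, patches from the same patient sit on both
sides of the train/test split and the measured accuracy answers the wrong
question — "can I recognise a patient I have already seen?" rather than
"can I grade a new patient?". A second, independent bias enters through the
ground truth itself: Gleason grading has high interobserver variability, so
training and evaluating against a single pathologist bakes that
pathologist's systematic tendencies into both sides of the measurement.

`patchcv` implements the evaluation protocol that exposes both biases —
grouped k-fold CV at patient, core, or patch level with leakage auditing,
majority-vote consensus labels, per-fold accuracy/sensitivity/specificity,
quadratic-weighted Cohen kappa, and paired McNemar comparison — together
with a hierarchical synthetic cohort and annotator simulator, so the whole
pipeline is demonstrable and testable without any real tissue data.

# The generative model

`simulate_cohort()` draws a cohort of patients, each contributing one or
two tissue cores (a 50/50 mix by default, so core-level and patient-level
grouping genuinely differ), each core holding a fixed number of patches.
Each patch has a true class in {benign, G3, G4, G5} drawn i.i.d. from the
configured prevalence, and a feature vector

$$x = \mu(\text{class}) + u_{\text{patient}} + v_{\text{core}} + \varepsilon,
\qquad u \sim N(0, \sigma_p^2 I),\;
v \sim N(0, \sigma_c^2 I),\;
\varepsilon \sim N(0, \sigma_e^2 I).$$

Class means are scaled unit basis vectors, $\mu(c) = \delta\, e_{c \bmod d}$,
so distinct classes sit $\delta\sqrt{2}$ apart; only relative separations
matter for any demonstration here, so one knob suffices. The patient and
core effects are additive mean shifts shared by all patches of the unit —
the minimal mechanism that makes a same-patient patch closer in feature
space than any other patient's patch, which is exactly what ungrouped CV
exploits. Patch grids are abstract: no spatial adjacency or within-core
label correlation is simulated, since none of the statistics computed here
use spatial structure.

Randomness is organised as one root seed plus a stable string-hash child
seed per patient, core, and annotator-core stream, so identical
configurations reproduce byte-identical cohorts and a cohort can be
extended without reshuffling existing units.

An optional image mode renders each patch as a toy 64×64 H&E-like raster
(gland lumens decreasing and nuclear density increasing with grade,
patient/core effects acting as channel-intensity shifts) and derives a
7-dimensional handcrafted feature vector (channel means, channel variances,
edge density at a gradient threshold of 0.1). It exists to exercise the
image-to-features path end to end; it is not realistic histology synthesis.

# Annotators and consensus

Each simulated annotator is a 4×4 row-stochastic confusion matrix plus a
core coverage fraction; coverage is decided per core (an annotator labels
every patch of a covered core or none), and labels are drawn independently
per patch from the confusion row of the true class. Error independence
across patches is a simplification: real pathologists disagree in spatially
coherent regions, so within-core error correlation is a known omission.

The default panel of six profiles mirrors a published annotation design:
four annotators cover all cores, two cover 191/333 and 92/333 of them.
Accuracies range from 0.55 to 0.80 with distinct systematic grade-shift
tendencies (strong under-caller to strong over-caller), because systematic
threshold differences — not random slips — dominate interobserver
variability in Gleason grading, and they are what makes "agreement with the
annotator you trained on" structurally different from "agreement with the
panel".

`majority_vote()` takes the modal label among non-missing votes. Ties go to
the most severe tied class by default: the convention is clinically
conservative and deterministic; least-severe and seeded-random rules are
selectable, and a minimum-vote threshold flags patches with too little
support as undefined rather than erroring. Patches with undefined consensus
are excluded from all experiments up front so that every scheme is
evaluated on one common patch universe — the McNemar pairing requires it.

# Partitioning and the two pinned scenarios

`make_folds()` shuffles the units of the chosen level (patients, cores, or
patches) with the fold specification's seed and deals them round-robin, so
fold sizes
differ by at most one unit; with $n = qk + r$ units the first $r$ folds get
$q+1$. No class stratification is applied by default (plain random
shuffling, matching common practice); a stratified patch-level variant sits
behind a flag. Degenerate folds that lack a class needed by a metric are
handled in the metrics layer, not prevented here.

Two named configurations anchor all frozen regression values:

* **Leakage scenario** (`default_scenario()`): 200 patients, 1–2 cores
  each, 50 patches per core, prevalence (0.4, 0.3, 0.2, 0.1), $\delta = 1$,
  $\sigma_p = 2$, $\sigma_c = 0.5$, $\sigma_e = 1$, 8 features, kNN with
  $k=1$, root seed 20190442. Patient effects twice the class separation
  make same-patient leakage the dominant signal.
* **Cross-expert scenario** (`cross_expert_scenario()`): identical
  structure, but $\sigma_p = 0.4$, $\sigma_c = 0.2$, $\sigma_e = 0.5$.

The two scenarios exist because the two demonstrations need opposite
signal-to-noise regimes, and this was a genuinely open design point. With
$\sigma_p \gg \delta$, no classifier can carry class signal across
patients — which is precisely why patch-level CV looks inflated there, but
also why every trained model's agreement with every annotator collapses
toward zero and the cross-expert comparison degenerates: in that regime the
quadratic-kappa ordering of trainers is governed by the dispersion of
predicted marginals rather than by training-label quality (an
oracle-trained model can score *below* a noisy-trained one). The
cross-expert study instead needs a classifier in the regime of published
grading classifiers — moderate agreement with the panel. Choosing the
per-coordinate noise s.d. $s = \sqrt{\sigma_p^2 + \sigma_c^2 + \sigma_e^2}
\approx 0.67$ against a pairwise class separation $\delta\sqrt 2$ puts
pairwise class confusion near $\Phi(-\delta\sqrt2/2s) \approx 15\%$ and the
resulting classifier-vs-panel kappa in the moderate band, which is where
the single-vs-majority contrast is informative.

# Classifiers

Two deterministic reference models stand in for a real (out-of-scope)
neural network behind a uniform fit/predict contract, chosen for what they
reveal about the protocol rather than for raw performance:

* `knn` with $k = 1$ memorises the training set; a same-patient neighbour
  in the training fold is typically nearest, so it is maximally
  leakage-sensitive. In the informative-feature regime its prediction is
  the trainer's label of a same-class neighbour, so it also faithfully
  propagates an annotator's systematic bias — which is what the
  cross-expert design measures.
* `nearest_centroid` averages patient effects out of the per-class means
  and generalises across patients; it is the natural null model for the
  leakage comparison.

Tie-breaking is deterministic everywhere: exact centroid-distance ties and
kNN vote ties resolve toward the more severe class, neighbour-distance ties
toward the smallest training index. Euclidean distance, no feature scaling
(the simulator controls all scales; scaling would couple the modules).

# Metrics

The four classes are binarized two ways: **detection** (benign vs cancer,
positive = {G3, G4, G5}, all patches included) and **grading** (low- vs
high-grade among true-cancer patches, positive = {G4, G5}). Under grading,
a *predicted* benign on a true-cancer patch counts as low-grade/negative —
the only binary-consistent way to keep every non-benign-truth patch in the
task — and benign-truth patches are excluded. High-grade as the positive
class is a package convention (reported in output headers), since either
convention is computable.

Rates are computed per fold and reported as mean (SD) across folds, SD with
the $n-1$ denominator. A fold whose denominator for a rate is zero (e.g. a
small test fold without positives) contributes nothing to that rate's
mean/SD; the skip is transparent in the per-fold table. Pooled confusion
counts are returned alongside and satisfy the identity
$\text{accuracy} = \pi \cdot \text{sens} + (1 - \pi)\cdot\text{spec}$ at
the pooled level.

Agreement uses quadratic-weighted Cohen kappa over the severity-ordered
classes, $w_{ij} = (i-j)^2/(C-1)^2$, with missing pairs dropped before
tabulation; identical constant vectors define $\kappa = 1$. The
conventional verbal bands are provided, with values in the conventionally
unnamed gap $(0, 0.1)$ labeled "below slight".

# Comparing schemes: McNemar

Because every scheme tests every patch exactly once on the same universe,
two schemes are compared by their paired per-patch correctness. Only the
discordant counts $b, c$ matter. The exact two-sided p-value doubles the
smaller binomial tail, $\min(1, 2\min(P(X \le b), P(X \ge b)))$ with
$X \sim \mathrm{Bin}(b+c, 1/2)$; the asymptotic branch uses the
continuity-corrected $\max(|b-c|-1, 0)^2/(b+c)$ on 1 df, with the
correction clamped at zero so balanced discordance gives $p = 1$ exactly as
the exact test does (unclamped, $b = c$ yields $p \approx 0.93$, an
artifact). The automatic rule switches from exact to chi-square at
$b + c = 25$; both variants are exposed, and they agree to about $10^{-3}$
in p for $b + c \ge 100$. The degenerate $b = c = 0$ case returns $p = 1$
by convention.

# Cross-expert study

Under one patient-level fold assignment, the classifier is trained once per
annotator (on that annotator's labeled patches outside the held-out fold)
and once on the majority-vote consensus; pooled held-out predictions are
scored by quadratic-weighted kappa against each annotator on the held-out
patches that annotator labeled, so partial-coverage annotators contribute
fewer pairs. The **overall** column pools the (prediction, label) pairs
across evaluators before computing kappa; since an "overall" summary could
equally be a per-evaluator mean, both rules are implemented and the one
used is recorded on the result. Kappa is computed per patch; no per-core
aggregation is applied first.

# Problem sizes and numerical choices

The shipped demonstrations run the pinned scenarios at roughly 15,000
patches (200 patients × ~1.5 cores × 50 patches), where the full study
completes in about two minutes on one CPU; unit tests use cohorts of a few
hundred to a few thousand patches, sized so that binomial-oracle checks
have 4-standard-deviation headroom. Exact distance ties in the centroid
classifier are detected with a relative tolerance of $10^{-9}$. All CSV and
JSON outputs avoid timestamps so a re-run under the same root seed is
byte-identical.

# What passing tests do and do not show

The simulator reproduces the *mechanisms* — hierarchical correlation that
ungrouped CV converts into optimistic bias, and systematic annotator
disagreement that single-expert training converts into biased agreement —
under Gaussian effects, independent annotator errors, and i.i.d. patch
classes. Real histopathology adds spatially correlated labels and errors,
non-Gaussian batch effects, class imbalance varying per patient, and a far
stronger classifier; absolute accuracies and kappas here are therefore not
comparable to published values on real tissue, and are not meant to be.
What carries over is ordinal: ungrouped CV overstates performance (even
with half the training data), grouping at the patient level removes the
inflation when no patient effect exists, and majority-vote training
agrees better with the panel than single-expert training.

# Known limitations

* Annotator errors are independent across patches given the true class; no
  contour geometry, no drift over time.
* No nested, repeated, or Monte-Carlo CV; no ROC/AUC or kappa confidence
  intervals.
* The image mode is a pipeline exerciser, not histology synthesis; no
  stain normalisation or physical (µm) calibration.
* Classifiers are intentionally minimal; real models plug in through the
  fit/predict contract but no deep learning is included.
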