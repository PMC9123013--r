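---
title: "Morphodynamic phenotyping of tracked cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphodynamic phenotyping of tracked cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Label-free brightfield time-lapse microscopy records living cells without
reporters: dark, low-contrast objects on a brighter background, imaged here
at a nominal 1 frame/min and 0.33 µm/px over hours. Many biologically
meaningful differences between experimental conditions — receptor knockdown,
drug dose — do not show up in any single frame. They show up in how a cell's
morphology *moves*: membrane ruffling, shape oscillation, crawling-related
cytoplasm remodelling. `morphodyn` quantifies exactly that signal. One
tracked cell becomes one statistical unit; its descriptor is the temporal
variability of a generic image encoding along its trajectory; classification
happens per track and is then consolidated over spatial cell clusters by
majority voting.

The pipeline is, in order: per-frame circle detection (Circular Hough
Transform), minimum-cost frame-to-frame linking (Munkres assignment),
single-linkage spatial clustering of tracks, extraction of a 63×63 px ROI
sequence per track, a luminance-robust preprocessing chain, a pluggable
image backbone producing per-frame feature vectors, the per-feature temporal
standard deviation as the track descriptor, AUC-quantile feature selection,
one of four classifiers under half-experiment-out cross-validation, and
cluster-level majority voting.

## Cell localisation and tracking

**Detection.** Cells are modelled as dark quasi-circular objects with radii
in 4.3–7.6 µm (13–23 px at 0.33 µm/px). Edge pixels (Sobel gradient
magnitude above `grad_threshold`, default 0.05 graylevel/px) vote along
their gradient ray at every radius in the search range ("ray voting"); this
keeps the centre of a moderately deformed cell accumulating even though its
boundary is not a perfect circle, which a strict single-radius vote does
not. The accumulator is smoothed with a σ = 3 px Gaussian; local maxima
above `sensitivity · 2πr · 0.3` (the 0.3 calibrates the peak attenuation
under that smoothing, so `sensitivity` reads as the required fraction of a
complete voting circle) become detections after non-maximum suppression at
1.5× the minimum search radius — two cell bodies cannot overlap that much.
Centres are refined to sub-pixel precision by a 3×3 vote-weighted centroid;
radii are integer-valued (the strongest per-radius vote near the centre).

**Linking.** Frame-to-frame association minimises the total squared
Euclidean centroid distance under a gating radius (default 2× the mean
detected radius) with an exact Hungarian/Munkres solver, implemented in the
package and tested against a brute-force permutation oracle. Unassigned
detections open tracks; gaps up to 2 frames are bridged with linearly
interpolated, flagged positions; tracks shorter than 10 frames are dropped
because temporal statistics on shorter signals are meaningless at this
sampling rate.

**Clusters.** Tracks whose time-averaged centroids lie within a threshold
(default 4× mean radius, i.e. twice the mean diameter) are joined by
single-linkage connected components. Labels are canonical — components are
numbered by their smallest member track id — so the assignment is invariant
to input order.

## ROI preprocessing

Each track yields a 63×63 px crop sequence centred on the rounded detection
(replicate-padded at frame borders). The four-stage chain is:

1. **Inversion** `I = 1 − I_O`: bright cell on dark background.
2. **Background suppression**: per frame, the mean luminance `m` is
   subtracted and negative values are clamped to zero. Because the mean of
   a constant-shifted frame shifts by the same constant, the output is
   *invariant to any constant luminance bias* that does not clip — this is
   the mechanism that makes the whole platform robust to illumination
   changes between acquisitions. The stage output is rounded to a 2⁻¹⁷
   graylevel grid (well below a 16-bit camera step) so the invariance is
   exact in floating-point arithmetic, not merely approximate. Pixels at
   exactly the mean map to zero under either reading of the threshold.
3. **Gaussian windowing**: multiplication by a centred 2-D Gaussian with
   σ = 18 px — the average radius of the detection search range, about
   5.9 µm — normalised to 1 at the centre so the cell centre's intensity is
   preserved (a unit-integral normalisation, which rescales every feature
   by one constant, is available as an option). The window suppresses
   neighbouring cells at the crop periphery.
4. **Adaptive contrast**: the first frame is stretched by the piecewise
   linear map sending its 1st-percentile graylevel `l1` to 0 and its
   99th-percentile `l2` to 1 (linear-interpolation quantiles, R type 7);
   every later frame is histogram-matched to the enhanced first frame.
   A degenerate first frame (`l1 = l2`) maps to all zeros rather than
   dividing by zero.

**Histogram matching** is implemented as exact histogram specification on
the empirical graylevels with a midpoint-CDF tie convention: an atom of
tied pixels (background suppression leaves a large mass at exactly zero) is
taken at the middle of its CDF mass, so atoms of slightly different weight
in source and reference map onto each other, and matching a frame to itself
is exactly the identity. A fixed-bin inverse-CDF table was tried first and
rejected: with a ~50% zero atom sharing a bin with continuum under a steep
stretch slope, coarse bins produced multi-bin errors, and the plain
right-continuous CDF convention could displace the entire atom. The
`hist_bins` parameter is retained for CDF diagnostics.

The "no preprocessing" comparison arm applies the inversion only, so the
backbone always sees the same object polarity; nothing in that arm protects
against luminance bias. Whether the original platform's baseline also
inverted is not stated anywhere; keeping the inversion is this package's
assumption and makes the comparison about background suppression alone.

## Feature backbones

The extractor is pluggable. Four published CNN architectures are recognised
by name; their transfer-layer dimensionalities are architectural constants
and are computed by layer-shape inference (kernel/stride/padding walks and
channel arithmetic) rather than asserted: AlexNet `pool5` 9216, GoogleNet
`pool5` 1024, ResNet101 `pool5` 2048, NASNet-Large `average_pooling` 4032,
with input sizes 227/224/224/331. No pretrained weights ship with this
package, so requesting a named backbone raises an explicit error unless the
fallback is permitted.

The working extractor is a deterministic **filter-bank backbone**: three
difference-of-Gaussian (blob) kernels at octave scale pairs, eight oriented
odd-Gabor (edge) kernels at two scales and four orientations, and two
unit-sum Gaussian local-luminance kernels. The input frame first passes a
fixed rectification `max(I − 0.1, 0)` — the analogue of a biased
convolution + ReLU input stage. This rectification is what makes the
encoding sensitive to absolute luminance, as pretrained CNN features are;
a purely zero-sum linear filter bank would be constitutionally blind to a
constant bias and the background-suppression comparison would be vacuous.
Responses are pooled over a 3×3 spatial grid (mean and absolute maximum per
cell; the luminance channels pool their own rectified response), giving
13 × 9 × 2 = 234 interpretable features per frame. A seeded Gaussian random
projection to any other dimensionality, followed by a ReLU, is available
but off by default: projection mixes periphery-contaminated pooled cells
into every output and measurably degrades cross-region generalisation.

**Track descriptor.** Each feature's signal over the track is summarised by
its sample (n−1) standard deviation; features that are zero for the whole
sequence are dropped and the mask recorded. The coefficient of variation
(sd/|mean|) is exposed as an option because the original description is
ambiguous between "standard deviation" and "relative standard deviation";
plain sd is the default.

**Traditional benchmark branch.** A pluggable segmenter (built-in: Otsu
threshold on the preprocessed frame, hole filling, nearest-to-centre
component; any external mask provider can be substituted) yields per-frame
masks from which four shape descriptors (area, perimeter, eccentricity,
solidity — the last as mask pixels over rasterised convex-hull pixels) and
13 Haralick GLCM texture statistics (distance 1, 4 directions averaged, 64
graylevels) are computed. Each of the 17 signals is summarised by five
trajectory statistics — mean, standard deviation, skewness, kurtosis, and
Shannon entropy of the signal's 32-bin value histogram — for an
85-dimensional descriptor. Constant signals report zero skewness and
kurtosis rather than NaN.

## Selection, classification, evaluation

**AUC-quantile selection.** Each feature's class-separation AUC is the
normalised Mann–Whitney pair statistic (midranks for ties; verified against
exhaustive pair counting). Features with AUC below the 0.1 quantile or
above the 0.9 quantile of all feature AUCs are selected — both tails are
informative, one with flipped sign. Thresholds are computed inside each
training fold only. If every AUC is identical the selection falls back to
the top features by |AUC − 0.5| and flags it. With more than two classes,
one-vs-rest AUCs are computed per feature and the largest deviation
|AUC − 0.5| (mapped back to the 0.5 + dev scale) is the selection score —
an extension chosen here to preserve the "keep the extremes" intent, since
the original selection is only defined for one AUC per feature.

**Classifiers.** Linear SVM (C = 1; any convergent linear-SVM optimiser
defines the same decision function, so the solver named in the original
environment is not material); a tree ensemble — the printed hyperparameter
grid (ensemble cycles, maximum splits, shrinkage learning rate) describes a
*boosted* ensemble rather than a classical random forest, so the boosted
variant (tuned over depth, learning rate and rounds by inner 5-fold CV) is
the default and a classical random forest is available; diagonal-covariance
LDA (closed form, pooled per-feature variances); and KNN with K = 9
restricted to the top 2.5% of features ranked by |AUC − 0.5| on the
training fold. Features are z-scored with training-fold statistics before
any distance-based or margin-based fit. All fits are seeded and
deterministic.

**Half-experiment-out cross-validation.** Every video is split at its
vertical midline; a cluster's side is the side of its mean track centroid.
Fold 1 tests all left clusters (training on all right clusters, across
videos); fold 2 is the mirror image. Whole clusters move together, so no
spatial neighbourhood is ever split between training and test; the fold
construction asserts this and a video whose clusters all fall on one side
is rejected with a diagnostic. Reported accuracies are the unbalanced
accuracy (confusion-matrix trace over total instances), mean ± sd over the
two folds.

**Cluster voting.** A cluster's label is the mode of its tracks' predicted
labels; ties break by the larger summed classifier score, then
lexicographically, and are flagged. Cluster-level confusion matrices count
clusters, not tracks. For independent track errors at per-track accuracy
p = 0.7 and cluster size 5, the closed-form majority-vote accuracy is
0.83692, which the test suite checks against Monte-Carlo voting.

**Bias sensitivity.** Models are trained on unbiased ROIs; a constant
graylevel offset (0.3 or 0.5 of the dynamic range) is injected into test
ROIs only, in both preprocessing arms. With background suppression and no
clipping the descriptor matrices are bit-identical across bias levels, so
every accuracy in that column is constant by construction; without
preprocessing the rectified backbone's features degrade as the bias pushes
the image across the rectification threshold.

**Single-time-point baseline.** Every frame is one instance described by
its raw per-frame feature vector; folds are inherited from the cluster
split so no frame of a test track appears in training. On synthetic classes
that differ only in temporal variance of morphology this baseline has no
signal to use, which is the premise of comparing it against track-level
dynamics.

**PCA scores.** Standardised descriptors are projected onto principal
components for score scatter plots; constant feature matrices are rejected.

## The synthetic-video generator

No acquisition from the original study is publicly deposited, so the
package ships a seeded generator that emulates the study conditions and
makes every stage testable. Cells are filled dark discs (contrast 0.35
below a 0.75 background) with two low-order angular boundary harmonics
(k = 2, 3) whose coefficients follow an Ornstein–Uhlenbeck process at the
class `fluctuation_rate`; `fluctuation_amplitude` a scales the radial
modulation as 0.5·a per harmonic. A slight static sinusoidal internal
texture avoids flat interiors. Motion is an OU random walk tethered to the
cluster centroid (tether 0.05/frame), so clusters persist as they do in
culture. Cluster centres sit on a jittered lattice at the requested
spacing; infeasible layouts fail explicitly. Gaussian camera noise
(sd 0.02) is added and values clamped to [0, 1]. The ground-truth table
includes the closed-form area of the perturbed boundary,
πr₀²(1 + (c₂² + c₃²)/2), which serves as the oracle for morphodynamic
effect-size checks.

Defaults, chosen once for realism at desk scale: 512×512 px, 60 frames at
1 frame/min (full 12-h, 720-frame runs remain configurable), radius
5.9 ± 0.5 µm (the centre of the detection search range), speed 0.2 µm/min
(slow epithelial crawling), fluctuation amplitude 0.15 and rate 0.2/min,
4 clusters of 5 cells at 80 µm centre spacing. The standard two-class
experiment contrasts amplitude 0 against 0.3 with 40 cells per class over
two videos per class — one condition per video, as in a real acquisition.

What the generator does **not** emulate: uneven illumination fields, focus
drift, cell division and death, intensity texture dynamics inside the cell,
optics (PSF), and any camera noise beyond stationary additive Gaussian.
Passing the synthetic end-to-end checks therefore demonstrates that the
machinery recovers a known morphodynamic signal under controlled conditions
— not that it reproduces the original biological accuracies, whose videos
are unavailable.

## Numerical choices and degenerate inputs

* Quantiles everywhere use R's default linear-interpolation estimator
  (type 7).
* Background suppression quantises its output (2⁻¹⁷ grid) to make bias
  invariance exact; the tie at the mean maps to zero either way.
* Degenerate stretch (`l1 = l2`) yields a zero frame; single-frame tracks
  are rejected by the dynamics descriptor; all-empty mask sequences are
  rejected by the traditional branch; empty frames yield flagged empty
  masks.
* Assignment costs must be finite; gating is implemented by padding the
  cost matrix so unassignment at gate cost is always available.
* Voting ties and selection fallbacks are deterministic and flagged.
* Every stochastic step (simulation, classifier fitting, projections)
  derives from an explicit integer seed; reruns are bit-identical.

## Problem sizes

The shipped tests and the acceptance script run the pipeline at desk scale:
512×512 px videos, 60 frames, 80 + 40 tracks for the two-class experiment
and its null control, 24 tracks × 30 frames for the bias-sensitivity table,
200-instance oracle sweeps, and 10⁵ Monte-Carlo draws for the voting check.
All sizes are configurable upward.

## Known limitations

* The CHT localises strongly deformed cells with a few pixels of bias
  toward their instantaneous best-fitting circle; the 63×63 crop absorbs
  this, but kinematic read-outs from these tracks would inherit it.
* The filter-bank backbone is a stand-in with an interface identical to a
  pretrained CNN's pooling layer; absolute accuracy levels are not
  comparable to published CNN numbers.
* Single-linkage clustering can chain adjacent clusters into one when
  inter-cluster spacing approaches the linkage threshold; the threshold is
  configurable.
* With two CV folds the reported ± spread is a coarse dispersion estimate;
  repeated seeded replicates are the better instrument and are supported by
  the experiment driver.
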