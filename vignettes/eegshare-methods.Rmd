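---
title: "Information-sharing EEG connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-sharing EEG connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegshare)
```

## Scope

`eegshare` implements a resting-state EEG functional-connectivity analysis
built around the weighted Symbolic Mutual Information (wSMI) measure, the
topographic group statistics used in frontotemporal-dementia connectivity
studies (between-ROI averages, connectivity as a function of distance, a
two-stage seed analysis), and a repeated-holdout SVM classification stage
driven by connectivity and neuropsychological features. Because clinical
resting-state EEG of this kind is not freely available, the package pairs
the analysis chain with a synthetic cohort generator whose ground truth
(which region pairs lose coupling, and by how much) is known, so every
stage can be validated end to end.

## The wSMI measure

Each channel is converted to a stream of ordinal patterns: at time $t$ the
$k$ samples $x_t, x_{t+\tau}, \dots, x_{t+(k-1)\tau}$ are replaced by the
permutation that sorts them (stable ties: the earlier sample ranks lower).
With $k = 3$ there are $3! = 6$ symbols. For two channels $X, Y$ the joint
symbol distribution $p(x, y)$ is accumulated over all time points of all
epochs of a subject, and

$$\mathrm{SMI}(X,Y) = \frac{1}{\log_2 k!} \sum_{x,y}
  p(x,y)\,\log_2\!\frac{p(x,y)}{p(x)\,p(y)},$$

so that independence gives 0 and a deterministic one-to-one symbol mapping
gives 1. wSMI multiplies each term by a binary weight that is zero when the
two symbols are identical or sign-mirrored (the pattern of $-x$). This
discounts the two couplings that a single common source seen by both
electrodes produces at zero lag — identical patterns, or mirrored ones when
the electrodes sit on opposite sides of a dipole — which is the standard
defence against volume conduction for this family of measures.

Two numerical notes:

* wSMI is **not** bounded above by SMI. When coupling is lagged, the
  identical/mirrored joint cells are *under*-represented relative to the
  product of marginals, their MI terms are negative, and removing them
  raises the value. The invariant the weighting actually guarantees — and
  the one the test suite asserts — is suppression: for a zero-lag common
  source wSMI is a small fraction of SMI, while lagged coupling survives.
* The plug-in estimator has a small positive bias at finite sample size;
  with the default epoch budget (about $3\times10^4$ symbol pairs per
  channel pair) independent channels score within $\pm 0.01$ of zero.

**Parameters.** $k = 3$ throughout (6 symbols keep the joint table well
populated at desk-scale epoch counts). The spacing $\tau$ sets the
frequency band the measure is sensitive to; the default is 16 ms (4 samples
at 256 Hz), which the test suite verifies empirically to prefer 8–20 Hz
(alpha/beta) coupling over slow rhythms — the band in which frontotemporal
dementia shows connectivity alterations. Both are exposed via
`symbol_params()`. Counts are pooled across epochs before normalizing,
which for equal-length epochs equals averaging per-epoch estimates; the
diagonal of every connectivity matrix is a structural zero.

## Head model and topography

Electrode positions live on a unit-radius spherical cap of half-angle
$\arcsin(0.9) \approx 64^\circ$, so the maximum chordal inter-electrode
distance is $2 \times 0.9 = 1.8$ (dimensionless head-sphere units). Only
the relative distance structure enters the analyses, and this choice makes
the observed range $[0, 1.8]$ divide into the short/mid/long tertiles at
0.6 and 1.2 used by the distance analysis. Distances are chordal rather
than along-scalp; both are monotonically related, so binned summaries are
unaffected by the choice.

Two deterministic layouts are provided: a 128-channel cap built from
equal-spacing rings (labels `E001`–`E128`) with seven regions of interest
assigned by azimuth/elevation sectors, and the clinical 20-electrode 10/20
set with a curated ROI map. The seven ROIs are left/right frontal (R1, R2),
right/left temporal (R3, R6), right/left posterior (R4, R5) and a
midline/central strip (R7, which also holds the midline occipital
electrode in the 10/20 layout). The exact electrode-to-region boundary of
a physical cap is not reproducible from published figures; the sector
rule approximates the standard seven-region partition, and every analysis
is a function of the partition only, so a user can substitute their own
montage table via `read_montage()`.

`subset_montage()` restricts a montage to a channel subset with ROI
assignments preserved — the low-density replication mode (running the
whole pipeline on 20 electrodes) is just the same pipeline on a subset or
on the 10/20 layout directly.

## Synthetic cohorts

`simulate_cohort()` emulates a two-group resting-state study, by default 13
patients vs 25 controls on the 20-channel montage with 60 two-second
epochs per subject at 256 Hz. Each channel is $1/f$ background noise plus
band-limited (8–20 Hz) oscillatory noise. Information sharing is injected
per ROI pair: each of the 21 pairs has a latent band-limited source mixed
into the channels of one region directly and into the channels of the
other region after a 16 ms lag and a mild `tanh` nonlinearity. The lag
matters: a zero-lag shared source is exactly what the wSMI weighting
suppresses, so an unlagged generator would be invisible to the measure it
is meant to exercise. Patients have the mixing weight of the designated
altered links (default: left frontal–left parietal R1–R5 and right
frontal–right temporal R2–R3, mirroring the frontotemporal
hypoconnectivity pattern) multiplied by $1 - \text{coupling\_drop}$.

Between-subject heterogeneity comes from a truncated-normal multiplicative
jitter on every link weight (`coupling_sd`). The defaults
(`base_coupling = 0.5`, `coupling_drop = 0.55`, `coupling_sd = 0.3`) were
calibrated once so that the subject-level wSMI difference on the altered
links is a large effect, Cohen's $d \approx 1$ (median across cohorts
$d \approx 1.0$–$1.1$ per link), matching the effect sizes reported for
this contrast in the clinical literature. An earlier log-normal jitter was
rejected because its heavy right tail inflated the control-group variance
and made the realized effect size unstable across cohorts.

What the generator does **not** emulate: volume-conduction mixing beyond
the zero-lag component implied by shared sources, artifacts (blinks, EMG),
non-stationarity, and realistic absolute wSMI levels — with six
independent pair sources per channel the pairwise shared-variance fraction
is bounded at 1/6, so synthetic wSMI values sit near 0.005 rather than the
~0.06 of clinical recordings. Passing tests therefore demonstrate that the
*pipeline* recovers group structure of a known size and location, not that
the generator reproduces clinical EEG.

A 19-variable neuropsychological table (global scores and subscores of a
global cognitive screen, a frontal/executive screen, a verbal learning
test, and two verbal fluencies) is drawn per subject from truncated
normals whose group means and SDs follow reference patient/control
summary statistics for this clinical contrast where available and
plausible values elsewhere (`default_npv_spec()`).

## Group statistics

*Between-ROI comparison.* The 21 ROI-pair connectivity means are compared
between groups with the two-sided Wilcoxon rank-sum test — exact
enumeration when the pooled sample size is at most 12 and tie-free, normal
approximation with tie correction otherwise (no continuity correction, so
identical samples give $p = 1$) — followed by Benjamini–Hochberg FDR at
$q = 0.05$. Cohen's $d$ (pooled, $n-1$ weighting) is reported per pair,
oriented so positive means controls above patients.

*Distance profiles.* Connections from ROI-internal to ROI-external
electrodes are binned by distance: tertile bins for the short/mid/long
summary, and sliding windows of width 0.15 stepped by 0.05 for the
per-distance curves (clinical reports of this analysis plot $p$ against
continuous distance, rarely stating a bin width; the window is narrow enough to
localize link-scale effects and wide enough to hold several connections on
a 20-channel montage). Empty bins are flagged, never zero-filled. Group
differences are tested per bin with a Monte-Carlo permutation test:
statistic $|$difference of group means$|$, subjects' group labels shuffled
jointly across bins, add-one estimator $p = (\text{exceedances}+1)/(n_{perm}+1)$,
default 5,000 permutations. The pooled rows are sorted into a canonical
order before permuting and the smaller group is resampled, which makes the
p-values exactly invariant to swapping the group arguments. A subject-level
bootstrap variant is deliberately not the default: label permutation is the
defensible core of the cited procedure and is what the calibration tests
certify.

*Seed analysis.* Every electrode of a seed region is tested against every
region-external electrode (rank-sum across subjects). Per external
electrode the map reports the median of the raw p-values over seeds and
the signed score $-\log_{10}(\text{median } p) \times \mathrm{sign}$,
where the sign is that of the median of $W$ minus its null expectation
across seeds — positive for hypoconnectivity in patients. Scores beyond
$\pm 1.3$ correspond to median $p < 0.05$. FDR correction is applied over
all seed-by-external connections of one seed region (not pooled across
seed regions), and the map counts FDR-significant connections per external
electrode. The second stage averages the left and right frontal maps per
shared external electrode, takes the regions containing scores above 1.3,
selects the five highest-scoring electrodes of each (ties broken by
channel label order), re-runs the seed analysis with these as seeds, and
groups the significant external electrodes falling in the original
frontal regions into derived "new left/right frontal" sets.

*Summary-statistics tests.* Published demographic tables report only
means, SDs and group sizes, so `summary_ttest()` implements the pooled-
variance two-sample t-test from summary data and `chisq_2x2()` the Pearson
chi-squared without continuity correction; the pooled form (not Welch)
reproduces the published p-values exactly, which the acceptance suite
asserts.

## Classification

Six connectivity variables per subject: mean connectivity of the left
frontal ROI over distances 0–1.45 and of the right frontal ROI over
0.6–1.45 (the distance ranges where frontotemporal hypoconnectivity is
reported clinically), plus the four set-pair means linking the derived
frontal seed sets to the left-parietal and right-temporal hub sets from
the seed analysis. On cohorts where a seed stage finds nothing (null
cohorts), the electrode sets fall back to the corresponding full ROIs so
the feature table stays well defined. Neuropsychological features are the
19 table columns.

The classifier is a linear-kernel SVM with $C = 1$ (the smallest
defensible choice at $n = 38$; kernel and cost are exposed), trained per
repeat on 7 randomly drawn subjects per group with features z-scored by
the training statistics, and evaluated on the held-out subjects — 6
patients and 18 controls per repeat at the default design. 1,000 repeats
(200 in the scaled validation runs) yield sensitivity/specificity means
and SDs; the single "classification rate" is reported as mean balanced
accuracy because the test sets are imbalanced, with raw accuracy
alongside. Decision scores are pooled across repeats, oriented so higher
means more patient-like, for ROC/AUC (a reversed ranking therefore scores
0, not 0.5). Models are compared with a two-sample Hotelling's $T^2$ on
the per-repeat (sensitivity, specificity) pairs, with the caveat that
repeats share subjects and are not independent — the test orders models
rather than providing calibrated error rates.

## Validation strategy and problem sizes

The package certifies itself at two levels, both runnable from
`tests/testthat/` and recomputed by `scripts/acceptance.R`:

* **Calibration (null cohorts).** With `coupling_drop = 0` the groups are
  generatively identical; over 300 reduced cohorts (8 one-second epochs
  at 128 Hz — the null behaviour of the tests does not depend on the
  epoch budget) the ROI-pair rank-sum test and the distance permutation
  test must hold their nominal 5% level within ±3 points.
* **Recovery (effect cohorts).** Over 50 cohorts at the full default
  design, the injected links must be FDR-flagged, the distance deficit
  detected at the distances the injected connections actually span, and
  the seed maps must light up the partner regions, each in at least 80%
  of cohorts; CNV-based classification must exceed 0.65 balanced accuracy
  on effect cohorts and sit at chance on null cohorts.

Note that each injected link constrains where its distance deficit can
appear: on the 10/20 montage the right frontal–right temporal connections
span distances 0.56–1.06 (short-to-mid; lateral frontal and temporal
electrodes are adjacent on the outer ring), while left frontal–left
parietal connections span 1.06–1.71. The recovery check therefore looks
for significant hypoconnectivity windows overlapping each link's own
distance support rather than a fixed "mid/long" interval.

## Known limitations

* Scalp-level only; no source localization or leakage correction beyond
  the wSMI weighting itself.
* The generator's coupling model is pairwise at the ROI level; it does not
  produce realistic cross-frequency structure or graph topology.
* Statistical power at the study's sample size (13 vs 25) with effects of
  $d \approx 1$ is intrinsically moderate for FDR-corrected 21-way
  comparisons; recovery rates near the 80% line reflect that, not an
  estimator defect.
* Hotelling's $T^2$ on repeated-holdout pairs inherits the dependence
  caveat above.
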