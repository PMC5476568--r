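# eegshare

Information-sharing EEG connectivity analysis with weighted Symbolic
Mutual Information (wSMI), for studies that ask whether a patient group —
the motivating case is behavioral-variant frontotemporal dementia against
matched controls, with an Alzheimer's group as disease control — shows
topographically specific loss of long-range cortical communication in
resting-state EEG, and whether that loss is useful as a classification
feature alongside neuropsychological testing.

## What it computes

**wSMI connectivity.** Each channel is reduced to ordinal patterns: the
permutation sorting the samples $x_t, x_{t+\tau}, \dots, x_{t+(k-1)\tau}$
(default $k = 3$, $\tau = 16$ ms, which makes the measure sensitive to
8–20 Hz coupling). For channels $X, Y$,

$$\mathrm{wSMI}(X,Y)=\frac{1}{\log_2 k!}\sum_{x,y} w(x,y)\,
p(x,y)\log_2\frac{p(x,y)}{p(x)p(y)},\qquad
w(x,y)=0 \iff x=y \text{ or } x=\bar y,$$

where $\bar y$ is the sign-mirrored pattern — the weight suppresses the
zero-lag couplings produced by common sources and volume conduction.

**Topographic group statistics.** Per-subject connectivity matrices are
reduced to (i) the 21 between-ROI average connectivities of a seven-region
scalp partition, compared with Wilcoxon rank-sum tests under
Benjamini–Hochberg FDR; (ii) connectivity as a function of
inter-electrode distance (short/mid/long tertiles and sliding windows)
tested with Monte-Carlo label-permutation tests; (iii) a two-stage seed
analysis producing per-electrode median-p maps (signed
$-\log_{10}$ scores, significant beyond ±1.3) and FDR connection counts.

**Classification.** Six connectivity variables (two frontal distance-range
means, four seed-derived set-pair means) and/or 19 neuropsychological
variables feed a linear SVM trained on 7 randomly drawn subjects per
group and evaluated on the rest, repeated 1,000 times, with
sensitivity/specificity summaries, pooled-score ROC/AUC, and Hotelling's
T² model comparisons.

**Synthetic cohorts.** Because the clinical recordings behind such studies
are not redistributable, `simulate_cohort()` generates two-group cohorts
(default 13 patients vs 25 controls, 20-channel 10/20 montage, 60 × 2 s
epochs at 256 Hz) with lagged, nonlinearly mixed band-limited sources
shared between region pairs, frontotemporal/frontoparietal coupling
reduced in patients at a calibrated effect size (Cohen's d ≈ 1), and a
matching neuropsychological table — so every stage of the pipeline can be
validated against ground truth.

## Worked example

```r
library(eegshare)

cfg <- pipeline_config(design = cohort_design(seed = 7),
                       n_perm = 999, n_repeats = 200)
bundle <- run_pipeline(cfg)

subset(bundle$roi_pairs, fdr_sig,
       select = c(pair, mean_patient, mean_control, p, p_adj, cohens_d))
#>     pair mean_patient mean_control      p p_adj cohens_d
#> 4  R1-R5      0.00075       0.0048 0.0027 0.021     1.16
#> 7  R2-R3      0.00091       0.0052 0.0020 0.021     0.88
#> 18 R4-R7      0.00675       0.0032 0.0030 0.021    -1.11
bundle$distance$left_frontal$test          # short / mid / long tertiles
#>   bin observed     p
#> 1   1 -0.00055 0.474
#> 2   2 -0.00112 0.027
#> 3   3 -0.00066 0.262
bundle$stage2$significant_rois
#> [1] "R5"
bundle$classification$CNV$classification_rate
#> [1] 0.693
bundle$classification$CNV$roc$auc
#> [1] 0.764
```

This cohort was generated with hypoconnectivity injected on the left
frontal–left parietal (R1–R5) and right frontal–right temporal (R2–R3)
links at subject-level Cohen's d ≈ 1. Both injected pairs survive FDR with
large positive effect sizes (controls above patients); R4–R7, with the
opposite sign, is a type-I slip of the 21-way comparison. The left frontal
ROI loses mid-range connectivity (permutation p = 0.027), the second-stage
seed analysis recovers the left parietal hub, and connectivity-only
classification reaches 0.69 balanced accuracy (AUC 0.76). Numbers vary
with the seed.

The seed maps (`bundle$stage1`), the derived second-stage ROIs
(`bundle$stage2`) and per-repeat classification tables are in the same
bundle; `write_bundle(bundle, "out/")` exports everything as tidy CSV plus
a JSON summary. A thin command-line wrapper lives at
`inst/cli/infoshare.R` (`simulate` and `run-all` subcommands).

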