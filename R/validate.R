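# Ground-truth validation of the pipeline on synthetic cohorts: does each
# analysis stage recover the injected hypoconnectivity links?

#' Evaluate recovery of injected effects on one synthetic cohort
#'
#' Runs the three topographic analyses plus the CNV classifier on a cohort
#' simulated with known altered links, and scores each stage against the
#' ground truth:
#' \describe{
#'   \item{pair_flagged}{at least one injected ROI pair is FDR-significant
#'     in the hypoconnectivity direction in [roi_pair_comparison()].}
#'   \item{false_pair}{some non-injected pair is FDR-flagged (specificity
#'     check).}
#'   \item{distance_deficit}{for at least one injected link, the seed-ROI
#'     fine-grained distance profile has a permutation-significant
#'     (p < 0.05) hypoconnectivity window overlapping the distances of that
#'     link's electrode connections (each link's deficit can only appear at
#'     the distances its connections span).}
#'   \item{seed_hotspot}{for at least one injected link, a stage-1 seed map
#'     of the link's first ROI scores an electrode of the partner ROI above
#'     [seed_score_threshold()].}
#'   \item{cnv_balanced_accuracy}{mean balanced accuracy of the CNV-only
#'     repeated-holdout SVM (stage-2-derived features).}
#' }
#'
#' @param cohort An `eeg_cohort` with connectivity matrices and a non-empty
#'   `truth` table (see [simulate_cohort()]).
#' @param n_perm Permutations for the distance tests.
#' @param n_repeats SVM repeats.
#' @param seed RNG seed for permutation and classification stages.
#' @param q FDR level.
#' @return List with the elements described above plus `flagged_pairs`.
#' @export
recover_injected_effects <- function(cohort, n_perm = 499, n_repeats = 200,
                                     seed = 1L, q = 0.05) {
  if (is.null(cohort$truth) || !nrow(cohort$truth))
    stop("cohort has no injected links to recover")
  m <- cohort$montage
  dm <- distance_matrix(m)
  links <- cohort$truth
  link_names <- paste(links$roi_a, links$roi_b, sep = "-")

  rp <- roi_pair_comparison(cohort, q = q)
  flagged <- rp$pair[rp$fdr_sig & rp$sign > 0]

  fine <- sliding_bins(max(dm))
  dist_hit <- vapply(seq_len(nrow(links)), function(i) {
    rf <- links$roi_a[i]; rh <- links$roi_b[i]
    supp <- range(dm[roi_electrodes(m, rf), roi_electrodes(m, rh)]) +
      c(-0.05, 0.05)
    gp <- group_distance_profiles(cohort, rf, fine)
    tt <- permutation_profile_test(gp$patient, gp$control, n_perm = n_perm,
                                   seed = seed)
    sel <- fine$hi > supp[1] & fine$lo < supp[2]
    any(tt$p[sel] < 0.05 & tt$observed[sel] < 0, na.rm = TRUE)
  }, logical(1))

  seed_rois <- unique(c(links$roi_a, "R1", "R2"))
  s1 <- seed_analysis(cohort, seed_rois, q = q)
  hot <- vapply(seq_len(nrow(links)), function(i) {
    mp <- s1[[links$roi_a[i]]]
    part <- roi_electrodes(m, links$roi_b[i])
    any(mp$score[mp$electrode %in% part] > seed_score_threshold())
  }, logical(1))

  stage2 <- second_stage_seeds(cohort, s1[c("R1", "R2")], q = q)
  fspec <- default_feature_spec(m, stage2)
  ft <- build_features(cohort, fspec, "CNV")
  rep <- svm_repeated_holdout(ft$x, ft$labels, n_repeats = n_repeats,
                              seed = seed)

  list(pair_flagged = any(link_names %in% flagged),
       false_pair = any(!flagged %in% link_names),
       distance_deficit = any(dist_hit),
       seed_hotspot = any(hot),
       cnv_balanced_accuracy = rep$classification_rate,
       flagged_pairs = flagged)
}
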