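# Shared fixtures: small designs and toy montages built in code.

# fast desk-scale design for unit tests (few short epochs, low rate)
tiny_design <- function(n_patients = 3, n_controls = 4,
                        epochs_per_subject = 4, epoch_len_s = 1, fs = 128,
                        seed = 42, ...) {
  cohort_design(n_patients = n_patients, n_controls = n_controls,
                epochs_per_subject = epochs_per_subject,
                epoch_len_s = epoch_len_s, fs = fs, seed = seed, ...)
}

# reduced design for calibration loops: null unless stated otherwise
calib_design <- function(seed, coupling_drop = 0, n_patients = 13,
                         n_controls = 25) {
  cohort_design(n_patients = n_patients, n_controls = n_controls,
                epochs_per_subject = 8, epoch_len_s = 1, fs = 128,
                coupling_drop = coupling_drop, seed = seed)
}

# two-ROI toy montage: 2 electrodes per ROI on a circle
toy_montage <- function() {
  pos <- rbind(c(0, 1, 0), c(sin(0.3), cos(0.3), 0),
               c(0, -1, 0), c(sin(0.3), -cos(0.3), 0))
  eegshare:::new_montage(c("a1", "a2", "b1", "b2"), pos,
                         c("RA", "RA", "RB", "RB"))
}

# connectivity matrix with prescribed upper-triangle values
toy_cm <- function(labels, values) {
  n <- length(labels)
  cm <- matrix(0, n, n, dimnames = list(labels, labels))
  cm[upper.tri(cm)] <- values
  cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
  cm
}

# cohort with hand-set connectivity matrices (no EEG)
cm_cohort <- function(cms, groups, montage, npv = NULL) {
  ids <- sprintf("S%02d", seq_along(cms))
  names(cms) <- ids
  if (is.null(npv)) npv <- data.frame(subject = ids)
  structure(list(subjects = data.frame(subject = ids, group = groups,
                                       stringsAsFactors = FALSE),
                 eeg = NULL, connectivity = cms, npv = npv,
                 montage = montage, design = NULL, truth = NULL),
            class = "eeg_cohort")
}
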