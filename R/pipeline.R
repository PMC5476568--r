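# End-to-end orchestration: simulate (or load) a cohort, compute wSMI
# connectivity, run the three topographic analyses, derive the six
# connectivity variables from the seed-analysis outputs, and classify.

#' Pipeline configuration
#'
#' @param design A [cohort_design()] (ignored when `cohort` is passed to
#'   [run_pipeline()] directly).
#' @param symbol_params A [symbol_params()]; defaults to k = 3, tau 16 ms at
#'   the design sampling rate.
#' @param fdr_q FDR level for all corrected comparisons.
#' @param n_perm Permutations for the distance-profile test.
#' @param n_train_per_group,n_repeats Repeated-holdout SVM settings.
#' @param modes Classification feature modes to run.
#' @param seed Master seed; per-stage seeds are derived from it by fixed
#'   offsets so stages can be rerun in isolation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = cohort_design(),
                            symbol_params = eegshare::symbol_params(fs = design$fs),
                            fdr_q = 0.05, n_perm = 5000,
                            n_train_per_group = 7, n_repeats = 1000,
                            modes = c("NPV", "CNV", "BOTH"),
                            seed = design$seed) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  structure(list(design = design, symbol_params = symbol_params,
                 fdr_q = fdr_q, n_perm = n_perm,
                 n_train_per_group = n_train_per_group,
                 n_repeats = n_repeats, modes = modes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# fixed per-stage seed offsets (documented fan-out from the master seed)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, permutation = 101L, classify = 211L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Default six-CNV feature specification
#'
#' Two frontal distance-range means (0-1.45 for the left frontal ROI,
#' 0.6-1.45 for the right frontal ROI) plus the four set-pair means linking
#' the derived frontal seed sets to the parietal/temporal hub sets. When a
#' stage of the seed analysis found nothing significant (e.g. on a null
#' cohort) the corresponding electrode sets fall back to the full frontal
#' ROIs and to the left-posterior/right-temporal ROIs, so that the feature
#' table is always well-defined.
#'
#' @param montage An `eeg_montage`.
#' @param stage2 Output of [second_stage_seeds()] (may be NULL).
#' @param npv_columns NPV column names (defaults to the 19 standard ones).
#' @return A [feature_spec()] with exactly six CNVs.
#' @export
default_feature_spec <- function(montage, stage2 = NULL,
                                 npv_columns = default_npv_spec()$variable) {
  hub_lp <- NULL; hub_rt <- NULL
  if (!is.null(stage2) && stage2$any_significant) {
    hub_lp <- stage2$new_seeds[["seed_R5"]]
    hub_rt <- stage2$new_seeds[["seed_R3"]]
    new_lf <- stage2$derived_rois$new_left_frontal
    new_rf <- stage2$derived_rois$new_right_frontal
  } else new_lf <- new_rf <- NULL
  if (is.null(hub_lp) || !length(hub_lp)) hub_lp <- roi_electrodes(montage, "R5")
  if (is.null(hub_rt) || !length(hub_rt)) hub_rt <- roi_electrodes(montage, "R3")
  if (is.null(new_lf) || !length(new_lf)) new_lf <- roi_electrodes(montage, "R1")
  if (is.null(new_rf) || !length(new_rf)) new_rf <- roi_electrodes(montage, "R2")
  feature_spec(
    range_features = list(
      list(roi = "R1", d_min = 0, d_max = 1.45, name = "cnv_lf_distance"),
      list(roi = "R2", d_min = 0.6, d_max = 1.45, name = "cnv_rf_distance")),
    set_features = list(
      list(set_a = new_rf, set_b = hub_rt, name = "cnv_rf_rtemporal"),
      list(set_a = new_rf, set_b = hub_lp, name = "cnv_rf_lparietal"),
      list(set_a = new_lf, set_b = hub_rt, name = "cnv_lf_rtemporal"),
      list(set_a = new_lf, set_b = hub_lp, name = "cnv_lf_lparietal")),
    npv_columns = npv_columns)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort simulation (or a supplied cohort), wSMI
#' connectivity, between-ROI comparison, distance analysis with permutation
#' tests on the two frontal ROIs, stage-1 and stage-2 seed analyses, CNV
#' construction from the seed outputs, and NPV/CNV/BOTH repeated-holdout
#' classification with ROC/AUC.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `eeg_cohort` (skips simulation).
#' @return A result bundle (list) with elements `config`, `cohort`,
#'   `roi_pairs`, `distance` (per frontal ROI: profiles and permutation
#'   p-values), `stage1`, `stage2`, `feature_spec`, `classification` (per
#'   mode: report and ROC/AUC).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$design)
  }
  if (is.null(cohort$connectivity))
    cohort <- compute_connectivity(cohort, config$symbol_params)
  m <- cohort$montage
  bins <- tertile_bins(max(distance_matrix(m)))

  roi_pairs <- roi_pair_comparison(cohort, q = config$fdr_q)

  distance <- lapply(c(left_frontal = "R1", right_frontal = "R2"),
                     function(roi) {
    gp <- group_distance_profiles(cohort, roi, bins)
    test <- permutation_profile_test(gp$patient, gp$control,
                                     n_perm = config$n_perm,
                                     seed = stage_seed(config$seed, "permutation"))
    list(roi = roi, bins = bins, profiles = gp, test = test)
  })

  stage1 <- seed_analysis(cohort, c("R1", "R2"), q = config$fdr_q)
  stage2 <- second_stage_seeds(cohort, stage1, q = config$fdr_q)

  fspec <- default_feature_spec(m, stage2)
  classification <- lapply(stats::setNames(config$modes, config$modes),
                           function(mode) {
    ft <- build_features(cohort, fspec, mode)
    rep <- svm_repeated_holdout(ft$x, ft$labels,
                                n_train_per_group = config$n_train_per_group,
                                n_repeats = config$n_repeats,
                                seed = stage_seed(config$seed, "classify"))
    c(rep, roc = list(roc_auc(rep)))
  })

  list(config = config, cohort = cohort, roi_pairs = roi_pairs,
       distance = distance, stage1 = stage1, stage2 = stage2,
       feature_spec = fspec, classification = classification)
}

#' Write the tabular outputs of a pipeline run
#'
#' Tidy CSVs (ROI-pair comparison, distance-profile tests, seed maps,
#' per-repeat classification metrics) plus a JSON summary with the config
#' echo and headline numbers.
#'
#' @param bundle Result of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$roi_pairs, file.path(dir, "roi_pairs.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$distance))
    utils::write.csv(bundle$distance[[nm]]$test,
                     file.path(dir, paste0("distance_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(bundle$stage1))
    utils::write.csv(bundle$stage1[[nm]],
                     file.path(dir, paste0("seedmap_stage1_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(bundle$classification)) {
    utils::write.csv(bundle$classification[[nm]]$per_repeat,
                     file.path(dir, paste0("classification_", nm, ".csv")),
                     row.names = FALSE)
  }
  summary <- list(
    seed = bundle$config$seed,
    design = bundle$config$design[c("n_patients", "n_controls",
                                    "montage_layout", "epochs_per_subject",
                                    "epoch_len_s", "fs", "band",
                                    "base_coupling", "coupling_drop")],
    fdr_significant_pairs = bundle$roi_pairs$pair[bundle$roi_pairs$fdr_sig],
    classification_rates = vapply(bundle$classification,
                                  `[[`, numeric(1), "classification_rate"),
    auc = vapply(bundle$classification,
                 function(cl) cl$roc$auc, numeric(1)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write / load a cohort as plain-text files
#'
#' Layout: `cohort.csv` (subject, group), `npv.csv`, `montage.tsv`,
#' `design.json` (epoch structure, sampling rate and generator settings) and
#' one `eeg/<subject>.csv` per subject — a delimited table with columns
#' `channel`, `epoch`, `s1..sN` (one row per channel and epoch).
#'
#' @param cohort An `eeg_cohort` with raw EEG.
#' @param dir Directory.
#' @return `write_cohort` returns `dir` invisibly; `load_cohort` an
#'   `eeg_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$eeg)) stop("cohort holds no raw EEG")
  dir.create(file.path(dir, "eeg"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$npv, file.path(dir, "npv.csv"), row.names = FALSE)
  write_montage(cohort$montage, file.path(dir, "montage.tsv"))
  d <- cohort$design
  jsonlite::write_json(
    list(fs = d$fs, epochs_per_subject = d$epochs_per_subject,
         epoch_len_s = d$epoch_len_s, montage_layout = d$montage_layout,
         n_patients = d$n_patients, n_controls = d$n_controls,
         band = d$band, base_coupling = d$base_coupling,
         coupling_sd = d$coupling_sd, coupling_drop = d$coupling_drop,
         altered_links = d$altered_links, seed = d$seed),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  for (id in cohort$subjects$subject) {
    e <- cohort$eeg[[id]]
    dims <- dim(e$data)
    flat <- matrix(aperm(e$data, c(3, 2, 1)), ncol = dims[3], byrow = TRUE)
    df <- data.table::data.table(
      channel = rep(dimnames(e$data)[[1]], each = dims[2]),
      epoch = rep(seq_len(dims[2]), dims[1]))
    data.table::fwrite(cbind(df, data.table::as.data.table(flat)),
                       file.path(dir, "eeg", paste0(id, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
load_cohort <- function(dir) {
  errs <- character()
  need <- c("cohort.csv", "npv.csv", "montage.tsv", "design.json")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      errs <- c(errs, paste("missing file:", f))
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  subjects <- utils::read.csv(file.path(dir, "cohort.csv"),
                              stringsAsFactors = FALSE)
  npv <- utils::read.csv(file.path(dir, "npv.csv"), stringsAsFactors = FALSE)
  montage <- read_montage(file.path(dir, "montage.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "design.json"),
                              simplifyVector = TRUE)
  design <- cohort_design(
    n_patients = meta$n_patients, n_controls = meta$n_controls,
    montage_layout = meta$montage_layout,
    epochs_per_subject = meta$epochs_per_subject,
    epoch_len_s = meta$epoch_len_s, fs = meta$fs, band = meta$band,
    base_coupling = meta$base_coupling, coupling_sd = meta$coupling_sd,
    altered_links = if (is.matrix(meta$altered_links))
      asplit(meta$altered_links, 1) else meta$altered_links,
    coupling_drop = meta$coupling_drop, seed = meta$seed)
  eeg <- list()
  for (id in subjects$subject) {
    path <- file.path(dir, "eeg", paste0(id, ".csv"))
    if (!file.exists(path)) {
      errs <- c(errs, paste("subject", id, "has no EEG file"))
      next
    }
    dt <- data.table::fread(path)
    chans <- unique(dt$channel)
    n_ep <- max(dt$epoch)
    n_s <- ncol(dt) - 2
    arr <- array(0, dim = c(length(chans), n_ep, n_s),
                 dimnames = list(chans, NULL, NULL))
    vals <- as.matrix(dt[, -(1:2)])
    for (r in seq_len(nrow(dt)))
      arr[dt$channel[r], dt$epoch[r], ] <- vals[r, ]
    eeg[[id]] <- epoched_eeg(id, arr, meta$fs)
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  structure(list(subjects = subjects, eeg = eeg, connectivity = NULL,
                 npv = npv, montage = montage, design = design,
                 truth = ground_truth(design)),
            class = "eeg_cohort")
}
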