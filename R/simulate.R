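# Synthetic two-group resting-state EEG cohorts with controllable
# cross-channel information sharing.
#
# Each channel is 1/f background noise plus band-limited (default 8-20 Hz)
# oscillatory noise. Information sharing is injected per ROI pair: every
# unordered ROI pair has its own band-limited latent source, mixed into the
# channels of one ROI directly and into the channels of the other ROI after a
# lag and a mild tanh nonlinearity. Lagging the shared source keeps the
# coupling visible to wSMI (whose identical/mirrored-symbol weighting nulls
# zero-lag common sources); the nonlinearity exercises the measure's
# sensitivity to non-linear coupling. Patients have the mixing weight of the
# designated altered ROI links multiplied by (1 - coupling_drop); all other
# links are shared at the base level by both groups.

#' Cohort design
#'
#' Defines the generative conditions for a two-group resting-state cohort.
#' Defaults emulate a 13-patient vs 25-control resting-state study on the
#' 20-channel 10/20 montage, with 60 two-second epochs per subject at 256 Hz
#' and hypoconnectivity injected on the left frontal-left parietal (R1-R5)
#' and right frontal-right temporal (R2-R3) links. `coupling_drop` and
#' `coupling_sd` defaults are calibrated so that the subject-level wSMI
#' difference on altered links is a large effect (Cohen's d near 1).
#'
#' @param n_patients,n_controls Group sizes.
#' @param montage_layout Montage name passed to [build_montage()].
#' @param epochs_per_subject,epoch_len_s,fs Epoch count, epoch length
#'   (seconds) and sampling rate (Hz).
#' @param band Passband (Hz) of the oscillatory component and the shared
#'   sources; must lie inside (0, fs/2).
#' @param base_coupling Mixing weight of each shared ROI-pair source, in
#'   [0, 1]; 0 makes all channels mutually independent.
#' @param coupling_sd Between-subject multiplicative jitter of each link's
#'   mixing weight: the weight is scaled by a truncated-normal multiplier
#'   `max(0.05, 1 + N(0, coupling_sd))`. This gives the groups a realistic
#'   subject-level spread of connectivity.
#' @param altered_links List of length-2 character vectors of ROI ids whose
#'   coupling is reduced in patients.
#' @param coupling_drop Fractional reduction of the altered links' weight in
#'   patients, in [0, 1].
#' @param lag_ms Lag (ms) applied to the shared source on the second ROI of
#'   each pair.
#' @param npv_spec Data frame describing the neuropsychological table (see
#'   [default_npv_spec()]).
#' @param seed Master RNG seed for the cohort.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_patients = 13, n_controls = 25,
                          montage_layout = "standard1020",
                          epochs_per_subject = 60, epoch_len_s = 2, fs = 256,
                          band = c(8, 20),
                          base_coupling = 0.5,
                          coupling_sd = 0.3,
                          altered_links = list(c("R1", "R5"), c("R2", "R3")),
                          coupling_drop = 0.55,
                          lag_ms = 16,
                          npv_spec = default_npv_spec(),
                          seed = 1L) {
  stopifnot(n_patients > 0, n_controls > 0, epochs_per_subject > 0,
            epoch_len_s > 0, fs > 0,
            coupling_drop >= 0, coupling_drop <= 1,
            base_coupling >= 0, base_coupling <= 1)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie inside (0, fs/2)")
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 montage_layout = montage_layout,
                 epochs_per_subject = epochs_per_subject,
                 epoch_len_s = epoch_len_s, fs = fs, band = band,
                 base_coupling = base_coupling, coupling_sd = coupling_sd,
                 altered_links = altered_links,
                 coupling_drop = coupling_drop, lag_ms = lag_ms,
                 npv_spec = npv_spec, seed = as.integer(seed)),
            class = "cohort_design")
}

# FFT-shaped noise: `n_series` independent columns of length n with power
# ~ 1/f within [f_lo, f_hi] (NULL bounds give broadband pink noise), each
# standardized to zero mean and unit variance.
shaped_noise <- function(n, fs, n_series = 1, f_lo = NULL, f_hi = NULL,
                         pink = TRUE) {
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  amp <- if (pink) 1 / sqrt(pmax(freqs, freqs[2])) else rep(1, length(freqs))
  if (!is.null(f_lo)) amp[freqs < f_lo] <- 0
  if (!is.null(f_hi)) amp[freqs > f_hi] <- 0
  amp[1] <- 0
  nf <- length(freqs)
  phase <- matrix(stats::runif(nf * n_series, 0, 2 * pi), nf)
  spec_half <- amp * exp(1i * phase)
  spec <- matrix(complex(real = 0), n, n_series)
  spec[1:nf, ] <- spec_half
  if (n %% 2 == 0) spec[nf, ] <- Re(spec_half[nf, ])
  if (nf > 2) spec[n:(n - nf + 3), ] <- Conj(spec_half[2:(nf - 1), ])
  x <- Re(stats::mvfft(spec, inverse = TRUE))
  standardize_cols(x)
}

standardize_cols <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

lag_series <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  c(x[(n - lag + 1):n], x[1:(n - lag)])  # circular shift, resting-state noise
}

#' Simulate one subject's epoched EEG
#'
#' @param design A [cohort_design()].
#' @param group `"patient"` or `"control"`.
#' @param subject_seed RNG seed for this subject.
#' @param subject_id Subject identifier.
#' @param montage Optional pre-built montage (defaults to the design layout).
#' @return An `epoched_eeg` object: `data` (channels x epochs x samples, uV),
#'   `fs`, `subject_id`.
#' @export
simulate_subject_eeg <- function(design, group = c("control", "patient"),
                                 subject_seed = design$seed,
                                 subject_id = "S01", montage = NULL) {
  group <- match.arg(group)
  if (is.null(montage)) montage <- build_montage(design$montage_layout)
  set.seed(subject_seed)
  n_ch <- length(montage$labels)
  n_ep <- design$epochs_per_subject
  n_s <- round(design$epoch_len_s * design$fs)
  n_tot <- n_ep * n_s
  lag <- max(1L, as.integer(round(design$lag_ms * design$fs / 1000)))
  b <- design$band

  altered <- canonical_links(design$altered_links)
  rois <- sort(unique(montage$roi))
  n_pairs <- if (design$base_coupling > 0 && length(rois) > 1)
    choose(length(rois), 2) else 0L

  # per-channel intrinsic activity: pink background + band-limited rhythm;
  # the channel rhythms and the per-ROI-pair latent sources share one FFT
  # batch (channel columns first, identical draws either way)
  pink <- shaped_noise(n_tot, design$fs, n_ch, pink = TRUE)
  band <- shaped_noise(n_tot, design$fs, n_ch + n_pairs, b[1], b[2],
                       pink = FALSE)
  sig <- t(pink) + 0.6 * t(band[, seq_len(n_ch), drop = FALSE])

  if (n_pairs > 0) {
    pairs <- utils::combn(rois, 2)
    sources <- band[, n_ch + seq_len(n_pairs), drop = FALSE]
    lagged <- standardize_cols(
      tanh(1.5 * apply(sources, 2, lag_series, lag = lag)))
    for (p in seq_len(ncol(pairs))) {
      ra <- pairs[1, p]; rb <- pairs[2, p]
      drop <- if (group == "patient" &&
                  paste(ra, rb, sep = "-") %in% altered)
        design$coupling_drop else 0
      w <- design$base_coupling * (1 - drop) *
        pmax(0.05, 1 + stats::rnorm(1, 0, design$coupling_sd))
      ia <- which(montage$roi == ra); ib <- which(montage$roi == rb)
      sig[ia, ] <- sig[ia, , drop = FALSE] +
        matrix(w * sources[, p], length(ia), n_tot, byrow = TRUE)
      sig[ib, ] <- sig[ib, , drop = FALSE] +
        matrix(w * lagged[, p], length(ib), n_tot, byrow = TRUE)
    }
  }

  # epoch the continuous record: ch x n_tot -> ch x epochs x samples
  data <- aperm(array(10 * sig, c(n_ch, n_s, n_ep)), c(1, 3, 2))
  dimnames(data) <- list(montage$labels, NULL, NULL)
  epoched_eeg(subject_id, data, design$fs)
}

#' Epoched EEG container
#'
#' @param subject_id Subject identifier.
#' @param data Numeric channels x epochs x samples array (uV); channel
#'   labels in `dimnames(data)[[1]]`.
#' @param fs Sampling rate (Hz).
#' @return An `epoched_eeg` object.
#' @export
epoched_eeg <- function(subject_id, data, fs) {
  stopifnot(length(dim(data)) == 3, all(is.finite(data)), fs > 0)
  structure(list(subject_id = subject_id, data = data, fs = fs),
            class = "epoched_eeg")
}

canonical_links <- function(links) {
  unique(vapply(links, function(l) paste(sort(l), collapse = "-"),
                character(1)))
}

#' Ground truth of injected connectivity alterations
#'
#' @param design A [cohort_design()].
#' @return Data frame of deduplicated altered ROI links with the injected
#'   effect direction (`"patient<control"` hypoconnectivity).
#' @export
ground_truth <- function(design) {
  links <- canonical_links(design$altered_links)
  if (!length(links))
    return(data.frame(roi_a = character(), roi_b = character(),
                      direction = character()))
  parts <- strsplit(links, "-", fixed = TRUE)
  data.frame(roi_a = vapply(parts, `[`, "", 1),
             roi_b = vapply(parts, `[`, "", 2),
             direction = "patient<control")
}

#' Default 19-variable neuropsychological table specification
#'
#' Global scores and subscores of three dementia-screening instruments
#' (global cognitive screen, frontal/executive screen, verbal learning test,
#' plus verbal fluencies), with control and patient means/SDs shaped like a
#' frontotemporal-dementia cohort and truncation bounds at each scale's
#' score range.
#'
#' @return Data frame with columns `variable`, `control_mean`, `control_sd`,
#'   `patient_mean`, `patient_sd`, `min`, `max` (19 rows).
#' @export
default_npv_spec <- function() {
  m <- rbind(
    c("ace_total",            92.17, 6.84, 70.77, 10.66, 0, 100),
    c("ace_attention",        17.5,  1.0,  14.0,  2.5,   0, 18),
    c("ace_memory",           23.0,  2.5,  15.0,  4.0,   0, 26),
    c("ace_fluency",          11.0,  1.8,  7.0,   2.5,   0, 14),
    c("ace_language",         25.0,  1.5,  22.0,  3.0,   0, 26),
    c("ace_visuospatial",     15.0,  1.5,  13.0,  2.5,   0, 16),
    c("ifs_total",            24.94, 2.25, 15.65, 4.39,  0, 30),
    c("ifs_motor_series",     2.7,   0.5,  1.8,   0.9,   0, 3),
    c("ifs_conflicting",      2.8,   0.4,  2.0,   0.9,   0, 3),
    c("ifs_go_no_go",         2.5,   0.6,  1.3,   1.0,   0, 3),
    c("ifs_backward_digits",  4.2,   1.0,  3.0,   1.2,   0, 7),
    c("ifs_verbal_wm",        3.5,   1.3,  2.2,   1.4,   0, 6),
    c("ifs_spatial_wm",       2.9,   0.8,  2.0,   1.0,   0, 4),
    c("ifs_abstraction",      2.4,   0.6,  1.4,   0.9,   0, 3),
    c("ifs_inhibitory",       5.4,   0.8,  3.6,   1.6,   0, 6),
    c("ravlt_immediate",      42.89, 10.07, 24.23, 8.87, 0, 75),
    c("ravlt_delayed",        7.28,  3.32, 3.69,  2.81,  0, 15),
    c("fluency_phonological", 16.0,  4.0,  10.0,  4.5,   0, 40),
    c("fluency_semantic",     18.0,  4.5,  11.0,  4.0,   0, 40))
  data.frame(variable = m[, 1],
             control_mean = as.numeric(m[, 2]),
             control_sd = as.numeric(m[, 3]),
             patient_mean = as.numeric(m[, 4]),
             patient_sd = as.numeric(m[, 5]),
             min = as.numeric(m[, 6]), max = as.numeric(m[, 7]),
             stringsAsFactors = FALSE)
}

simulate_npv <- function(npv_spec, groups, seed) {
  set.seed(seed)
  out <- lapply(seq_len(nrow(npv_spec)), function(i) {
    r <- npv_spec[i, ]
    mu <- ifelse(groups == "patient", r$patient_mean, r$control_mean)
    sd <- ifelse(groups == "patient", r$patient_sd, r$control_sd)
    pmin(pmax(stats::rnorm(length(groups), mu, sd), r$min), r$max)
  })
  names(out) <- npv_spec$variable
  as.data.frame(out)
}

#' Simulate a full two-group cohort
#'
#' Generates per-subject EEG and the neuropsychological table; retains the
#' design and the ground truth of altered links. Per-subject seeds are drawn
#' once from the design's master seed, so the cohort is fully reproducible
#' and subjects can be regenerated in isolation.
#'
#' @param design A [cohort_design()].
#' @param keep_eeg Keep the raw EEG arrays in the returned object (set
#'   `FALSE` to retain only connectivity matrices once computed).
#' @param symbol_params If non-NULL, a [symbol_params()] object: connectivity
#'   matrices are computed immediately and stored in `$connectivity`.
#' @return An `eeg_cohort` object: `subjects` (data frame with `subject`,
#'   `group`), `eeg` (list of `epoched_eeg`), `npv` (data frame), `montage`,
#'   `design`, `truth`.
#' @export
simulate_cohort <- function(design, keep_eeg = TRUE, symbol_params = NULL) {
  montage <- build_montage(design$montage_layout)
  n <- design$n_patients + design$n_controls
  groups <- c(rep("patient", design$n_patients),
              rep("control", design$n_controls))
  ids <- sprintf("S%03d", seq_len(n))
  set.seed(design$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  npv_seed <- sample.int(.Machine$integer.max - 1L, 1)
  eeg <- vector("list", n); names(eeg) <- ids
  conn <- vector("list", n); names(conn) <- ids
  for (i in seq_len(n)) {
    e <- simulate_subject_eeg(design, groups[i], subject_seeds[i], ids[i],
                              montage)
    if (!is.null(symbol_params)) conn[[i]] <- connectivity_matrix(e, symbol_params)
    if (keep_eeg) eeg[[i]] <- e
  }
  structure(list(subjects = data.frame(subject = ids, group = groups,
                                       stringsAsFactors = FALSE),
                 eeg = if (keep_eeg) eeg else NULL,
                 connectivity = if (!is.null(symbol_params)) conn else NULL,
                 npv = cbind(data.frame(subject = ids),
                             simulate_npv(design$npv_spec, groups, npv_seed)),
                 montage = montage, design = design,
                 truth = ground_truth(design)),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("<eeg_cohort>", nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "patient"), "patients /",
      sum(x$subjects$group == "control"), "controls ) on",
      length(x$montage$labels), "channels\n")
  invisible(x)
}

#' Compute and attach connectivity matrices for a cohort
#'
#' @param cohort An `eeg_cohort` with raw EEG.
#' @param params A [symbol_params()] object.
#' @return The cohort with `$connectivity` filled (list of matrices).
#' @export
compute_connectivity <- function(cohort,
                                 params = symbol_params(fs = cohort$design$fs)) {
  if (is.null(cohort$eeg)) stop("cohort holds no raw EEG")
  cohort$connectivity <- lapply(cohort$eeg, connectivity_matrix, params = params)
  cohort
}
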