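# Between-group inference: rank-sum tests with FDR correction on ROI-pair
# connectivity, Monte-Carlo permutation tests on distance profiles, the
# two-stage seed analysis, and demographic comparisons from printed summary
# statistics.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the total sample size is at most 12 and tie-free;
#' normal approximation with tie correction (no continuity correction)
#' otherwise. The sign is that of `W` minus its null expectation
#' `n_a * n_b / 2`, so a positive sign means the first group tends larger.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `W` (Mann-Whitney statistic of `a`), `sign`, `p`.
#' @export
ranksum_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  exact <- (length(a) + length(b)) <= 12 && !any(duplicated(c(a, b)))
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  W <- unname(res$statistic)
  list(W = W, sign = sign(W - length(a) * length(b) / 2),
       p = min(res$p.value, 1))
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up FDR control at level `q`.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask (empty input gives an empty mask).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Cohen's d with pooled SD
#'
#' `(mean(a) - mean(b))` divided by the pooled (n-1 weighted) standard
#' deviation. Undefined (NA with a warning) when the pooled SD is zero.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) {
    warning("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sp
}

cohort_groups <- function(cohort) {
  list(patient = cohort$subjects$subject[cohort$subjects$group == "patient"],
       control = cohort$subjects$subject[cohort$subjects$group == "control"])
}

cohort_conn <- function(cohort) {
  if (is.null(cohort$connectivity))
    stop("cohort has no connectivity matrices; run compute_connectivity()")
  cohort$connectivity
}

#' Between-group comparison of all ROI-pair connectivities
#'
#' Rank-sum test per unordered ROI pair across subjects, BH-FDR corrected,
#' with group summaries and Cohen's d. Positive sign and positive d mean
#' controls above patients (hypoconnectivity in patients).
#'
#' @param cohort An `eeg_cohort` with connectivity matrices.
#' @param q FDR level.
#' @return Data frame with one row per ROI pair: `pair`, `mean_patient`,
#'   `sd_patient`, `mean_control`, `sd_control`, `W`, `sign`, `p`, `p_adj`,
#'   `fdr_sig`, `cohens_d`.
#' @export
roi_pair_comparison <- function(cohort, q = 0.05) {
  conn <- cohort_conn(cohort)
  grp <- cohort_groups(cohort)
  if (length(grp$patient) < 2 || length(grp$control) < 2)
    stop("each group needs >= 2 subjects")
  vals <- t(vapply(conn, roi_pair_means, m = cohort$montage,
                   numeric(length(roi_pair_names(cohort$montage)))))
  pairs <- colnames(vals)
  rows <- lapply(pairs, function(pr) {
    pa <- vals[grp$patient, pr]; co <- vals[grp$control, pr]
    rs <- ranksum_test(co, pa)
    data.frame(pair = pr,
               mean_patient = mean(pa), sd_patient = stats::sd(pa),
               mean_control = mean(co), sd_control = stats::sd(co),
               W = rs$W, sign = rs$sign, p = rs$p,
               cohens_d = cohens_d(co, pa))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$fdr_sig <- fdr_bh(out$p, q)
  out
}

#' Monte-Carlo permutation test on distance profiles
#'
#' Per distance bin, the statistic is the absolute difference of group mean
#' connectivities; the null is built by shuffling group labels across
#' subjects (every bin shares each shuffle), with the add-one estimator
#' `p = (exceedances + 1) / (n_perm + 1)`.
#'
#' @param profiles_a,profiles_b Subjects x bins matrices of per-subject
#'   per-bin mean connectivity (same bins, e.g. stacked `mean` columns of
#'   [distance_profile()]).
#' @param n_perm Number of label permutations (>= 100; default 5000).
#' @param seed RNG seed.
#' @return Data frame per bin: `bin`, `observed` (group a minus group b),
#'   `p`.
#' @export
permutation_profile_test <- function(profiles_a, profiles_b, n_perm = 5000,
                                     seed = 1L) {
  profiles_a <- rbind(profiles_a); profiles_b <- rbind(profiles_b)
  if (ncol(profiles_a) != ncol(profiles_b))
    stop("groups have different bins")
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  n_a <- nrow(profiles_a)
  x <- rbind(profiles_a, profiles_b)
  n <- nrow(x)
  ok <- colSums(is.na(x)) == 0  # bins empty for some subject stay NA
  obs_diff <- colMeans(profiles_a) - colMeans(profiles_b)
  obs <- abs(obs_diff)
  exceed <- numeric(ncol(x))
  xs <- x[, ok, drop = FALSE]
  # canonical row order and resampling of the smaller group: the permutation
  # null then depends only on the pooled sample, so swapping the two groups
  # (same seed) yields identical p-values
  xs <- xs[do.call(order, as.data.frame(xs)), , drop = FALSE]
  n_draw <- min(n_a, n - n_a)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, n_draw)
    stat <- abs(colMeans(xs[idx, , drop = FALSE]) -
                  colMeans(xs[-idx, , drop = FALSE]))
    exceed[ok] <- exceed[ok] + (stat >= obs[ok])
  }
  p <- (exceed + 1) / (n_perm + 1)
  p[!ok] <- NA_real_
  data.frame(bin = seq_len(ncol(x)), observed = obs_diff, p = p)
}

#' Distance-profile matrices per group
#'
#' Convenience builder: per-subject [distance_profile()] means stacked into
#' subjects x bins matrices for each group.
#'
#' @param cohort An `eeg_cohort` with connectivity matrices.
#' @param roi Seed ROI id.
#' @param bins Bins as in [distance_profile()].
#' @return List with `patient` and `control` matrices and `bins`.
#' @export
group_distance_profiles <- function(cohort, roi,
                                    bins = tertile_bins(max(distance_matrix(cohort$montage)))) {
  conn <- cohort_conn(cohort)
  grp <- cohort_groups(cohort)
  m <- cohort$montage
  inside <- m$labels[m$roi == roi]
  if (!length(inside)) stop("ROI ", roi, " is empty")
  outside <- setdiff(m$labels, inside)
  grid <- expand.grid(a = inside, b = outside, stringsAsFactors = FALSE)
  idx <- cbind(grid$a, grid$b)
  d <- distance_matrix(m)[idx]
  iv <- bins_to_intervals(bins)
  n_b <- nrow(iv)
  # connection-by-bin membership, computed once for all subjects
  memb <- vapply(seq_len(n_b), function(i) {
    d >= iv$lo[i] & (if (i == n_b) d <= iv$hi[i] else d < iv$hi[i])
  }, logical(length(d))) * 1
  counts <- colSums(memb)
  prof <- function(ids) t(vapply(conn[ids], function(cm) {
    out <- as.vector(crossprod(memb, cm[idx])) / counts
    out[counts == 0] <- NA_real_
    out
  }, numeric(n_b)))
  list(patient = prof(grp$patient), control = prof(grp$control), bins = bins)
}

#' Seed analysis: per-external-electrode summaries of seed connections
#'
#' Every electrode of the seed set is framed as a seed; each connection from
#' a seed to an ROI-external electrode is tested with a rank-sum test
#' (controls vs patients, so a positive sign means hypoconnectivity in
#' patients). Per external electrode the map reports the median of the raw
#' p-values over seeds, the signed score `-log10(median p) * sign` (sign of
#' the median of `W` minus its null expectation across seeds; scores beyond
#' +/-1.3 correspond to median p < 0.05), and the number of FDR-significant
#' seed connections (BH over all seed x external connections of this seed
#' set).
#'
#' @param cohort An `eeg_cohort` with connectivity matrices.
#' @param seeds Character vector of ROI ids, or a named list of electrode
#'   sets to use as seeds.
#' @param q FDR level for the connection-count map.
#' @return Named list of `seed_map` data frames (`electrode`, `median_p`,
#'   `score`, `n_fdr_sig`), with the seed electrodes as attribute `"seeds"`.
#' @export
seed_analysis <- function(cohort, seeds = c("R1", "R2"), q = 0.05) {
  conn <- cohort_conn(cohort)
  grp <- cohort_groups(cohort)
  m <- cohort$montage
  if (is.character(seeds)) {
    seed_sets <- lapply(seeds, roi_electrodes, m = m)
    names(seed_sets) <- seeds
  } else seed_sets <- seeds
  arr <- simplify2array(conn)  # ch x ch x subject
  pat <- match(grp$patient, cohort$subjects$subject)
  con_i <- match(grp$control, cohort$subjects$subject)
  lapply(seed_sets, function(seed_el) {
    externals <- setdiff(m$labels, seed_el)
    if (!length(externals)) stop("no ROI-external electrodes")
    pmat <- matrix(NA_real_, length(seed_el), length(externals),
                   dimnames = list(seed_el, externals))
    smat <- pmat
    for (s in seed_el) for (e in externals) {
      rs <- ranksum_test(arr[s, e, con_i], arr[s, e, pat])
      pmat[s, e] <- rs$p
      smat[s, e] <- rs$W - length(con_i) * length(pat) / 2
    }
    rej <- matrix(fdr_bh(as.vector(pmat), q), nrow(pmat))
    med_p <- apply(pmat, 2, stats::median)
    sgn <- sign(apply(smat, 2, stats::median))
    out <- data.frame(electrode = externals,
                      median_p = med_p,
                      score = -log10(med_p) * sgn,
                      n_fdr_sig = colSums(rej))
    rownames(out) <- NULL
    attr(out, "seeds") <- seed_el
    class(out) <- c("seed_map", class(out))
    out
  })
}

#' Significance threshold of the seed-map score scale
#'
#' Scores beyond this value (in absolute terms) correspond to a median
#' p-value below 0.05.
#'
#' @return `-log10(0.05)`, about 1.3.
#' @export
seed_score_threshold <- function() -log10(0.05)

#' Second-stage seed analysis
#'
#' Averages the left and right frontal stage-1 seed maps per shared external
#' electrode, finds the ROIs containing significant hypoconnectivity scores
#' (above `threshold`), selects the `top_n` highest-scoring electrodes of
#' each such ROI as new seeds (ties broken by channel label order), re-runs
#' the seed analysis with the new seed sets, and groups the significant
#' external electrodes that fall in the original frontal ROIs into derived
#' "new left frontal" / "new right frontal" ROIs.
#'
#' @param cohort An `eeg_cohort` with connectivity matrices.
#' @param stage1 Output of `seed_analysis(cohort, c("R1", "R2"))` (named
#'   list with elements `R1` and `R2`).
#' @param top_n Electrodes selected per significant region.
#' @param threshold Seed-map score threshold (default `-log10(0.05)`).
#' @param q FDR level passed to the stage-2 seed analysis.
#' @return List: `avg_scores` (named vector over shared externals),
#'   `significant_rois`, `new_seeds` (named list of electrode sets),
#'   `stage2_maps`, `derived_rois` (list `new_left_frontal`,
#'   `new_right_frontal`), `any_significant`.
#' @export
second_stage_seeds <- function(cohort, stage1, top_n = 5,
                               threshold = seed_score_threshold(), q = 0.05) {
  m <- cohort$montage
  shared <- intersect(stage1$R1$electrode, stage1$R2$electrode)
  avg <- (stage1$R1$score[match(shared, stage1$R1$electrode)] +
            stage1$R2$score[match(shared, stage1$R2$electrode)]) / 2
  names(avg) <- shared
  cand_rois <- setdiff(sort(unique(m$roi)), c("R1", "R2"))
  sig_rois <- cand_rois[vapply(cand_rois, function(r) {
    el <- intersect(shared, m$labels[m$roi == r])
    length(el) > 0 && any(avg[el] > threshold)
  }, logical(1))]
  if (!length(sig_rois)) {
    return(list(avg_scores = avg, significant_rois = character(),
                new_seeds = list(), stage2_maps = list(),
                derived_rois = list(new_left_frontal = character(),
                                    new_right_frontal = character()),
                any_significant = FALSE))
  }
  new_seeds <- lapply(sig_rois, function(r) {
    el <- intersect(shared, m$labels[m$roi == r])
    el[order(-avg[el], el)][seq_len(min(top_n, length(el)))]
  })
  names(new_seeds) <- paste0("seed_", sig_rois)
  maps <- seed_analysis(cohort, new_seeds, q = q)
  sig_ext <- unique(unlist(lapply(maps, function(mp)
    mp$electrode[mp$score > threshold])))
  list(avg_scores = avg, significant_rois = sig_rois, new_seeds = new_seeds,
       stage2_maps = maps,
       derived_rois = list(
         new_left_frontal = sort(intersect(sig_ext, m$labels[m$roi == "R1"])),
         new_right_frontal = sort(intersect(sig_ext, m$labels[m$roi == "R2"]))),
       any_significant = TRUE)
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Student t with pooled variance and `n1 + n2 - 2` degrees of freedom,
#' two-sided.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @return List with `t`, `df`, `p`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("negative SD")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means; test degenerate")
    return(list(t = Inf * sign(mean1 - mean2), df = df, p = 0))
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' No continuity correction; 1 degree of freedom.
#'
#' @param table 2x2 matrix of nonnegative counts with no zero margins.
#' @return List with `chi2`, `p`.
#' @export
chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("table must be 2x2")
  if (any(table < 0) || any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table must have nonnegative counts and no zero margins")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), p = res$p.value)
}

#' Group comparisons from a demographic/neuropsychological summary table
#'
#' Applies the pooled-variance t-test to continuous rows and the Pearson
#' chi-squared test to categorical (sex) rows, as is standard for published
#' "Table 1" summaries.
#'
#' @param summary_table Data frame with columns `variable`, `type`
#'   (`"continuous"` or `"categorical"`), `g1_mean`, `g1_sd`, `g1_n`,
#'   `g2_mean`, `g2_sd`, `g2_n` for continuous rows and `g1_x`, `g1_y`,
#'   `g2_x`, `g2_y` (2x2 counts) for categorical rows.
#' @return Data frame: `variable`, `statistic`, `df`, `p`.
#' @export
compare_demographics <- function(summary_table) {
  if (!nrow(summary_table))
    return(data.frame(variable = character(), statistic = numeric(),
                      df = numeric(), p = numeric()))
  rows <- lapply(seq_len(nrow(summary_table)), function(i) {
    r <- summary_table[i, ]
    if (identical(r$type, "continuous")) {
      res <- summary_ttest(r$g1_mean, r$g1_sd, r$g1_n,
                           r$g2_mean, r$g2_sd, r$g2_n)
      data.frame(variable = r$variable, statistic = res$t, df = res$df,
                 p = res$p)
    } else if (identical(r$type, "categorical")) {
      res <- chisq_2x2(matrix(c(r$g1_x, r$g1_y, r$g2_x, r$g2_y), 2,
                              byrow = TRUE))
      data.frame(variable = r$variable, statistic = res$chi2, df = 1,
                 p = res$p)
    } else stop("row ", i, " (", r$variable, "): unknown type '", r$type, "'")
  })
  do.call(rbind, rows)
}

#' Bundled demographic summary table
#'
#' Reference group summary statistics (means, SDs, group sizes and sex
#' counts) for a frontotemporal-dementia cohort and its Alzheimer's
#' disease-control arm, as shipped in `inst/extdata/`.
#'
#' @param arm `"bvftd"` (patients vs matched controls) or `"ad"` (disease
#'   control arm).
#' @return Summary table in the format of [compare_demographics()].
#' @export
demographics_table <- function(arm = c("bvftd", "ad")) {
  arm <- match.arg(arm)
  path <- system.file("extdata", "table1_demographics.csv",
                      package = "eegshare", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab[tab$arm == arm, setdiff(names(tab), "arm")]
}
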