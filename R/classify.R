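# Connectivity/neuropsychological feature construction, repeated-holdout
# linear SVM classification, Hotelling's T2 model comparison, and ROC/AUC.

#' Feature specification for classification
#'
#' Defines the six connectivity variables (CNVs): two distance-range means
#' anchored on the frontal ROIs and four electrode-set pair means linking
#' the derived frontal seed sets to the parietal/temporal hub sets; plus the
#' neuropsychological columns (NPVs) to use.
#'
#' @param range_features List of `list(roi=, d_min=, d_max=, name=)` entries
#'   evaluated with [range_mean()].
#' @param set_features List of `list(set_a=, set_b=, name=)` entries
#'   evaluated with [set_pair_mean()].
#' @param npv_columns Character vector of neuropsychological column names.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(range_features = list(), set_features = list(),
                         npv_columns = character()) {
  structure(list(range_features = range_features,
                 set_features = set_features,
                 npv_columns = npv_columns),
            class = "feature_spec")
}

#' Per-subject feature table
#'
#' @param cohort An `eeg_cohort` (with connectivity matrices when CNVs are
#'   requested).
#' @param spec A [feature_spec()].
#' @param mode `"NPV"`, `"CNV"` or `"BOTH"`.
#' @return List with `x` (subjects x features numeric matrix) and `labels`
#'   (factor with levels control, patient).
#' @export
build_features <- function(cohort, spec, mode = c("BOTH", "NPV", "CNV")) {
  mode <- match.arg(mode)
  ids <- cohort$subjects$subject
  cols <- list()
  if (mode %in% c("CNV", "BOTH")) {
    conn <- cohort_conn(cohort)
    for (rf in spec$range_features) {
      cols[[rf$name]] <- vapply(conn[ids], function(cm)
        range_mean(cm, cohort$montage, rf$roi, rf$d_min, rf$d_max),
        numeric(1))
    }
    for (sf in spec$set_features) {
      cols[[sf$name]] <- vapply(conn[ids], function(cm)
        set_pair_mean(cm, sf$set_a, sf$set_b), numeric(1))
    }
  }
  if (mode %in% c("NPV", "BOTH")) {
    missing <- setdiff(spec$npv_columns, names(cohort$npv))
    if (length(missing))
      stop("NPV column(s) not in cohort table: ",
           paste(missing, collapse = ", "))
    for (v in spec$npv_columns)
      cols[[v]] <- cohort$npv[[v]][match(ids, cohort$npv$subject)]
  }
  if (!length(cols)) stop("feature specification yields no features")
  x <- do.call(cbind, cols)
  rownames(x) <- ids
  list(x = x,
       labels = factor(cohort$subjects$group, levels = c("control", "patient")))
}

#' Repeated-holdout linear SVM classification
#'
#' Per repeat: draw `n_train_per_group` subjects from each group for
#' training, z-score all features by the training statistics, fit a
#' linear-kernel SVM (cost `cost`), and classify the held-out subjects.
#' Sensitivity is the correctly classified patient fraction and specificity
#' the control fraction of each test set; decision scores are pooled across
#' repeats (oriented so higher means more patient-like) for ROC analysis.
#'
#' @param x Subjects x features numeric matrix.
#' @param labels Factor with levels `control`, `patient`.
#' @param n_train_per_group Training subjects drawn per group (default 7).
#' @param n_repeats Number of repeats (default 1000).
#' @param seed RNG seed.
#' @param cost SVM cost parameter.
#' @return A `classification_report`: `per_repeat` data frame (sensitivity,
#'   specificity, accuracy, balanced_accuracy), `scores` (pooled test-set
#'   decision scores with labels), `summary` (means and SDs), and
#'   `classification_rate` (mean balanced accuracy).
#' @export
svm_repeated_holdout <- function(x, labels, n_train_per_group = 7,
                                 n_repeats = 1000, seed = 1L, cost = 1) {
  labels <- factor(labels, levels = c("control", "patient"))
  idx_pat <- which(labels == "patient")
  idx_con <- which(labels == "control")
  if (length(idx_pat) <= n_train_per_group ||
      length(idx_con) <= n_train_per_group)
    stop("each group must have more than n_train_per_group subjects")
  set.seed(seed)
  per <- matrix(NA_real_, n_repeats, 4,
                dimnames = list(NULL, c("sensitivity", "specificity",
                                        "accuracy", "balanced_accuracy")))
  scores <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    tr <- c(sample(idx_pat, n_train_per_group),
            sample(idx_con, n_train_per_group))
    te <- setdiff(seq_along(labels), tr)
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- e1071::svm(xtr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, xte, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # orient decision values so larger = more patient-like
    if (grepl("^control/", colnames(attr(pred, "decision.values"))[1]))
      dv <- -dv
    truth <- labels[te]
    sens <- mean(pred[truth == "patient"] == "patient")
    spec <- mean(pred[truth == "control"] == "control")
    per[r, ] <- c(sens, spec, mean(pred == truth), (sens + spec) / 2)
    scores[[r]] <- data.frame(score = dv, label = truth)
  }
  per <- as.data.frame(per)
  structure(list(per_repeat = per,
                 scores = do.call(rbind, scores),
                 summary = data.frame(
                   metric = colnames(per),
                   mean = colMeans(per),
                   sd = apply(per, 2, stats::sd), row.names = NULL),
                 classification_rate = mean(per$balanced_accuracy),
                 n_repeats = n_repeats,
                 n_train_per_group = n_train_per_group),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>", x$n_repeats, "repeats;",
      sprintf("sensitivity %.3f (SD %.3f), specificity %.3f (SD %.3f), rate %.3f\n",
              x$summary$mean[1], x$summary$sd[1],
              x$summary$mean[2], x$summary$sd[2], x$classification_rate))
  invisible(x)
}

#' ROC curve and AUC from pooled decision scores
#'
#' ROC over the pooled test-subject decision scores of all repeats, with a
#' fixed orientation (higher score means patient), so a reversed ranking
#' yields AUC 0 rather than being flipped.
#'
#' @param report A `classification_report`, or a data frame with `score` and
#'   `label` columns.
#' @return List with `curve` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(report) {
  sc <- if (inherits(report, "classification_report")) report$scores else report
  if (length(unique(sc$label)) < 2)
    stop("pooled scores contain a single class")
  r <- pROC::roc(response = sc$label, predictor = sc$score,
                 levels = c("control", "patient"), direction = "<",
                 quiet = TRUE)
  list(curve = data.frame(fpr = 1 - r$specificities,
                          tpr = r$sensitivities),
       auc = as.numeric(r$auc))
}

#' Two-sample Hotelling's T-squared test
#'
#' Compares the mean vectors of two independent multivariate samples (here,
#' per-repeat (sensitivity, specificity) pairs of two classification
#' models) with the F approximation.
#'
#' @param a,b Numeric matrices (observations x variables, same number of
#'   variables >= 2, each with at least 3 observations).
#' @return List with `T2`, `F`, `df1`, `df2`, `p`.
#' @export
hotelling_t2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  p <- ncol(a)
  if (p < 2 || ncol(b) != p) stop("need >= 2 matching variables")
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 3 || n2 < 3) stop("each sample needs >= 3 observations")
  d <- colMeans(a) - colMeans(b)
  s <- ((n1 - 1) * stats::cov(a) + (n2 - 1) * stats::cov(b)) / (n1 + n2 - 2)
  si <- tryCatch(solve(s), error = function(e) NULL)
  if (is.null(si)) {
    warning("singular pooled covariance; test degenerate")
    return(list(T2 = NA_real_, F = NA_real_, df1 = p,
                df2 = n1 + n2 - p - 1, p = NA_real_))
  }
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% si %*% d)
  df1 <- p; df2 <- n1 + n2 - p - 1
  f <- t2 * df2 / ((n1 + n2 - 2) * p)
  list(T2 = t2, F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
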