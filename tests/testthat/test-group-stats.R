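test_that("rank-sum test matches exact enumeration for small samples", {
  r <- ranksum_test(c(1, 2), c(3, 4))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$sign, -1)
  r2 <- ranksum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r2$p, 0.1, tolerance = 1e-12)  # 2 / C(6,3)
  # identical multisets: sign 0, p = 1
  r3 <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$sign, 0)
  expect_equal(r3$p, 1)
  expect_error(ranksum_test(numeric(0), 1:3), ">= 2")
})

test_that("exact rank-sum p-values match full enumeration for n <= 10", {
  enum_p <- function(a, b) {
    pool <- c(a, b); n <- length(pool); na <- length(a)
    obs <- sum(rank(pool)[seq_len(na)]) - na * (na + 1) / 2
    mu <- na * length(b) / 2
    combs <- utils::combn(n, na)
    stats <- apply(combs, 2, function(idx)
      sum(rank(pool)[idx]) - na * (na + 1) / 2)
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(11)
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- sample(1000, na + nb)  # tie-free
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(ranksum_test(a, b)$p, enum_p(a, b), tolerance = 1e-9)
  }
})

test_that("BH-FDR matches a brute-force step-up implementation", {
  brute_bh <- function(p, q) {
    n <- length(p)
    o <- order(p)
    k <- max(c(0, which(p[o] <= seq_len(n) * q / n)))
    rej <- logical(n)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(fdr_bh(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(fdr_bh(0.049, 0.05), TRUE)
  expect_length(fdr_bh(numeric(0)), 0)
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p, 0.05), brute_bh(p, 0.05))
  }
})

test_that("Cohen's d uses the pooled n-1 weighted SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)  # pooled SD 1
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_warning(expect_true(is.na(cohens_d(c(1, 1), c(2, 2)))), "pooled")
})

test_that("summary t-test reproduces the published demographic p-values", {
  # patient arm: age 0.67, education 0.10, delayed recall 0.002
  expect_equal(round(summary_ttest(69.31, 10.55, 13, 70.40, 5.22, 25)$p, 2),
               0.67)
  expect_equal(round(summary_ttest(15, 3.34, 13, 16.96, 3.47, 25)$p, 2), 0.10)
  expect_equal(round(summary_ttest(3.69, 2.81, 13, 7.28, 3.32, 25)$p, 3),
               0.002)
  # disease-control arm: age 0.20
  expect_equal(round(summary_ttest(75.62, 9.42, 13, 72.28, 4.42, 18)$p, 2),
               0.20)
  r <- summary_ttest(5, 1, 10, 5, 1, 10)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(summary_ttest(1, 0, 5, 1, 0, 5)$p, 1)
})

test_that("2x2 chi-squared matches the published sex comparisons and hand formula", {
  expect_equal(round(chisq_2x2(matrix(c(11, 2, 12, 6), 2, byrow = TRUE))$p, 2),
               0.26)
  # patient-arm sex split: p = 0.7155 (published rounding prints 0.71)
  expect_equal(chisq_2x2(matrix(c(7, 6, 15, 10), 2, byrow = TRUE))$p, 0.7155,
               tolerance = 1e-4)
  prop <- chisq_2x2(matrix(c(10, 10, 20, 20), 2, byrow = TRUE))
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  h <- chisq_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(h$chi2, 10)
  expect_equal(round(h$p, 5), 0.00157)
  expect_error(chisq_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("compare_demographics handles the bundled arms and degenerate input", {
  bv <- compare_demographics(demographics_table("bvftd"))
  expect_equal(round(bv$p[bv$variable == "age"], 2), 0.67)
  expect_equal(round(bv$p[bv$variable == "education"], 2), 0.10)
  expect_equal(round(bv$p[bv$variable == "ravlt_delayed"], 3), 0.002)
  expect_equal(bv$p[bv$variable == "sex"], 0.7155, tolerance = 1e-4)
  ad <- compare_demographics(demographics_table("ad"))
  expect_equal(round(ad$p[ad$variable == "age"], 2), 0.20)
  expect_equal(round(ad$p[ad$variable == "sex"], 2), 0.26)
  expect_equal(nrow(compare_demographics(demographics_table("ad")[0, ])), 0)
})

test_that("permutation profile test: floor, symmetry, and monotone invariance", {
  set.seed(13)
  a <- matrix(rnorm(10 * 3), 10)
  b <- matrix(rnorm(12 * 3), 12)
  expect_error(permutation_profile_test(a, b, n_perm = 50), "100")
  # huge separation hits the add-one floor 1/(n_perm+1)
  r <- permutation_profile_test(a + 100, b, n_perm = 200, seed = 1)
  expect_equal(r$p, rep(1 / 201, 3))
  # two-sided symmetry: swapping groups gives identical p
  r1 <- permutation_profile_test(a, b, n_perm = 300, seed = 2)
  r2 <- permutation_profile_test(b, a, n_perm = 300, seed = 2)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$observed, -r2$observed)
  # order-preserving bin-wise affine transform preserves p
  sc <- c(2, 0.5, 7)
  r3 <- permutation_profile_test(sweep(a, 2, sc, "*"),
                                 sweep(b, 2, sc, "*"), n_perm = 300, seed = 2)
  expect_equal(r3$p, r1$p)
})

test_that("roi_pair_comparison flags injected hypoconnectivity in a toy cohort", {
  m <- build_montage("standard1020")
  set.seed(14)
  n_pair <- choose(20, 2)
  make_cm <- function(drop) {
    v <- 0.06 + rnorm(n_pair, 0, 0.002)
    cm <- toy_cm(m$labels, v)
    if (drop > 0) {
      sel_a <- m$labels[m$roi == "R2"]; sel_b <- m$labels[m$roi == "R3"]
      cm[sel_a, sel_b] <- cm[sel_a, sel_b] - drop
      cm[sel_b, sel_a] <- t(cm[sel_a, sel_b])
    }
    cm
  }
  cms <- c(lapply(1:8, function(i) make_cm(0.02)),
           lapply(1:10, function(i) make_cm(0)))
  co <- cm_cohort(cms, rep(c("patient", "control"), c(8, 10)), m)
  res <- roi_pair_comparison(co)
  expect_equal(nrow(res), 21)
  expect_true(res$fdr_sig[res$pair == "R2-R3"])
  expect_gt(res$cohens_d[res$pair == "R2-R3"], 0)  # controls > patients
  expect_equal(sum(res$fdr_sig), 1)
  expect_error(roi_pair_comparison(cm_cohort(cms[1:3],
                                             c("patient", "control", "control"),
                                             m)),
               ">= 2")
})

test_that("seed analysis summarizes per-external-electrode statistics", {
  m <- build_montage("standard1020")
  set.seed(15)
  n_pair <- choose(20, 2)
  # patients lose connectivity from R1 seeds to T7 only
  make_cm <- function(patient) {
    cm <- toy_cm(m$labels, 0.06 + rnorm(n_pair, 0, 0.002))
    if (patient) {
      r1 <- m$labels[m$roi == "R1"]
      cm[r1, "T7"] <- cm[r1, "T7"] - 0.03
      cm["T7", r1] <- cm[r1, "T7"]
    }
    cm
  }
  cms <- c(lapply(1:10, function(i) make_cm(TRUE)),
           lapply(1:12, function(i) make_cm(FALSE)))
  co <- cm_cohort(cms, rep(c("patient", "control"), c(10, 12)), m)
  maps <- seed_analysis(co, "R1")
  mp <- maps$R1
  expect_equal(nrow(mp), 17)  # 20 - 3 seed electrodes
  expect_equal(attr(mp, "seeds"), m$labels[m$roi == "R1"])
  t7 <- mp[mp$electrode == "T7", ]
  expect_gt(t7$score, seed_score_threshold())   # hypoconnectivity: positive
  expect_equal(t7$n_fdr_sig, 3)                 # all three seed connections
  expect_lt(max(abs(mp$score[mp$electrode != "T7"])), seed_score_threshold())
  # score crosses +/- 1.3 iff median p < 0.05
  expect_equal(mp$score > 1.3 | mp$score < -1.3, mp$median_p < 0.05)
})

test_that("seed-map sign convention: patients above controls maps negative", {
  m <- build_montage("standard1020")
  set.seed(16)
  n_pair <- choose(20, 2)
  cms <- c(lapply(1:8, function(i) toy_cm(m$labels, 0.08 + rnorm(n_pair, 0, 0.001))),
           lapply(1:8, function(i) toy_cm(m$labels, 0.06 + rnorm(n_pair, 0, 0.001))))
  co <- cm_cohort(cms, rep(c("patient", "control"), each = 8), m)
  mp <- seed_analysis(co, "R1")$R1
  expect_true(all(mp$score < 0))
})

test_that("second-stage seed selection picks top electrodes deterministically", {
  m <- build_montage("standard1020")
  set.seed(17)
  n_pair <- choose(20, 2)
  # patients lose connectivity from both frontal ROIs to all of R5
  make_cm <- function(patient) {
    cm <- toy_cm(m$labels, 0.06 + rnorm(n_pair, 0, 0.002))
    if (patient) {
      fr <- m$labels[m$roi %in% c("R1", "R2")]
      r5 <- m$labels[m$roi == "R5"]
      cm[fr, r5] <- cm[fr, r5] - 0.03
      cm[r5, fr] <- t(cm[fr, r5])
    }
    cm
  }
  cms <- c(lapply(1:10, function(i) make_cm(TRUE)),
           lapply(1:12, function(i) make_cm(FALSE)))
  co <- cm_cohort(cms, rep(c("patient", "control"), c(10, 12)), m)
  s1 <- seed_analysis(co, c("R1", "R2"))
  s2 <- second_stage_seeds(co, s1, top_n = 2)
  expect_true(s2$any_significant)
  expect_true("R5" %in% s2$significant_rois)
  expect_length(s2$new_seeds$seed_R5, 2)
  expect_true(all(s2$new_seeds$seed_R5 %in% m$labels[m$roi == "R5"]))
  # derived ROIs live inside the frontal ROIs
  expect_true(all(s2$derived_rois$new_left_frontal %in%
                    m$labels[m$roi == "R1"]))
  expect_true(all(s2$derived_rois$new_right_frontal %in%
                    m$labels[m$roi == "R2"]))
  # null cohort: no significant region, flagged empty result
  set.seed(18)
  cms0 <- lapply(1:20, function(i) toy_cm(m$labels, 0.06 + rnorm(n_pair, 0, 0.002)))
  co0 <- cm_cohort(cms0, rep(c("patient", "control"), each = 10), m)
  s20 <- second_stage_seeds(co0, seed_analysis(co0, c("R1", "R2")))
  expect_false(s20$any_significant)
  expect_length(s20$new_seeds, 0)
})

test_that("tie at the selection boundary breaks by channel label order", {
  m <- build_montage("standard1020")
  set.seed(19)
  cms <- lapply(1:8, function(i) toy_cm(m$labels, runif(choose(20, 2))))
  co <- cm_cohort(cms, rep(c("patient", "control"), each = 4), m)
  # hand-built stage-1 maps: R5 electrodes P3, O1 tied at the top, P7 lower
  fake_map <- function(seed_roi) {
    ext <- setdiff(m$labels, m$labels[m$roi == seed_roi])
    score <- rep(0.1, length(ext))
    names(score) <- ext
    score[c("P3", "O1", "P7")] <- c(2, 2, 1.8)
    out <- data.frame(electrode = ext, median_p = 10^(-score), score = score,
                      n_fdr_sig = 0L)
    attr(out, "seeds") <- m$labels[m$roi == seed_roi]
    out
  }
  s2 <- second_stage_seeds(co, list(R1 = fake_map("R1"), R2 = fake_map("R2")),
                           top_n = 2)
  # O1 before P3 alphabetically at the tied rank; P7 excluded
  expect_equal(s2$new_seeds$seed_R5, c("O1", "P3"))
})
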