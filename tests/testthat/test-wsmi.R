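params_tau1 <- symbol_params(k = 3, tau_ms = 4, fs = 250)   # tau = 1 sample

test_that("symbolization encodes argsort permutations with stable ties", {
  # strictly increasing signal: always the identity pattern (code 0)
  expect_equal(symbolize(1:10, params_tau1), rep(0L, 8))
  # hand enumeration: (1,3,2,5,4,6) -> (0,2,1),(1,0,2),(0,2,1),(1,0,2)
  expect_equal(symbolize(c(1, 3, 2, 5, 4, 6), params_tau1),
               c(1L, 2L, 1L, 2L))
  # constant signal: stable tie-breaking gives the identity pattern
  expect_equal(symbolize(rep(7, 6), params_tau1), rep(0L, 4))
  expect_error(symbolize(c(1, 2), params_tau1), "too short")
})

test_that("symbolization respects tau spacing and matches a general-k oracle", {
  set.seed(1)
  x <- rnorm(50)
  for (tau in c(2L, 5L)) {
    p <- symbol_params(k = 3, tau_ms = tau * 1000 / 256, fs = 256)
    expect_equal(p$tau_samples, tau)
    got <- symbolize(x, p)
    # oracle: explicit order() per window
    n_sym <- length(x) - 2 * tau
    ref <- vapply(seq_len(n_sym), function(t) {
      w <- x[c(t, t + tau, t + 2 * tau)]
      eegshare:::perm_to_code(order(w) - 1L)
    }, integer(1))
    expect_identical(got, ref)
  }
})

test_that("the vectorized array symbolizer agrees with per-epoch symbolize", {
  set.seed(2)
  data <- array(rnorm(3 * 4 * 40), dim = c(3, 4, 40),
                dimnames = list(c("a", "b", "c"), NULL, NULL))
  p <- symbol_params(k = 3, tau_ms = 3 * 1000 / 256, fs = 256)
  sym <- eegshare:::symbolize_array(data, p)
  n_sym <- 40 - 2 * p$tau_samples
  for (ch in 1:3) for (ep in 1:4) {
    expect_identical(sym[ch, ((ep - 1) * n_sym + 1):(ep * n_sym)],
                     symbolize(data[ch, ep, ], p))
  }
})

test_that("mirror_symbol reverses patterns and is an involution", {
  expect_equal(mirror_symbol(0L, 3), 5L)          # (0,1,2) -> (2,1,0)
  expect_equal(mirror_symbol(1L, 3), 3L)          # (0,2,1) -> (1,2,0)
  expect_equal(mirror_symbol(mirror_symbol(0:5, 3), 3), 0:5)
  for (k in c(2, 4)) {
    codes <- 0:(factorial(k) - 1)
    expect_equal(mirror_symbol(mirror_symbol(codes, k), k), codes)
  }
  # mirroring = symbolizing the negated signal
  set.seed(3)
  x <- rnorm(30)
  expect_equal(symbolize(-x, params_tau1),
               mirror_symbol(symbolize(x, params_tau1), 3))
  expect_error(mirror_symbol(6L, 3), "out of range")
})

test_that("joint counts tally symbol pairs and conserve mass", {
  sa <- c(0L, 1L, 0L, 5L)
  sb <- c(2L, 1L, 2L, 0L)
  j <- joint_symbol_counts(sa, sb)
  expect_equal(j$n_total, 4)
  expect_equal(sum(j$counts), 4)
  expect_equal(j$counts[1, 3], 2)  # (0,2) twice
  expect_equal(j$counts[2, 2], 1)
  expect_equal(j$counts[6, 1], 1)
  expect_error(joint_symbol_counts(sa, sb[1:3]), "length")
  # identical increasing signals: all mass at ((0,1,2),(0,1,2))
  s <- symbolize(1:20, params_tau1)
  ji <- joint_symbol_counts(s, s)
  expect_equal(ji$counts[1, 1], ji$n_total)
})

test_that("SMI endpoints: independence gives 0, uniform diagonal gives 1", {
  indep <- eegshare:::joint_from_counts(matrix(1, 6, 6))
  expect_equal(smi(indep), 0)
  diag6 <- eegshare:::joint_from_counts(diag(6))
  expect_equal(smi(diag6), 1)
  expect_error(smi(eegshare:::joint_from_counts(matrix(0, 6, 6))), "empty")
})

test_that("SMI and wSMI match a naive per-cell oracle on random joints", {
  naive <- function(counts, k = 3) {
    n <- sum(counts); p <- counts / n
    px <- rowSums(p); py <- colSums(p)
    mir <- mirror_symbol(0:(factorial(k) - 1), k)
    s_val <- 0; w_val <- 0
    for (x in 1:nrow(p)) for (y in 1:ncol(p)) {
      if (p[x, y] > 0) {
        term <- p[x, y] * log2(p[x, y] / (px[x] * py[y]))
        s_val <- s_val + term
        if (x != y && y != mir[x] + 1L) w_val <- w_val + term
      }
    }
    c(smi = s_val / log2(factorial(k)), wsmi = w_val / log2(factorial(k)))
  }
  set.seed(4)
  for (i in 1:100) {
    counts <- matrix(rpois(36, lambda = sample(1:20, 1)), 6, 6)
    if (sum(counts) == 0) counts[1, 1] <- 1
    j <- eegshare:::joint_from_counts(counts)
    ref <- naive(counts)
    expect_lt(abs(smi(j) - ref["smi"]), 1e-12)
    expect_lt(abs(wsmi(j) - ref["wsmi"]), 1e-12)
    expect_lte(ref["smi"], 1 + 1e-12)
    expect_gte(ref["smi"], 0)
  }
})

test_that("wSMI nulls identical and mirrored signals and matches hand example", {
  set.seed(5)
  x <- rnorm(500)
  sx <- symbolize(x, params_tau1)
  expect_equal(wsmi(joint_symbol_counts(sx, sx)), 0)
  expect_equal(wsmi(joint_symbol_counts(sx, symbolize(-x, params_tau1))), 0)
  # mass 1/2 on ((0,1,2),(0,2,1)) and 1/2 on ((0,2,1),(0,1,2))
  counts <- matrix(0, 6, 6); counts[1, 2] <- 1; counts[2, 1] <- 1
  expect_equal(wsmi(eegshare:::joint_from_counts(counts)), 0.38685,
               tolerance = 1e-5)
})

test_that("connectivity matrices are symmetric with zero diagonal", {
  d <- tiny_design()
  e <- simulate_subject_eeg(d, "control", 7)
  cm <- connectivity_matrix(e, symbol_params(fs = d$fs))
  expect_identical(cm, t(cm))
  expect_true(all(diag(cm) == 0))
  expect_identical(rownames(cm), build_montage("standard1020")$labels)
  # duplicated channel: off-diagonal wSMI of the duplicate pair is 0
  e2 <- e
  e2$data[2, , ] <- e2$data[1, , ]
  cm2 <- connectivity_matrix(e2, symbol_params(fs = d$fs))
  expect_equal(cm2[1, 2], 0)
})

test_that("independent channels score near the independence baseline", {
  set.seed(6)
  data <- array(rnorm(4 * 10 * 300), dim = c(4, 10, 300),
                dimnames = list(paste0("ch", 1:4), NULL, NULL))
  cm <- connectivity_matrix(epoched_eeg("s", data, 256), symbol_params(fs = 256))
  # > 10^4 symbol pairs: small positive plug-in bias, near zero
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.01))
})

test_that("lagged coupling raises wSMI above uncoupled pairs", {
  p <- symbol_params(fs = 256)
  wins <- 0
  for (r in 1:40) {
    set.seed(100 + r)
    n <- 2048
    shared <- eegshare:::shaped_noise(n, 256, 1, 8, 20, pink = FALSE)
    lagged <- eegshare:::shaped_noise(n, 256, 1, 8, 20, pink = FALSE)
    a <- rnorm(n) + shared
    b <- rnorm(n) + c(shared[(n - 3):n], shared[1:(n - 4)])  # lag 4
    c_ <- rnorm(n) + lagged
    sa <- symbolize(a, p); sb <- symbolize(b, p); sc <- symbolize(c_, p)
    coupled <- wsmi(joint_symbol_counts(sa, sb))
    uncoupled <- wsmi(joint_symbol_counts(sa, sc))
    wins <- wins + (coupled > uncoupled)
  }
  expect_gte(wins, 38)  # >= 95% of runs
})

test_that("the default tau targets the 8-20 Hz band, not slow rhythms", {
  p <- symbol_params(k = 3, tau_ms = 16, fs = 256)
  score <- function(freq) {
    vals <- vapply(1:10, function(r) {
      set.seed(200 + r)
      t <- seq_len(2560) / 256
      common <- sin(2 * pi * freq * t + runif(1, 0, 2 * pi))
      a <- 0.8 * common + rnorm(length(t))
      b <- 0.8 * c(tail(common, 16), head(common, -16)) + rnorm(length(t))
      wsmi(joint_symbol_counts(symbolize(a, p), symbolize(b, p)))
    }, numeric(1))
    mean(vals)
  }
  expect_gt(score(12), score(2))
})

test_that("the weighting suppresses zero-lag common sources but keeps lagged coupling", {
  p <- symbol_params(fs = 256)
  for (r in 1:10) {
    set.seed(300 + r)
    n <- 4000
    shared <- eegshare:::shaped_noise(n, 256, 1, 8, 20, pink = FALSE)
    # zero-lag common source (volume-conduction-like): SMI sees strong
    # coupling, the weighting removes most of it
    a0 <- 0.3 * rnorm(n) + shared
    b0 <- 0.3 * rnorm(n) + shared
    j0 <- joint_symbol_counts(symbolize(a0, p), symbolize(b0, p))
    expect_lt(wsmi(j0), smi(j0))
    expect_lt(wsmi(j0), 0.25 * smi(j0))
    # lagged coupling survives the weighting
    b1 <- 0.3 * rnorm(n) + c(tail(shared, 4), head(shared, -4))
    j1 <- joint_symbol_counts(symbolize(a0, p), symbolize(b1, p))
    expect_gt(wsmi(j1), wsmi(j0))
    expect_gt(wsmi(j1), 0.05)
  }
})
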