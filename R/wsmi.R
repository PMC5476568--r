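# Ordinal-pattern symbolization and (weighted) Symbolic Mutual Information.
#
# A signal window of k samples spaced tau apart is summarized by its ordinal
# pattern: the argsort permutation of the window, encoded as its lexicographic
# index in [0, k!). SMI is the mutual information between the symbol streams
# of two channels (log base 2, normalized by log2(k!), so SMI is in [0, 1]).
# wSMI additionally zero-weights joint cells whose symbols are identical or
# sign-mirrored, discounting spurious coupling from common sources and
# volume conduction.

#' Symbolization parameters
#'
#' @param k Samples per ordinal pattern (kernel size, default 3; k = 3 gives
#'   6 possible symbols).
#' @param tau_ms Spacing between the k samples, in milliseconds. The spacing
#'   sets the frequency band the measure is sensitive to; the 16 ms default
#'   targets roughly 8-20 Hz.
#' @param fs Sampling rate in Hz.
#' @return A `symbol_params` object with the spacing converted to samples.
#' @export
symbol_params <- function(k = 3, tau_ms = 16, fs = 256) {
  if (k < 2) stop("k must be >= 2")
  tau <- max(1L, as.integer(round(tau_ms * fs / 1000)))
  structure(list(k = as.integer(k), tau_ms = tau_ms, fs = fs,
                 tau_samples = tau),
            class = "symbol_params")
}

n_symbols <- function(k) factorial(k)

# Lexicographic index of a 0-based permutation (Lehmer code).
perm_to_code <- function(perm) {
  k <- length(perm)
  code <- 0L
  for (i in seq_len(k - 1)) {
    code <- code + sum(perm[(i + 1):k] < perm[i]) * factorial(k - i)
  }
  as.integer(code)
}

# All permutations of 0:(k-1) in lexicographic order (row i = code i-1).
all_perms <- function(k) {
  if (k == 1) return(matrix(0L, 1, 1))
  sub <- all_perms(k - 1)
  out <- matrix(0L, factorial(k), k)
  row <- 1
  for (first in 0:(k - 1)) {
    rest <- setdiff(0:(k - 1), first)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[j, ] + 1L])
      row <- row + 1
    }
  }
  out
}

# rank -> code lookup for k = 3: key from the (1-based) rank triple.
.k3_rank_lookup <- local({
  perms <- all_perms(3)
  lookup <- rep(NA_integer_, 27)
  for (code in 0:5) {
    a <- perms[code + 1, ]            # argsort permutation
    r <- integer(3); r[a + 1L] <- 1:3 # ranks of the samples
    key <- (r[1] - 1) * 9 + (r[2] - 1) * 3 + (r[3] - 1)
    lookup[key + 1] <- code
  }
  lookup
})

#' Symbolize a signal into ordinal-pattern codes
#'
#' Symbol t encodes the argsort permutation of
#' `(x[t], x[t+tau], ..., x[t+(k-1)tau])`; ties are broken stably (the
#' earlier sample ranks lower). Codes are lexicographic permutation indexes
#' in `[0, k!)`.
#'
#' @param x Numeric vector (one epoch of one channel).
#' @param params A [symbol_params()] object.
#' @return Integer vector of `length(x) - (k-1)*tau` symbol codes.
#' @export
symbolize <- function(x, params) {
  k <- params$k; tau <- params$tau_samples
  n_sym <- length(x) - (k - 1) * tau
  if (n_sym < 1) stop("signal too short for k = ", k, ", tau = ", tau)
  if (k == 3) {
    i <- seq_len(n_sym)
    x0 <- x[i]; x1 <- x[i + tau]; x2 <- x[i + 2L * tau]
    # stable ranks: rank_i = 1 + #{j: x_j < x_i} + #{j < i: x_j == x_i}
    r0 <- 1L + (x1 < x0) + (x2 < x0)
    r1 <- 1L + (x0 <= x1) + (x2 < x1)
    r2 <- 1L + (x0 <= x2) + (x1 <= x2)
    key <- (r0 - 1L) * 9L + (r1 - 1L) * 3L + (r2 - 1L)
    return(.k3_rank_lookup[key + 1L])
  }
  windows <- vapply(0:(k - 1), function(j) x[seq_len(n_sym) + j * tau],
                    numeric(n_sym))
  if (n_sym == 1) windows <- matrix(windows, 1)
  apply(windows, 1, function(w)
    perm_to_code(order(w) - 1L))
}

#' Mirror (sign-flip) symbol
#'
#' The ordinal pattern of the negated sample window is the reversed argsort
#' permutation; `mirror_symbol` maps each code to the code of its mirrored
#' pattern. It is an involution.
#'
#' @param code Integer symbol code(s) in `[0, k!)`.
#' @param k Kernel size.
#' @return Integer code(s) of the mirrored symbol(s).
#' @export
mirror_symbol <- function(code, k = 3) {
  nk <- n_symbols(k)
  if (any(code < 0 | code >= nk)) stop("symbol code out of range for k = ", k)
  perms <- all_perms(k)
  map <- apply(perms[, k:1, drop = FALSE], 1, perm_to_code)
  map[code + 1L]
}

#' Joint symbol distribution of two symbol streams
#'
#' Accumulates a k! x k! contingency table of simultaneous symbol pairs,
#' pooled over all time points (and, upstream, over all epochs of a subject).
#'
#' @param sa,sb Equal-length integer code vectors.
#' @param k Kernel size.
#' @return A `joint_symbol_counts` object: `counts` (k! x k! matrix) and
#'   `n_total`.
#' @export
joint_symbol_counts <- function(sa, sb, k = 3) {
  if (length(sa) != length(sb)) stop("symbol sequences differ in length")
  nk <- n_symbols(k)
  counts <- matrix(tabulate(sa * nk + sb + 1L, nbins = nk * nk),
                   nrow = nk, byrow = TRUE)
  structure(list(counts = counts, n_total = length(sa), k = k),
            class = "joint_symbol_counts")
}

joint_from_counts <- function(counts, k = 3) {
  structure(list(counts = counts, n_total = sum(counts), k = k),
            class = "joint_symbol_counts")
}

mi_terms <- function(j) {
  if (j$n_total <= 0) stop("empty joint distribution")
  p <- j$counts / j$n_total
  px <- rowSums(p); py <- colSums(p)
  denom <- outer(px, py)
  terms <- matrix(0, nrow(p), ncol(p))
  nz <- p > 0
  terms[nz] <- p[nz] * log2(p[nz] / denom[nz])
  terms
}

#' Symbolic mutual information
#'
#' `smi()` is the plug-in mutual information of the joint symbol
#' distribution, base-2, normalized by `log2(k!)` so independence gives 0 and
#' a deterministic one-to-one symbol correspondence gives 1. `wsmi()`
#' zero-weights cells with identical or mirrored symbol pairs; it can be
#' slightly negative.
#'
#' @param j A [joint_symbol_counts()] object.
#' @param k Kernel size (defaults to the one recorded in `j`).
#' @return Numeric scalar.
#' @export
smi <- function(j, k = j$k) {
  sum(mi_terms(j)) / log2(n_symbols(k))
}

#' @rdname smi
#' @export
wsmi <- function(j, k = j$k) {
  sum(mi_terms(j) * wsmi_weights(k)) / log2(n_symbols(k))
}

# 0/1 weight matrix zeroing identical and mirrored symbol pairs; memoized
.weight_cache <- new.env(parent = emptyenv())
wsmi_weights <- function(k) {
  key <- as.character(k)
  if (!is.null(.weight_cache[[key]])) return(.weight_cache[[key]])
  nk <- n_symbols(k)
  codes <- 0:(nk - 1)
  w <- matrix(1, nk, nk)
  w[cbind(codes + 1L, codes + 1L)] <- 0
  w[cbind(codes + 1L, mirror_symbol(codes, k) + 1L)] <- 0
  .weight_cache[[key]] <- w
  w
}

# Symbolize every channel of a channels x epochs x samples array; returns a
# channels x (epochs * n_sym) integer matrix (epochs never straddled).
# Vectorized over channels and epochs for the k = 3 fast path.
symbolize_array <- function(data, params) {
  dims <- dim(data)
  n_ch <- dims[1]; n_ep <- dims[2]; n_s <- dims[3]
  k <- params$k; tau <- params$tau_samples
  n_sym <- n_s - (k - 1) * tau
  if (n_sym < 1) stop("epochs too short for the symbolization parameters")
  if (k == 3) {
    i <- seq_len(n_sym)
    x0 <- data[, , i, drop = FALSE]
    x1 <- data[, , i + tau, drop = FALSE]
    x2 <- data[, , i + 2L * tau, drop = FALSE]
    r0 <- 1L + (x1 < x0) + (x2 < x0)
    r1 <- 1L + (x0 <= x1) + (x2 < x1)
    r2 <- 1L + (x0 <= x2) + (x1 <= x2)
    codes <- .k3_rank_lookup[(r0 - 1L) * 9L + (r1 - 1L) * 3L + r2]
    dim(codes) <- c(n_ch, n_ep, n_sym)
    codes <- aperm(codes, c(1, 3, 2))  # ch x n_sym x ep
    dim(codes) <- c(n_ch, n_sym * n_ep)  # epochs concatenated in order
    return(codes)
  }
  out <- matrix(0L, n_ch, n_ep * n_sym)
  for (ch in seq_len(n_ch)) {
    for (ep in seq_len(n_ep)) {
      out[ch, ((ep - 1) * n_sym + 1):(ep * n_sym)] <-
        symbolize(data[ch, ep, ], params)
    }
  }
  out
}

#' Per-subject wSMI connectivity matrix
#'
#' Computes wSMI for every unordered channel pair, pooling joint symbol
#' counts across all epochs before normalizing. The result is symmetric with
#' a structural zero diagonal.
#'
#' @param eeg An [epoched_eeg()] object (channels x epochs x samples).
#' @param params A [symbol_params()] object.
#' @return A channels x channels matrix with channel labels as dimnames.
#' @export
connectivity_matrix <- function(eeg, params = symbol_params(fs = eeg$fs)) {
  data <- eeg$data
  n_ch <- dim(data)[1]
  labels <- dimnames(data)[[1]]
  sym <- symbolize_array(data, params)
  nk <- n_symbols(params$k)
  n_t <- ncol(sym)
  w <- wsmi_weights(params$k)
  log2nk <- log2(nk)
  rows <- lapply(seq_len(n_ch), function(a) sym[a, ])
  cm <- matrix(0, n_ch, n_ch, dimnames = list(labels, labels))
  for (a in seq_len(n_ch - 1)) {
    sa_scaled <- rows[[a]] * nk + 1L
    for (b in (a + 1):n_ch) {
      p <- matrix(tabulate(sa_scaled + rows[[b]], nbins = nk * nk),
                  nrow = nk, byrow = TRUE) / n_t
      px <- rowSums(p); py <- colSums(p)
      nz <- p > 0
      v <- sum((p[nz] * log2(p[nz] / outer(px, py)[nz]) * w[nz])) / log2nk
      cm[a, b] <- v
      cm[b, a] <- v
    }
  }
  cm
}

#' Write / read a connectivity matrix as CSV
#'
#' Square CSV with a channel-label header and row names.
#'
#' @param cm Connectivity matrix.
#' @param path File path.
#' @export
write_connectivity <- function(cm, path) {
  utils::write.csv(cm, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
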