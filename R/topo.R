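# Topographic reductions of per-subject connectivity matrices: between-ROI
# averages, distance-binned profiles, and electrode-set means.

check_cm_montage <- function(cm, m) {
  if (is.null(rownames(cm)) || !identical(rownames(cm), m$labels) ||
      !identical(colnames(cm), m$labels))
    stop("connectivity matrix channels do not match the montage")
}

#' Mean connectivity for every unordered ROI pair
#'
#' For each of the `C(7,2) = 21` ROI pairs, the mean wSMI over all
#' inter-electrode connections linking the two ROIs (within-ROI connections
#' excluded).
#'
#' @param cm Connectivity matrix (channels x channels, labels as dimnames).
#' @param m The matching `eeg_montage`.
#' @return Named numeric vector, names like `"R1-R2"`, in lexicographic pair
#'   order.
#' @export
roi_pair_means <- function(cm, m) {
  check_cm_montage(cm, m)
  rois <- sort(unique(m$roi))
  pairs <- utils::combn(rois, 2)
  out <- apply(pairs, 2, function(p) {
    mean(cm[m$roi == p[1], m$roi == p[2], drop = FALSE])
  })
  names(out) <- apply(pairs, 2, paste, collapse = "-")
  out
}

#' ROI pair names for a montage
#' @param m An `eeg_montage`.
#' @return Character vector of unordered ROI pair names.
#' @export
roi_pair_names <- function(m) {
  apply(utils::combn(sort(unique(m$roi)), 2), 2, paste, collapse = "-")
}

# connections from ROI-internal electrodes to every ROI-external electrode:
# returns data.frame(value, distance)
roi_connections <- function(cm, m, roi) {
  check_cm_montage(cm, m)
  inside <- m$labels[m$roi == roi]
  if (!length(inside)) stop("ROI ", roi, " is empty")
  outside <- setdiff(m$labels, inside)
  dm <- distance_matrix(m)
  grid <- expand.grid(a = inside, b = outside, stringsAsFactors = FALSE)
  data.frame(a = grid$a, b = grid$b,
             value = cm[cbind(grid$a, grid$b)],
             distance = dm[cbind(grid$a, grid$b)])
}

#' Sliding distance bins
#'
#' Overlapping windows of width `width` stepped by `step` over
#' `[0, max_distance]`, for fine-grained connectivity-vs-distance curves.
#'
#' @param max_distance Upper end of the distance range.
#' @param width,step Window width and step (same unit as distances).
#' @return Data frame with columns `lo`, `hi`.
#' @export
sliding_bins <- function(max_distance, width = 0.15, step = 0.05) {
  lo <- seq(0, max_distance - width, by = step)
  data.frame(lo = lo, hi = lo + width)
}

bins_to_intervals <- function(bins) {
  if (inherits(bins, "distance_bins")) {
    br <- bins$breaks
    data.frame(lo = br[-length(br)], hi = br[-1])
  } else {
    stopifnot(all(c("lo", "hi") %in% names(bins)))
    as.data.frame(bins)[, c("lo", "hi")]
  }
}

#' Connectivity as a function of distance for one ROI
#'
#' All connections between ROI-internal and ROI-external electrodes are
#' binned by chordal electrode distance; per-bin mean connectivity is
#' reported. Intervals are half-open `[lo, hi)` except the last, which is
#' closed. Bins with no connections are flagged (`n = 0`, `mean = NA`), not
#' zero-filled.
#'
#' @param cm Connectivity matrix.
#' @param m The matching `eeg_montage`.
#' @param roi Seed ROI id.
#' @param bins A `distance_bins` object (e.g. [tertile_bins()]) or a data
#'   frame of `lo`/`hi` intervals (e.g. [sliding_bins()]); overlapping
#'   intervals are allowed.
#' @return Data frame: `bin`, `lo`, `hi`, `center`, `mean`, `n`, `empty`.
#' @export
distance_profile <- function(cm, m, roi, bins = tertile_bins(max(distance_matrix(m)))) {
  con <- roi_connections(cm, m, roi)
  iv <- bins_to_intervals(bins)
  n_b <- nrow(iv)
  res <- lapply(seq_len(n_b), function(i) {
    hi_closed <- i == n_b
    sel <- con$distance >= iv$lo[i] &
      (if (hi_closed) con$distance <= iv$hi[i] else con$distance < iv$hi[i])
    c(mean = if (any(sel)) mean(con$value[sel]) else NA_real_,
      n = sum(sel))
  })
  res <- do.call(rbind, res)
  data.frame(bin = seq_len(n_b), lo = iv$lo, hi = iv$hi,
             center = (iv$lo + iv$hi) / 2,
             mean = res[, "mean"], n = as.integer(res[, "n"]),
             empty = res[, "n"] == 0)
}

#' Mean ROI-anchored connectivity in a distance range
#'
#' Mean wSMI over connections from ROI-internal to ROI-external electrodes
#' whose distance falls in `[d_min, d_max)`. Returns `NA` (with a warning)
#' when no connection falls in the range.
#'
#' @param cm Connectivity matrix.
#' @param m The matching `eeg_montage`.
#' @param roi Seed ROI id.
#' @param d_min,d_max Distance range, `d_min < d_max`.
#' @return Numeric scalar (or `NA_real_`).
#' @export
range_mean <- function(cm, m, roi, d_min, d_max) {
  if (d_min >= d_max) stop("d_min must be < d_max")
  con <- roi_connections(cm, m, roi)
  sel <- con$distance >= d_min & con$distance < d_max
  if (!any(sel)) {
    warning("no connections in distance range [", d_min, ", ", d_max, ")")
    return(NA_real_)
  }
  mean(con$value[sel])
}

#' Mean connectivity between two electrode sets
#'
#' Mean wSMI over the `|A| x |B|` cross pairs of two disjoint non-empty
#' electrode sets.
#'
#' @param cm Connectivity matrix.
#' @param set_a,set_b Character vectors of channel labels.
#' @return Numeric scalar.
#' @export
set_pair_mean <- function(cm, set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stop("electrode sets must be non-empty")
  if (length(intersect(set_a, set_b))) stop("electrode sets must be disjoint")
  missing <- setdiff(c(set_a, set_b), rownames(cm))
  if (length(missing)) stop("unknown channel: ", paste(missing, collapse = ", "))
  mean(cm[set_a, set_b, drop = FALSE])
}
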