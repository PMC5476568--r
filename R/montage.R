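# Electrode montages on a unit-radius spherical head model.
#
# Positions live on a spherical cap of half-angle asin(0.9) (~64 deg from the
# vertex), so the largest chordal inter-electrode distance is 2*0.9 = 1.8.
# Only the relative distance structure matters downstream; the cap radius is
# chosen so that the observed distance range matches the 0-1.8 range used by
# the distance-binned analyses (tertile cuts at 0.6 and 1.2).

CAP_HALF_ANGLE <- asin(0.9)

#' Seven scalp regions of interest
#'
#' ROI identifiers used throughout the package: `R1` left frontal, `R2` right
#' frontal, `R3` right temporal, `R4` right posterior, `R5` left posterior
#' (parietal), `R6` left temporal, `R7` midline/central strip.
#'
#' @return Character vector of the seven ROI ids.
#' @export
roi_ids <- function() paste0("R", 1:7)

sph_to_xyz <- function(theta, phi_deg) {
  phi <- phi_deg * pi / 180
  cbind(x = sin(theta) * cos(phi),
        y = sin(theta) * sin(phi),
        z = cos(theta))
}

# 10/20-style layout: polar angle as a fraction of the cap half-angle, azimuth
# in degrees counterclockwise from +x (right ear); anterior is +y (90 deg).
standard1020_table <- function() {
  tab <- rbind(
    c("Fp1", 1.00, 108), c("Fp2", 1.00,  72),
    c("F7",  1.00, 144), c("F3",  0.72, 129), c("Fz", 0.45,  90),
    c("F4",  0.72,  51), c("F8",  1.00,  36),
    c("T7",  1.00, 180), c("C3",  0.45, 180), c("Cz", 0.00,   0),
    c("C4",  0.45,   0), c("T8",  1.00,   0),
    c("P7",  1.00, 216), c("P3",  0.72, 231), c("Pz", 0.45, 270),
    c("P4",  0.72, 309), c("P8",  1.00, 324),
    c("O1",  1.00, 252), c("Oz",  1.00, 270), c("O2",  1.00, 288)
  )
  data.frame(label = tab[, 1],
             theta_frac = as.numeric(tab[, 2]),
             phi = as.numeric(tab[, 3]),
             stringsAsFactors = FALSE)
}

standard1020_rois <- function() {
  c(Fp1 = "R1", F3 = "R1", F7 = "R1",
    Fp2 = "R2", F4 = "R2", F8 = "R2",
    T8 = "R3",
    P4 = "R4", P8 = "R4", O2 = "R4",
    P3 = "R5", P7 = "R5", O1 = "R5",
    T7 = "R6",
    Fz = "R7", Cz = "R7", C3 = "R7", C4 = "R7", Pz = "R7", Oz = "R7")
}

# Sector-based ROI assignment for the dense layout: electrodes close to the
# vertex form the central strip; the rest split into frontal / temporal /
# posterior azimuthal sectors per hemisphere (half-open sectors, measured from
# the anterior midline).
assign_roi_by_sector <- function(theta, phi_deg) {
  d <- (phi_deg - 90) %% 360  # 0 = anterior midline, increasing toward left
  roi <- character(length(theta))
  central <- theta <= 0.38 * CAP_HALF_ANGLE
  roi[central] <- "R7"
  lat <- !central
  sector <- findInterval(d[lat], c(0, 60, 125, 180, 235, 300, 360),
                         rightmost.closed = TRUE)
  roi[lat] <- c("R1", "R6", "R5", "R4", "R3", "R2")[sector]
  roi
}

dense128_table <- function() {
  ring_n <- c(1, 8, 12, 16, 20, 23, 24, 24)
  theta_frac <- c(0, (1:7) / 7)
  rows <- do.call(rbind, lapply(seq_along(ring_n), function(i) {
    n <- ring_n[i]
    offset <- if (i %% 2 == 0) 180 / n else 0
    phi <- 90 + offset + (0:(n - 1)) * 360 / n
    cbind(theta_frac = rep(theta_frac[i], n), phi = phi %% 360)
  }))
  data.frame(label = sprintf("E%03d", seq_len(nrow(rows))),
             theta_frac = rows[, "theta_frac"],
             phi = rows[, "phi"],
             stringsAsFactors = FALSE)
}

new_montage <- function(labels, positions, roi) {
  stopifnot(length(labels) == nrow(positions), length(roi) == length(labels))
  rownames(positions) <- labels
  names(roi) <- labels
  structure(list(labels = labels, positions = positions, roi = roi),
            class = "eeg_montage")
}

#' Build an electrode montage
#'
#' Constructs one of the two supported deterministic spherical layouts with
#' its seven-ROI partition: `"dense128"`, a 128-channel cap laid out on
#' equal-spacing rings with sector-based ROI assignment, or
#' `"standard1020"`, the 20-electrode 10/20 clinical set.
#'
#' @param layout `"dense128"` or `"standard1020"`.
#' @return An `eeg_montage` object: `labels`, unit-norm 3D `positions`
#'   (dimensionless head-sphere coordinates), and `roi`, a named vector
#'   mapping every channel to one of [roi_ids()].
#' @examples
#' m <- build_montage("standard1020")
#' table(m$roi)
#' @export
build_montage <- function(layout = c("dense128", "standard1020")) {
  if (length(layout) == 1 && !layout %in% c("dense128", "standard1020"))
    stop("unsupported montage layout: ", layout)
  layout <- match.arg(layout)
  tab <- switch(layout, dense128 = dense128_table(),
                standard1020 = standard1020_table())
  theta <- tab$theta_frac * CAP_HALF_ANGLE
  pos <- sph_to_xyz(theta, tab$phi)
  roi <- switch(layout,
                dense128 = assign_roi_by_sector(theta, tab$phi),
                standard1020 = unname(standard1020_rois()[tab$label]))
  new_montage(tab$label, pos, roi)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage>", length(x$labels), "channels;",
      "ROI sizes:", paste(sprintf("%s=%d", names(table(x$roi)), table(x$roi)),
                          collapse = " "), "\n")
  invisible(x)
}

#' Chordal distance between two electrodes
#'
#' Straight-line (chordal) distance between unit-sphere positions, in the
#' same dimensionless unit as the montage coordinates; range 0 to 2.
#'
#' @param m An `eeg_montage`.
#' @param a,b Channel labels.
#' @return Numeric distance.
#' @export
electrode_distance <- function(m, a, b) {
  for (ch in c(a, b))
    if (!ch %in% m$labels) stop("unknown channel: ", ch)
  sqrt(sum((m$positions[a, ] - m$positions[b, ])^2))
}

#' Full inter-electrode distance matrix
#'
#' @param m An `eeg_montage`.
#' @return Symmetric zero-diagonal matrix of chordal distances.
#' @export
distance_matrix <- function(m) {
  d <- as.matrix(stats::dist(m$positions))
  dimnames(d) <- list(m$labels, m$labels)
  d
}

#' Distance bins
#'
#' @param breaks Increasing numeric vector of bin boundaries starting at the
#'   lower end of the distance range.
#' @return A `distance_bins` object with `breaks`, `edges` (interior cut
#'   points) and `n_bins`.
#' @export
distance_bins <- function(breaks) {
  if (length(breaks) < 2 || any(diff(breaks) <= 0) || breaks[1] < 0)
    stop("breaks must be nonnegative and strictly increasing")
  structure(list(breaks = breaks,
                 edges = breaks[c(-1, -length(breaks))],
                 n_bins = length(breaks) - 1),
            class = "distance_bins")
}

#' Tertile distance bins
#'
#' Divides the total distance range `[0, max_distance]` into three
#' equal-width bins (short / mid / long range). For the 0-1.8 range of the
#' spherical-cap montages the interior cut points are 0.6 and 1.2.
#'
#' @param max_distance Largest inter-electrode distance (> 0).
#' @return A `distance_bins` object with three bins.
#' @export
tertile_bins <- function(max_distance) {
  if (!is.numeric(max_distance) || max_distance <= 0)
    stop("max_distance must be positive")
  distance_bins(seq(0, max_distance, length.out = 4))
}

#' Restrict a montage to a channel subset
#'
#' ROI assignments and positions are preserved; used to re-run analyses in
#' low-density (portable EEG) mode.
#'
#' @param m An `eeg_montage`.
#' @param keep Channel labels to retain (must all exist in `m`).
#' @return The restricted `eeg_montage`.
#' @export
subset_montage <- function(m, keep) {
  missing <- setdiff(keep, m$labels)
  if (length(missing)) stop("unknown channel: ", paste(missing, collapse = ", "))
  idx <- match(keep, m$labels)
  new_montage(m$labels[idx], m$positions[idx, , drop = FALSE],
              unname(m$roi[idx]))
}

#' Electrodes belonging to an ROI
#'
#' @param m An `eeg_montage`.
#' @param roi ROI id (one of [roi_ids()]).
#' @return Character vector of channel labels.
#' @export
roi_electrodes <- function(m, roi) {
  if (!roi %in% m$roi) stop("ROI ", roi, " is empty or unknown in this montage")
  m$labels[m$roi == roi]
}

#' Write / read a montage as a delimited text table
#'
#' Five columns: label, x, y, z, roi.
#'
#' @param m An `eeg_montage`.
#' @param path File path.
#' @return `read_montage` returns an `eeg_montage`; `write_montage` returns
#'   `path` invisibly.
#' @export
write_montage <- function(m, path) {
  df <- data.frame(label = m$labels, x = m$positions[, 1],
                   y = m$positions[, 2], z = m$positions[, 3],
                   roi = unname(m$roi))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_montage(df$label, as.matrix(df[, c("x", "y", "z")]), df$roi)
}
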