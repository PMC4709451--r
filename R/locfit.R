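# FrameStack -> filtered LocalizationTable.
#
# Coordinate convention (used package-wide): pixels are 0-based, pixel i
# spans [i, i+1) in pixel units and has its center at i + 0.5; nm
# coordinates are pixel units * pixel_size.

#' Running temporal median background subtraction
#'
#' For each pixel and frame t, subtracts the median over frames
#' `[t - (w-1)/2, t + (w-1)/2]` (window truncated at the stack ends).
#' Background-corrected values are signed by default; set `clip = TRUE` to
#' clamp negatives at zero.
#'
#' @param stack ny x nx x nt numeric array.
#' @param window odd window length (frames), default 101.
#' @param clip clamp negative corrected values at 0 (default `FALSE`).
#' @return array of the same dimensions (corrected stack).
#' @export
temporal_median_background <- function(stack, window = 101, clip = FALSE) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  bg <- cpp_temporal_median(stack, as.integer(window))
  out <- stack - bg
  if (clip) out[out < 0] <- 0
  out
}

#' Threshold-based spot detection in one frame
#'
#' Pixels above `threshold_k` times the frame's robust noise sd
#' (1.4826 x median absolute deviation) are grouped into 8-connected
#' components; each component's bounding box, padded by one pixel, becomes
#' a candidate region.  Components with any pixel on the image border are
#' dropped.
#'
#' @param frame 2D numeric matrix (background-corrected; rows = y).
#' @param threshold_k threshold in multiples of the robust sd (default 5).
#' @return list of candidate regions, each a list with 0-based pixel index
#'   vectors `xs`, `ys` (the padded bounding box) and the value matrix
#'   `values` (rows = ys).
#' @export
detect_spots <- function(frame, threshold_k = 5) {
  stopifnot(is.matrix(frame))
  med <- median(frame)
  sigma <- 1.4826 * median(abs(frame - med))
  thr <- threshold_k * sigma
  mask <- frame > thr
  if (!any(mask)) return(list())
  lab <- cpp_label_components(mask)
  ny <- nrow(frame); nx <- ncol(frame)
  ids <- seq_len(max(lab))
  out <- list()
  for (id in ids) {
    px <- which(lab == id, arr.ind = TRUE)   # 1-based (row=y, col=x)
    if (any(px[, 1] == 1 | px[, 1] == ny | px[, 2] == 1 | px[, 2] == nx))
      next                                   # touches border
    y0 <- max(1, min(px[, 1]) - 1); y1 <- min(ny, max(px[, 1]) + 1)
    x0 <- max(1, min(px[, 2]) - 1); x1 <- min(nx, max(px[, 2]) + 1)
    out[[length(out) + 1]] <- list(
      xs = (x0:x1) - 1L, ys = (y0:y1) - 1L,
      values = frame[y0:y1, x0:x1, drop = FALSE])
  }
  out
}

#' Center-of-mass sub-pixel localization of one candidate region
#'
#' Position is the intensity-weighted mean of pixel centers (0-based pixel
#' i has center i + 0.5), converted to nm by `pixel_size`.  Width is the
#' rms spot radius, `sqrt(mean(eigenvalues))` of the intensity-weighted
#' covariance, times `pixel_size`; asymmetry is `sqrt(lmax/lmin)` of that
#' covariance.  Negative pixel values (possible after signed background
#' subtraction) contribute zero weight.  A single-pixel region gets
#' asymmetry 1 and the quantization width `pixel_size/sqrt(12)`.
#'
#' @param region a candidate from [detect_spots()].
#' @param pixel_size_nm camera pixel size (nm).
#' @param frame_index frame number stored in the record.
#' @param channel channel id stored in the record.
#' @return one-row localization data.frame, or `NULL` if the region has
#'   non-positive total intensity.
#' @export
localize_com <- function(region, pixel_size_nm = 132, frame_index = 1L,
                         channel = 1L) {
  w <- pmax(region$values, 0)
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  cx <- region$xs + 0.5
  cy <- region$ys + 0.5
  wx <- colSums(w); wy <- rowSums(w)
  mx <- sum(cx * wx) / tot
  my <- sum(cy * wy) / tot
  npos <- sum(w > 0)
  if (npos <= 1) {
    width_px <- 1 / sqrt(12)
    asym <- 1
  } else {
    vxx <- sum(wx * (cx - mx)^2) / tot
    vyy <- sum(wy * (cy - my)^2) / tot
    vxy <- sum(w * outer(cy - my, cx - mx)) / tot
    tr <- vxx + vyy
    det <- vxx * vyy - vxy^2
    disc <- sqrt(max(0, (tr / 2)^2 - det))
    l1 <- tr / 2 + disc
    l2 <- tr / 2 - disc
    width_px <- sqrt(max(tr / 2, 0))
    asym <- if (l2 <= .Machine$double.eps * l1) Inf else sqrt(l1 / l2)
  }
  data.frame(frame = as.integer(frame_index),
             x_nm = mx * pixel_size_nm, y_nm = my * pixel_size_nm,
             intensity = tot,
             width_nm = width_px * pixel_size_nm,
             asymmetry = asym, channel = channel)
}

#' Quality filter specification
#' @param min_intensity minimum background-corrected photon count.
#' @param max_width_nm maximum rms spot radius (nm).
#' @param max_asymmetry maximum covariance asymmetry ratio (>= 1).
#' @return a `qc_filter` object.
#' @export
qc_filter <- function(min_intensity = 200, max_width_nm = 250,
                      max_asymmetry = 1.5) {
  stopifnot(min_intensity > 0, max_width_nm > 0, max_asymmetry >= 1)
  structure(list(min_intensity = min_intensity, max_width_nm = max_width_nm,
                 max_asymmetry = max_asymmetry), class = "qc_filter")
}

#' Filter a localization table on intensity, width and asymmetry
#'
#' Keeps records with `intensity >= min_intensity`,
#' `width_nm <= max_width_nm` and `asymmetry <= max_asymmetry`,
#' preserving order.  Kept/dropped counts per criterion are attached as
#' the `"qc_report"` attribute.
#'
#' @param table localization data.frame.
#' @param qc a [qc_filter()].
#' @return filtered table with a `qc_report` attribute.
#' @export
filter_localizations <- function(table, qc = qc_filter()) {
  stopifnot(inherits(qc, "qc_filter"))
  if (nrow(table) == 0) {
    attr(table, "qc_report") <- list(n_in = 0L, n_kept = 0L,
                                     dropped_intensity = 0L,
                                     dropped_width = 0L,
                                     dropped_asymmetry = 0L)
    return(table)
  }
  ok_i <- table$intensity >= qc$min_intensity
  ok_w <- table$width_nm <= qc$max_width_nm
  ok_a <- table$asymmetry <= qc$max_asymmetry
  keep <- ok_i & ok_w & ok_a
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_report") <- list(
    n_in = nrow(table), n_kept = sum(keep),
    dropped_intensity = sum(!ok_i),
    dropped_width = sum(!ok_w),
    dropped_asymmetry = sum(!ok_a))
  out
}

#' Localize an entire movie stack
#'
#' Convenience driver: temporal median background subtraction, per-frame
#' spot detection, COM localization, and QC filtering.
#'
#' @param stack ny x nx x nt array (raw movie, photons).
#' @param pixel_size_nm camera pixel size (nm).
#' @param window temporal median window (frames).
#' @param threshold_k detection threshold in robust-sd multiples.
#' @param qc a [qc_filter()], or `NULL` to skip filtering.
#' @param channel channel id written into the records.
#' @return filtered localization data.frame (with `qc_report` attribute
#'   when `qc` is given).
#' @export
localize_stack <- function(stack, pixel_size_nm = 132, window = 101,
                           threshold_k = 5, qc = qc_filter(), channel = 1L) {
  corrected <- temporal_median_background(stack, window)
  nt <- dim(corrected)[3]
  recs <- vector("list", nt)
  for (t in seq_len(nt)) {
    regions <- detect_spots(corrected[, , t], threshold_k)
    if (length(regions) == 0) next
    rows <- lapply(regions, localize_com, pixel_size_nm = pixel_size_nm,
                   frame_index = t, channel = channel)
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) recs[[t]] <- do.call(rbind, rows)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  tab <- if (length(recs)) do.call(rbind, recs) else {
    emp <- empty_loc_table(); emp$label_id <- NULL; emp
  }
  rownames(tab) <- NULL
  if (!is.null(qc)) tab <- filter_localizations(tab, qc)
  tab
}

#' Localize fiducial beads from the raw (uncorrected) stack
#'
#' Beads are ON in every frame, so they cancel under temporal median
#' subtraction; they are instead detected on the temporal mean image of
#' the raw stack, where their integrated signal dominates blinking
#' emitters by orders of magnitude.
#'
#' @param stack raw ny x nx x nt array (photons).
#' @param pixel_size_nm camera pixel size (nm).
#' @param threshold_k detection threshold on the mean image (robust-sd
#'   multiples; high by default because the mean image is nearly
#'   noise-free).
#' @param min_mean_photons minimum summed mean-image intensity
#'   (photons/frame) for a candidate to count as a bead.  This must sit
#'   above the time-averaged brightness of a whole emitter cluster (a
#'   synapse with n emitters of rate r and duty cycle d averages n*r*d
#'   photons/frame), not just of a single emitter.
#' @return m x 2 matrix of bead xy positions (nm).
#' @export
localize_beads <- function(stack, pixel_size_nm = 132, threshold_k = 20,
                           min_mean_photons = 1500) {
  meanimg <- rowMeans(stack, dims = 2)
  meanimg <- meanimg - median(meanimg)
  regions <- detect_spots(meanimg, threshold_k)
  rows <- lapply(regions, localize_com, pixel_size_nm = pixel_size_nm)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(matrix(numeric(), ncol = 2,
                                       dimnames = list(NULL, c("x_nm", "y_nm"))))
  tab <- do.call(rbind, rows)
  tab <- tab[tab$intensity >= min_mean_photons, , drop = FALSE]
  cbind(x_nm = tab$x_nm, y_nm = tab$y_nm)
}
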