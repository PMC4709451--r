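# Transsynaptic COM distance statistics: line-profile (1D) and rectangle
# (2D) COM distances, 10 nm histograms, the top-fraction mean estimator,
# cutoff sensitivity, and the analytic projection oracle.

#' Line ROI across a synapse
#'
#' A band of the given `width_nm` (default 300) centered on the line from
#' `anchor_nm` along `direction` for `length_nm`, marking the presumed
#' transsynaptic axis perpendicular to the apparent synaptic cleft.
#' Axial positions in extracted profiles are measured from the anchor, so
#' only COM differences are meaningful, not absolute positions.
#'
#' @param anchor_nm xy start point (nm).
#' @param direction in-plane direction (normalized internally).
#' @param length_nm line length (nm).
#' @param width_nm band width (nm, default 300).
#' @param synapse_id identifier carried through to results.
#' @return a `line_roi`.
#' @export
line_roi <- function(anchor_nm, direction, length_nm, width_nm = 300,
                     synapse_id = NA) {
  stopifnot(length_nm > 0, width_nm > 0)
  structure(list(anchor_nm = as.numeric(anchor_nm)[1:2],
                 direction = unitize(as.numeric(direction)[1:2]),
                 length_nm = length_nm, width_nm = width_nm,
                 synapse_id = synapse_id), class = "line_roi")
}

#' Rectangle ROI enclosing a synapse
#'
#' @param corner_nm xy corner (nm).
#' @param edge1_nm,edge2_nm edge vectors (must be orthogonal).
#' @param synapse_id identifier carried through to results.
#' @return a `rect_roi`.
#' @export
rect_roi <- function(corner_nm, edge1_nm, edge2_nm, synapse_id = NA) {
  e1 <- as.numeric(edge1_nm)[1:2]; e2 <- as.numeric(edge2_nm)[1:2]
  if (abs(sum(e1 * e2)) > 1e-9 * vec_norm(e1) * vec_norm(e2))
    stop("rectangle edges must be orthogonal")
  if (vec_norm(e1) == 0 || vec_norm(e2) == 0) stop("rectangle has zero area")
  structure(list(corner_nm = as.numeric(corner_nm)[1:2],
                 edge1_nm = e1, edge2_nm = e2, synapse_id = synapse_id),
            class = "rect_roi")
}

assert_raw_input <- function(x) {
  if (inherits(x, "sr_image") && x$blur_sigma_nm > 0)
    stop("COM analysis requires raw (unblurred) data; got a blurred image")
  invisible(x)
}

# localization table or sr_image -> points (x, y, weight)
as_points <- function(x, channel = NULL) {
  if (inherits(x, "sr_image")) {
    assert_raw_input(x)
    m <- x$data
    nz <- which(m > 0, arr.ind = TRUE)
    data.frame(
      x_nm = x$origin_nm[1] + (nz[, 2] - 0.5) * x$raster_nm,
      y_nm = x$origin_nm[2] + (nz[, 1] - 0.5) * x$raster_nm,
      w = m[nz])
  } else {
    tab <- x
    if (!is.null(channel)) tab <- tab[tab$channel == channel, , drop = FALSE]
    data.frame(x_nm = tab$x_nm, y_nm = tab$y_nm, w = tab$intensity)
  }
}

#' One-dimensional intensity profiles along a line ROI
#'
#' Rotates coordinates into the (axial, transverse) frame of the ROI,
#' keeps data with `|transverse| <= width/2` and axial offset in
#' `[0, length]`, accumulates intensity into axial bins of `bin_nm`, and
#' divides by the ROI width (average across the band).  Input must be raw:
#' a localization table (default path) or an unblurred `sr_image` per
#' channel; blurred images are refused.
#'
#' @param x localization data.frame (both channels) or a list of two raw
#'   `sr_image`s named/ordered by channel.
#' @param roi a [line_roi()].
#' @param bin_nm axial bin width (nm, default 10).
#' @param channels the two channel ids (table input).
#' @return list of two `intensity_profile`s (fields `centers_nm`, `values`,
#'   `channel`, `empty`).
#' @export
extract_line_profiles <- function(x, roi, bin_nm = 10, channels = c(1, 2)) {
  stopifnot(inherits(roi, "line_roi"), bin_nm > 0)
  dirv <- roi$direction
  perp <- c(-dirv[2], dirv[1])
  edges <- seq(0, roi$length_nm, by = bin_nm)
  if (tail(edges, 1) < roi$length_nm) edges <- c(edges, tail(edges, 1) + bin_nm)
  centers <- head(edges, -1) + bin_nm / 2
  one <- function(pts, ch) {
    dx <- pts$x_nm - roi$anchor_nm[1]
    dy <- pts$y_nm - roi$anchor_nm[2]
    a <- dx * dirv[1] + dy * dirv[2]
    tr <- dx * perp[1] + dy * perp[2]
    keep <- abs(tr) <= roi$width_nm / 2 & a >= 0 & a <= roi$length_nm
    v <- numeric(length(centers))
    if (any(keep)) {
      bin <- pmin(findInterval(a[keep], edges, rightmost.closed = FALSE),
                  length(centers))
      acc <- rowsum(pts$w[keep], bin)
      v[as.integer(rownames(acc))] <- acc[, 1]
    }
    structure(list(centers_nm = centers, values = v / roi$width_nm,
                   channel = ch, empty = !any(keep)),
              class = "intensity_profile")
  }
  if (is.data.frame(x)) {
    lapply(seq_along(channels), function(i)
      one(as_points(x, channels[i]), channels[i]))
  } else {
    lapply(seq_along(x), function(i) {
      img <- x[[i]]
      one(as_points(img), img$channel %||% i)
    })
  }
}

#' Intensity-weighted center of mass of a 1D profile
#' @param profile an `intensity_profile`.
#' @return axial COM position (nm, relative to the ROI anchor).
#' @export
com_1d <- function(profile) {
  tot <- sum(profile$values)
  if (tot <= 0) stop("profile has zero total intensity")
  sum(profile$centers_nm * profile$values) / tot
}

#' 1D COM distance between two profiles
#' @param p_a,p_b `intensity_profile`s on the same bin grid.
#' @return `|com_1d(p_a) - com_1d(p_b)|` in nm.
#' @export
com_distance_1d <- function(p_a, p_b) {
  if (length(p_a$centers_nm) != length(p_b$centers_nm) ||
      any(abs(p_a$centers_nm - p_b$centers_nm) > 1e-9))
    stop("profiles must share the same bin grid")
  abs(com_1d(p_a) - com_1d(p_b))
}

#' 2D COM Euclidean distance inside a rectangle ROI
#'
#' Intensity-weighted 2D COM per channel over the records inside the
#' rectangle; returns the Euclidean distance between the two COMs.
#'
#' @param table localization data.frame (raw).
#' @param roi a [rect_roi()].
#' @param channels the two channel ids.
#' @return distance in nm.
#' @export
com_2d_distance <- function(table, roi, channels = c(1, 2)) {
  stopifnot(inherits(roi, "rect_roi"))
  assert_raw_input(table)
  l1 <- sum(roi$edge1_nm^2); l2 <- sum(roi$edge2_nm^2)
  com_ch <- function(ch) {
    tab <- table[table$channel == ch, , drop = FALSE]
    dx <- tab$x_nm - roi$corner_nm[1]
    dy <- tab$y_nm - roi$corner_nm[2]
    u <- (dx * roi$edge1_nm[1] + dy * roi$edge1_nm[2]) / l1
    v <- (dx * roi$edge2_nm[1] + dy * roi$edge2_nm[2]) / l2
    keep <- u >= 0 & u <= 1 & v >= 0 & v <= 1
    if (!any(keep))
      stop(sprintf("channel %s has no localizations inside the rectangle", ch))
    w <- tab$intensity[keep]
    c(sum(tab$x_nm[keep] * w), sum(tab$y_nm[keep] * w)) / sum(w)
  }
  a <- com_ch(channels[1]); b <- com_ch(channels[2])
  sqrt(sum((a - b)^2))
}

#' Top-fraction mean distance estimator
#'
#' Sorts distances in decreasing order, keeps the top `ceiling(q * n)`
#' (ties broken by the stable sort), and reports their mean and SEM
#' (sample sd of the kept subset / sqrt(n_used)).  The histogram is built
#' on the full set in `hist_bin_nm` bins.  Restricting to the largest
#' distances selects synapses whose cleft is close to perpendicular to
#' the image plane, countering the 2D projection bias.
#'
#' @param distances numeric vector of per-synapse distances (nm).
#' @param q retained fraction in (0, 1], default 0.4.
#' @param hist_bin_nm histogram bin width (nm, default 10).
#' @return an `estimator_result`: `mean_distance_nm`, `sem_nm`, `n_total`,
#'   `n_used`, `fraction_q`, `histogram` (data.frame mid/counts).
#' @export
top_fraction_mean <- function(distances, q = 0.4, hist_bin_nm = 10) {
  if (length(distances) == 0) stop("no distances supplied")
  stopifnot(q > 0, q <= 1)
  n <- length(distances)
  n_used <- as.integer(ceiling(q * n))
  used <- sort(distances, decreasing = TRUE)[seq_len(n_used)]
  brk <- seq(0, (floor(max(distances) / hist_bin_nm) + 1) * hist_bin_nm,
             by = hist_bin_nm)
  cnt <- tabulate(findInterval(distances, brk), length(brk) - 1)
  structure(list(
    mean_distance_nm = mean(used),
    sem_nm = if (n_used > 1) sd(used) / sqrt(n_used) else 0,
    n_total = n, n_used = n_used, fraction_q = q,
    histogram = data.frame(mid_nm = head(brk, -1) + hist_bin_nm / 2,
                           count = cnt)),
    class = "estimator_result")
}

#' @export
print.estimator_result <- function(x, ...) {
  cat(sprintf("top-%d%% mean COM distance: %.1f +/- %.1f nm (SEM; n = %d of %d)\n",
              round(100 * x$fraction_q), x$mean_distance_nm, x$sem_nm,
              x$n_used, x$n_total))
  invisible(x)
}

#' Cutoff sensitivity sweep
#'
#' Applies [top_fraction_mean()] for each fraction in `q_list` and reports
#' whether the mean is non-increasing in q (it must be, by order
#' statistics), mirroring the robustness-to-cutoff check.
#'
#' @param distances numeric vector (nm).
#' @param q_list fractions to evaluate.
#' @return data.frame (q, mean_distance_nm, sem_nm, n_used) with attribute
#'   `monotone_nonincreasing`.
#' @export
cutoff_sweep <- function(distances, q_list = c(0.2, 0.4, 0.6, 0.8, 1.0)) {
  res <- lapply(q_list, function(q) top_fraction_mean(distances, q))
  out <- data.frame(
    q = q_list,
    mean_distance_nm = vapply(res, `[[`, numeric(1), "mean_distance_nm"),
    sem_nm = vapply(res, `[[`, numeric(1), "sem_nm"),
    n_used = vapply(res, `[[`, integer(1), "n_used"))
  attr(out, "monotone_nonincreasing") <-
    all(diff(out$mean_distance_nm[order(out$q)]) <= 1e-12)
  out
}

#' Analytic projection factor of the top-fraction estimator
#'
#' For a true 3D separation d with axes uniform on the hemisphere, the
#' noiseless apparent separation is d*sin(theta) with u = cos(theta)
#' uniform on (0, 1).  Keeping the top fraction q of apparent separations
#' keeps u in (0, q), so the expected estimator-to-truth ratio is
#' `(1/q) * (u*sqrt(1-u^2) + asin(u)) / 2` evaluated at `u = q`.
#' Limits: q -> 0 gives 1 (only in-plane synapses kept); q = 1 gives
#' pi/4, the unconditional mean of sin(theta).
#'
#' @param q retained fraction in (0, 1].
#' @return expected ratio of the estimator to the true separation.
#' @export
projection_factor <- function(q) {
  if (any(q <= 0 | q > 1)) stop("q must lie in (0, 1]")
  (q * sqrt(1 - q^2) + asin(q)) / (2 * q)
}

#' Line ROIs derived from simulated ground truth
#'
#' Builds, for each simulated synapse, a line ROI centered on the synapse
#' along its projected transsynaptic axis — the surrogate for the manual
#' synapse marking done on real data.  Synapses whose axis projects to
#' (almost) nothing in-plane fall back to the x direction.
#'
#' @param truths list of `synapse_truth` objects.
#' @param length_nm ROI length (nm).
#' @param width_nm ROI width (nm, default 300).
#' @return list of [line_roi()]s.
#' @export
rois_from_truth <- function(truths, length_nm = 1200, width_nm = 300) {
  lapply(truths, function(tr) {
    d2 <- tr$axis[1:2]
    if (vec_norm(d2) < 1e-9) d2 <- c(1, 0)
    d2 <- unitize(d2)
    line_roi(anchor_nm = tr$center[1:2] - d2 * length_nm / 2,
             direction = d2, length_nm = length_nm, width_nm = width_nm,
             synapse_id = tr$id)
  })
}

#' Rectangle ROIs derived from simulated ground truth
#' @param truths list of `synapse_truth` objects.
#' @param half_extent_nm half edge length of the square ROI (nm).
#' @return list of [rect_roi()]s.
#' @export
rect_rois_from_truth <- function(truths, half_extent_nm = 600) {
  lapply(truths, function(tr) {
    rect_roi(corner_nm = tr$center[1:2] - half_extent_nm,
             edge1_nm = c(2 * half_extent_nm, 0),
             edge2_nm = c(0, 2 * half_extent_nm),
             synapse_id = tr$id)
  })
}

#' Measure per-synapse 1D COM distances over a set of line ROIs
#'
#' @param table localization data.frame (both channels, registered and
#'   drift-corrected, raw).
#' @param rois list of [line_roi()]s.
#' @param bin_nm profile bin width (nm).
#' @param channels the two channel ids.
#' @return data.frame (synapse_id, distance_nm); synapses with an empty
#'   channel profile are dropped with a message.
#' @export
measure_line_distances <- function(table, rois, bin_nm = 10,
                                   channels = c(1, 2)) {
  rows <- lapply(rois, function(roi) {
    prof <- extract_line_profiles(table, roi, bin_nm, channels)
    if (prof[[1]]$empty || prof[[2]]$empty) return(NULL)
    data.frame(synapse_id = roi$synapse_id,
               distance_nm = com_distance_1d(prof[[1]], prof[[2]]))
  })
  drop <- sum(vapply(rows, is.null, logical(1)))
  if (drop > 0)
    message(sprintf("dropped %d ROI(s) with an empty channel profile", drop))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(synapse_id = integer(),
                                      distance_nm = numeric())
  rownames(out) <- NULL
  out
}
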