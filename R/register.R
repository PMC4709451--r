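# Two-channel registration (bead-fitted transform) and redundant
# cross-correlation (RCC) drift correction.

poly_terms <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Fit a channel-mapping transform from matched beads
#'
#' Least-squares fit of a transform T minimizing
#' `sum ||T(p2) - p1||^2` over matched fiducial beads, mapping channel-2
#' coordinates onto channel 1.  If the two bead lists are not row-matched,
#' set `match = TRUE` to pair them by mutual nearest neighbor within
#' `match_gate_nm`.
#'
#' @param beads_ch1,beads_ch2 n x 2 matrices of bead positions (nm).
#' @param kind `"affine"` (6 parameters) or `"polynomial"` (2nd order,
#'   12 parameters).
#' @param match pair beads by mutual nearest neighbor first.
#' @param match_gate_nm maximum pairing distance (nm).
#' @return a `transform_model` with `kind`, `coef` (2-row coefficient
#'   matrix), `fit_rms_nm`, `n_beads`.
#' @export
fit_channel_transform <- function(beads_ch1, beads_ch2, kind = c("affine",
                                  "polynomial"), match = FALSE,
                                  match_gate_nm = 500) {
  kind <- match.arg(kind)
  p1 <- as.matrix(beads_ch1); p2 <- as.matrix(beads_ch2)
  if (match) {
    m <- match_beads(p1, p2, match_gate_nm)
    p1 <- p1[m[, 1], , drop = FALSE]
    p2 <- p2[m[, 2], , drop = FALSE]
  }
  if (nrow(p1) != nrow(p2)) stop("bead lists must be matched (same length)")
  n <- nrow(p1)
  need <- if (kind == "affine") 3 else 6
  if (n < need)
    stop(sprintf("too few matched beads for %s fit: need >= %d, got %d",
                 kind, need, n))
  X <- if (kind == "affine") cbind(1, p2[, 1], p2[, 2])
       else poly_terms(p2[, 1], p2[, 2])
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("degenerate bead layout (collinear or otherwise rank-deficient)")
  coef <- qr.coef(qrX, p1)             # ncol(X) x 2
  pred <- X %*% coef
  res <- p1 - pred
  rms <- sqrt(mean(rowSums(res^2)))
  structure(list(kind = kind, coef = t(coef), fit_rms_nm = rms, n_beads = n),
            class = "transform_model")
}

#' Mutual nearest-neighbor bead matching
#' @param p1,p2 n x 2 matrices (nm).
#' @param gate_nm maximum allowed pairing distance (nm).
#' @return two-column matrix of row indices (i1, i2).
#' @export
match_beads <- function(p1, p2, gate_nm = 500) {
  p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
  nn12 <- apply(d2, 1, which.min)
  nn21 <- apply(d2, 2, which.min)
  keep <- which(nn21[nn12] == seq_len(nrow(p1)) &
                d2[cbind(seq_len(nrow(p1)), nn12)] <= gate_nm^2)
  cbind(i1 = keep, i2 = nn12[keep])
}

transform_points <- function(t, xy) {
  xy <- as.matrix(xy)
  X <- if (t$kind == "affine") cbind(1, xy[, 1], xy[, 2])
       else poly_terms(xy[, 1], xy[, 2])
  X %*% t(t$coef)
}

#' Identity transform
#' @param kind transform family.
#' @return a `transform_model` acting as the identity.
#' @export
identity_transform <- function(kind = "affine") {
  coef <- if (kind == "affine") rbind(c(0, 1, 0), c(0, 0, 1))
          else rbind(c(0, 1, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0))
  structure(list(kind = kind, coef = coef, fit_rms_nm = 0, n_beads = 0L),
            class = "transform_model")
}

#' Invert an affine transform
#' @param t an affine `transform_model`.
#' @return the inverse `transform_model`.
#' @export
invert_transform <- function(t) {
  if (t$kind != "affine") stop("only affine transforms have a closed-form inverse")
  A <- t$coef[, 2:3]
  b <- t$coef[, 1]
  Ai <- solve(A)
  bi <- -Ai %*% b
  structure(list(kind = "affine", coef = cbind(bi, Ai), fit_rms_nm = 0,
                 n_beads = t$n_beads), class = "transform_model")
}

#' Apply a channel transform to a localization table
#'
#' Replaces `x_nm`/`y_nm` by the transformed coordinates; all other
#' columns and the row order are unchanged.
#'
#' @param table localization data.frame.
#' @param t a `transform_model`.
#' @return transformed table.
#' @export
apply_transform <- function(table, t) {
  stopifnot(inherits(t, "transform_model"))
  if (nrow(table) == 0) return(table)
  p <- transform_points(t, cbind(table$x_nm, table$y_nm))
  table$x_nm <- p[, 1]
  table$y_nm <- p[, 2]
  table
}

# sparse 2D localization histogram: unique bin indices + counts
loc_histogram_sparse <- function(x, y, bin_nm) {
  ix <- as.integer(floor(x / bin_nm))
  iy <- as.integer(floor(y / bin_nm))
  key <- paste(ix, iy)
  acc <- rowsum(rep(1, length(key)), key)
  parts <- do.call(rbind, strsplit(rownames(acc), " ", fixed = TRUE))
  list(x = as.integer(parts[, 1]), y = as.integer(parts[, 2]),
       w = as.numeric(acc[, 1]))
}

# windowed cross-correlation of two sparse histograms; returns the
# sub-bin shift (in bins) of image B relative to image A (B = A shifted
# by +shift), searched over |shift| <= m bins.  The correlogram is
# smoothed with a 1-bin Gaussian before peak finding: localization
# clusters are many bins wide, so the raw correlation has a flat, shot-
# noise-limited top whose bare argmax wanders by several bins.
xcorr_shift <- function(A, B, m) {
  C <- cpp_sparse_xcorr(A$x, A$y, A$w, B$x, B$y, B$w, m)
  k <- exp(-((-3:3)^2) / 2); k <- k / sum(k)
  C <- reflect_conv(C, k)
  pk <- which(C == max(C), arr.ind = TRUE)[1, ]
  refine <- function(get, k, n) {
    if (k <= 1 || k >= n) return(k)          # peak on window edge: no refine
    cm <- get(k - 1); c0 <- get(k); cp <- get(k + 1)
    den <- cm - 2 * c0 + cp
    if (den == 0) return(k)
    k + 0.5 * (cm - cp) / den
  }
  n <- 2 * m + 1
  ky <- refine(function(k) C[k, pk[2]], pk[1], n)
  kx <- refine(function(k) C[pk[1], k], pk[2], n)
  c(dx = kx - (m + 1), dy = ky - (m + 1))
}

#' Redundant cross-correlation drift estimation
#'
#' Splits the table's frame range into `n_segments` contiguous temporal
#' segments, renders each as a 2D localization histogram at `bin_nm`,
#' cross-correlates all segment pairs (FFT, 3-point parabolic sub-bin peak
#' per axis), and solves the overdetermined pairwise-shift system by least
#' squares with segment 1 anchored at (0, 0).  Per-frame drift is the
#' linear interpolation between segment centers (linearly extrapolated
#' beyond the first/last center).
#'
#' @param table localization data.frame (one or both channels).
#' @param n_segments number of temporal segments (default 10).
#' @param bin_nm histogram raster (nm, default 10).
#' @param max_shift_nm largest pairwise shift searched for (nm); the
#'   correlation is evaluated only inside this window, which keeps RCC
#'   tractable on large fields.  Must exceed the total expected drift.
#' @return a `drift_trace` with `centers` (frame), `dx_nm`, `dy_nm`,
#'   `frame_range`.
#' @export
estimate_drift_rcc <- function(table, n_segments = 10, bin_nm = 10,
                               max_shift_nm = 1000) {
  stopifnot(n_segments >= 2, bin_nm > 0, max_shift_nm >= 2 * bin_nm)
  if (nrow(table) == 0) stop("empty localization table")
  fr <- range(table$frame)
  bounds <- round(seq(fr[1] - 0.5, fr[2] + 0.5, length.out = n_segments + 1))
  seg <- findInterval(table$frame, bounds, rightmost.closed = TRUE)
  seg[seg < 1] <- 1; seg[seg > n_segments] <- n_segments
  counts <- tabulate(seg, n_segments)
  if (any(counts == 0))
    stop("segment with zero localizations; reduce n_segments")
  if (any(counts < 100))
    warning("fewer than 100 localizations in some segments; drift estimate may be noisy")
  imgs <- lapply(seq_len(n_segments), function(s) {
    i <- seg == s
    loc_histogram_sparse(table$x_nm[i], table$y_nm[i], bin_nm)
  })
  m <- as.integer(ceiling(max_shift_nm / bin_nm))
  pairs <- t(combn(n_segments, 2))
  meas <- t(apply(pairs, 1, function(p)
    xcorr_shift(imgs[[p[1]]], imgs[[p[2]]], m)))
  # shift of segment j relative to segment i: s_j - s_i = meas
  K <- n_segments
  D <- matrix(0, nrow(pairs), K - 1)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i > 1) D[r, i - 1] <- -1
    D[r, j - 1] <- 1
  }
  sx <- c(0, qr.coef(qr(D), meas[, 1]))
  sy <- c(0, qr.coef(qr(D), meas[, 2]))
  centers <- (head(bounds, -1) + tail(bounds, -1) + 1) / 2
  structure(list(centers = centers, dx_nm = sx * bin_nm, dy_nm = sy * bin_nm,
                 frame_range = fr, bin_nm = bin_nm),
            class = "drift_trace")
}

#' Evaluate a drift trace at given frames
#' @param trace a `drift_trace`.
#' @param frames integer frame indices.
#' @return n x 2 matrix of xy shifts (nm).
#' @export
drift_at <- function(trace, frames) {
  stopifnot(inherits(trace, "drift_trace"))
  cbind(dx_nm = lin_interp_extrap(trace$centers, trace$dx_nm, frames),
        dy_nm = lin_interp_extrap(trace$centers, trace$dy_nm, frames))
}

#' Build a drift trace from explicit knots
#'
#' Useful for tests and for serializing externally measured drift.
#' @param centers frame indices of the knots.
#' @param dx_nm,dy_nm shifts at the knots (nm).
#' @return a `drift_trace`.
#' @export
drift_trace <- function(centers, dx_nm, dy_nm) {
  stopifnot(length(centers) == length(dx_nm), length(dx_nm) == length(dy_nm),
            all(is.finite(dx_nm)), all(is.finite(dy_nm)))
  structure(list(centers = centers, dx_nm = dx_nm, dy_nm = dy_nm,
                 frame_range = range(centers), bin_nm = NA_real_),
            class = "drift_trace")
}

#' Correct a localization table for drift
#'
#' Subtracts the interpolated per-frame shift from each record.
#' @param table localization data.frame.
#' @param trace a `drift_trace`.
#' @return corrected table.
#' @export
correct_drift <- function(table, trace) {
  if (nrow(table) == 0) return(table)
  if (any(table$frame < trace$frame_range[1] - 0.5 |
          table$frame > trace$frame_range[2] + 0.5))
    stop("table contains frames outside the drift trace's frame range")
  s <- drift_at(trace, table$frame)
  table$x_nm <- table$x_nm - s[, 1]
  table$y_nm <- table$y_nm - s[, 2]
  table
}
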