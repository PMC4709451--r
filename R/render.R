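# Super-resolution reconstruction: nearest-pixel binning on a 10 nm
# raster, intensity weighted, with optional display-only Gaussian blur.

#' Reconstruct a super-resolution image from a localization table
#'
#' Each localization adds its weight (its intensity, or 1 when
#' `weighting = "count"`) to the raster pixel containing it.  Bins are
#' half-open `[k*raster, (k+1)*raster)`; the image origin snaps to raster
#' multiples covering all localizations.  No per-localization kernel is
#' applied: blurring, if any, is a separate display step
#' ([sr_gaussian_blur()]), and all COM analyses operate on the raw image.
#'
#' @param table non-empty localization data.frame.
#' @param raster_nm pixel raster (nm, default 10).
#' @param weighting `"intensity"` (default) or `"count"`.
#' @param channel channel id stored in the image metadata.
#' @return an `sr_image`: list with `data` (matrix, rows = y), `origin_nm`
#'   (xy of the lower-left pixel edge), `raster_nm`, `channel`,
#'   `blur_sigma_nm` (0 = raw).
#' @export
render_sr_image <- function(table, raster_nm = 10,
                            weighting = c("intensity", "count"),
                            channel = NA) {
  weighting <- match.arg(weighting)
  if (nrow(table) == 0) stop("empty localization table: nothing to render")
  stopifnot(raster_nm > 0)
  ix <- floor(table$x_nm / raster_nm)
  iy <- floor(table$y_nm / raster_nm)
  x0 <- min(ix); y0 <- min(iy)
  nx <- max(ix) - x0 + 1
  ny <- max(iy) - y0 + 1
  w <- if (weighting == "intensity") table$intensity else rep(1, nrow(table))
  m <- matrix(0, ny, nx)
  idx <- (ix - x0) * ny + (iy - y0) + 1
  acc <- rowsum(w, idx)
  m[as.integer(rownames(acc))] <- acc[, 1]
  structure(list(data = m, origin_nm = c(x0, y0) * raster_nm,
                 raster_nm = raster_nm, channel = channel,
                 blur_sigma_nm = 0, weighting = weighting),
            class = "sr_image")
}

# separable reflective-boundary convolution with a normalized kernel
reflect_conv <- function(m, kernel) {
  r <- (length(kernel) - 1) / 2
  pad_idx <- function(n) c(r:1, 1:n, n:(n - r + 1))
  conv1 <- function(mat) {
    # convolve down the rows
    n <- nrow(mat)
    if (r >= n) stop("blur kernel larger than image")
    p <- mat[pad_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (k in seq_along(kernel))
      out <- out + kernel[k] * p[(k - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Gaussian blur of a super-resolution image (display only)
#'
#' Convolution with an isotropic Gaussian (sigma in raster units =
#' `sigma_nm / raster_nm`), reflective boundary, total intensity conserved.
#' Blurring an already blurred image is refused: the COM distance analysis
#' must run on raw reconstructions, and a recorded `blur_sigma_nm > 0`
#' marks an image as display-processed.
#'
#' @param img an `sr_image` with `blur_sigma_nm == 0`.
#' @param sigma_nm Gaussian sigma (nm, default 10).
#' @return blurred `sr_image` with `blur_sigma_nm` recorded.
#' @export
sr_gaussian_blur <- function(img, sigma_nm = 10) {
  stopifnot(inherits(img, "sr_image"), sigma_nm > 0)
  if (img$blur_sigma_nm > 0)
    stop("image is already blurred; blur must only be applied once, to raw data")
  s <- sigma_nm / img$raster_nm
  r <- max(1, ceiling(4 * s))
  k <- exp(-((-r:r)^2) / (2 * s^2))
  k <- k / sum(k)
  img$data <- reflect_conv(img$data, k)
  img$blur_sigma_nm <- sigma_nm
  img
}

#' Intensity-weighted center of mass of a super-resolution image
#' @param img an `sr_image`.
#' @return xy COM in nm (pixel-center convention).
#' @export
sr_com <- function(img) {
  m <- img$data
  tot <- sum(m)
  if (tot <= 0) stop("image has non-positive total intensity")
  xs <- img$origin_nm[1] + (seq_len(ncol(m)) - 0.5) * img$raster_nm
  ys <- img$origin_nm[2] + (seq_len(nrow(m)) - 0.5) * img$raster_nm
  c(x_nm = sum(colSums(m) * xs) / tot, y_nm = sum(rowSums(m) * ys) / tot)
}
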