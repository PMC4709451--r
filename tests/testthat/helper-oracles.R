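# Independent oracles and fixture builders (all in code; no stored data).

# brute-force per-pixel sliding median subtraction (truncated window)
brute_median_subtract <- function(stack, window) {
  h <- (window - 1) / 2
  d <- dim(stack)
  out <- array(0, d)
  for (iy in seq_len(d[1])) {
    for (ix in seq_len(d[2])) {
      ts <- stack[iy, ix, ]
      for (t in seq_len(d[3])) {
        w <- ts[max(1, t - h):min(d[3], t + h)]
        out[iy, ix, t] <- ts[t] - median(w)
      }
    }
  }
  out
}

# minimal localization table builder
loc_table <- function(x, y, intensity = 1, channel = 1, frame = 1,
                      width_nm = 150, asymmetry = 1.1) {
  n <- length(x)
  data.frame(frame = rep_len(frame, n), x_nm = x, y_nm = y,
             intensity = rep_len(intensity, n),
             width_nm = rep_len(width_nm, n),
             asymmetry = rep_len(asymmetry, n),
             channel = rep_len(channel, n))
}

# dense brute-force windowed cross-correlation of two point sets binned at
# bin_nm; returns the integer (dx, dy) bin shift maximizing the correlation
brute_xcorr_argmax <- function(x1, y1, x2, y2, bin_nm, m) {
  b1 <- cbind(floor(x1 / bin_nm), floor(y1 / bin_nm))
  b2 <- cbind(floor(x2 / bin_nm), floor(y2 / bin_nm))
  rng_x <- range(c(b1[, 1], b2[, 1])); rng_y <- range(c(b1[, 2], b2[, 2]))
  nx <- diff(rng_x) + 1; ny <- diff(rng_y) + 1
  A <- matrix(0, ny, nx); B <- matrix(0, ny, nx)
  for (i in seq_len(nrow(b1)))
    A[b1[i, 2] - rng_y[1] + 1, b1[i, 1] - rng_x[1] + 1] <-
      A[b1[i, 2] - rng_y[1] + 1, b1[i, 1] - rng_x[1] + 1] + 1
  for (i in seq_len(nrow(b2)))
    B[b2[i, 2] - rng_y[1] + 1, b2[i, 1] - rng_x[1] + 1] <-
      B[b2[i, 2] - rng_y[1] + 1, b2[i, 1] - rng_x[1] + 1] + 1
  best <- c(NA, NA); bestv <- -Inf
  for (dx in -m:m) {
    for (dy in -m:m) {
      # C(dx, dy) = sum A(p) * B(p + d)
      ax <- max(1, 1 - dx):min(nx, nx - dx)
      ay <- max(1, 1 - dy):min(ny, ny - dy)
      if (length(ax) == 0 || length(ay) == 0) next
      v <- sum(A[ay, ax] * B[ay + dy, ax + dx])
      if (v > bestv) { bestv <- v; best <- c(dx, dy) }
    }
  }
  best
}

# integrated 2D Gaussian spot sampled on a pixel grid (oracle-side renderer,
# independent of the package's add_psf)
gauss_spot <- function(n_px, cx_px, cy_px, sd_px, photons) {
  xs <- 0:(n_px - 1)
  fx <- pnorm((xs + 1 - cx_px) / sd_px) - pnorm((xs - cx_px) / sd_px)
  fy <- pnorm((xs + 1 - cy_px) / sd_px) - pnorm((xs - cy_px) / sd_px)
  photons * outer(fy, fx)
}
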