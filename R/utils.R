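# internal geometry / numeric helpers

vec_norm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthonormal basis (e1, e2, u) with u the supplied unit axis
axis_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitize(cross3(u, ref))
  e2 <- cross3(u, e1)
  list(e1 = e1, e2 = e2, u = u)
}

# linear interpolation with linear extrapolation beyond the end knots
lin_interp_extrap <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (length(x) == 1) return(rep(y, length(xout)))
  out <- approx(x, y, xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[length(x)]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    n <- length(x)
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

# derive a child seed (< 2^31) from a base seed and a stream label
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
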