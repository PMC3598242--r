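# Internal array / histogram primitives shared across modules.

clamp01 <- function(x) pmin(1, pmax(0, x))

#' @noRd
round_half_up <- function(x, digits = 2) {
  # base round() is half-to-even; report parity needs half-up
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shift a 3D logical/numeric array by `by` voxels along axis `axis`,
# padding with `fill`. by > 0 moves content toward higher indices.
shift_array <- function(a, axis, by, fill = FALSE) {
  if (by == 0L) return(a)
  d <- dim(a)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    src <- seq_len(n - by); dst <- seq(by + 1, n)
  } else {
    src <- seq(1 - by, n); dst <- seq_len(n + by)
  }
  if (axis == 1L) out[dst, , ] <- a[src, , ]
  else if (axis == 2L) out[, dst, ] <- a[, src, ]
  else out[, , dst] <- a[, , src]
  out
}

# Binary erosion of a 3D mask by an axis-aligned box structuring element
# with half-widths `extent` (voxels per axis). Outside the array counts as
# background, so masks touching the array border erode there too.
erode_box <- function(mask, extent) {
  stopifnot(length(extent) == 3, all(extent >= 0))
  out <- mask
  for (axis in 1:3) {
    e <- extent[axis]
    if (e == 0L) next
    acc <- out
    for (s in seq_len(e)) {
      acc <- acc & shift_array(out, axis, s) & shift_array(out, axis, -s)
    }
    out <- acc
  }
  out
}

# Separable convolution of a 3D array with a 1D kernel along one axis,
# replicating the edge (constant extension) so flat regions stay flat.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  k <- length(kernel)
  half <- (k - 1L) / 2L
  # band matrix acting on the chosen axis
  K <- matrix(0, n, n)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kernel[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  res <- K %*% m
  ap2 <- array(res, dim = d[perm])
  aperm(ap2, order(perm))
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 3D separable Gaussian smoothing with per-axis sigmas (voxels).
gaussian_smooth3d <- function(a, sigma) {
  stopifnot(length(sigma) == 3)
  for (axis in 1:3) {
    if (sigma[axis] > 0) a <- conv_axis(a, gaussian_kernel(sigma[axis]), axis)
  }
  a
}

#' Otsu threshold of an intensity sample
#'
#' Picks the threshold maximizing the between-class variance of the two
#' classes it induces, on a fixed-width histogram of the values. Returned on
#' the intensity scale; values strictly greater than the threshold are
#' "above".
#'
#' @param x numeric vector of intensities (>= 2 distinct values).
#' @param levels number of histogram bins used for the search.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) {
    stop("degenerate intensity distribution: all values identical")
  }
  width <- diff(rng) / levels
  bin <- pmin(levels, floor((x - rng[1]) / width) + 1L)
  h <- tabulate(bin, nbins = levels)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(levels) - 0.5) * width
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-levels])  # threshold between bins k and k+1
  rng[1] + k * width
}
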