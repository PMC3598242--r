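#' Export a false-color overlay of a field
#'
#' Maximum-intensity projection (over z) of the two channels with the
#' conventional false colors — MeC green, DAPI blue — and optional
#' low-intensity sites shaded cyan, written as a PNG.
#'
#' @param stack a [volume_stack()].
#' @param path output PNG path.
#' @param sites optional logical 3D site volume (e.g. from [detect_sites()]);
#'   any voxel of a site column marks the projected pixel.
#' @param gamma display gamma applied to the normalized intensities.
#' @return invisibly, the path.
#' @export
export_overlay <- function(stack, path, sites = NULL, gamma = 0.7) {
  mip <- function(a) apply(a, c(1, 2), max)
  norm <- function(m) {
    m <- m - min(m)
    if (max(m) > 0) m <- m / max(m)
    m^gamma
  }
  g <- norm(mip(stack$mec))
  b <- norm(mip(stack$dapi))
  r <- matrix(0, nrow(g), ncol(g))
  if (!is.null(sites)) {
    if (!identical(dim(sites), dim(stack$mec))) stop("site/grid mismatch")
    sm <- mip(sites * 1) > 0
    # cyan shading: full green + blue where sites project
    g[sm] <- 1
    b[sm] <- 1
  }
  # PNG rasters are row-major from the top: transpose image x/y
  img <- array(0, dim = c(ncol(g), nrow(g), 3))
  img[, , 1] <- t(r); img[, , 2] <- t(g); img[, , 3] <- t(b)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(img, path)
  invisible(path)
}
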