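# Shared fixture builders. Unit tests use small nuclei / fields so the suite
# stays fast; geometry-sensitive calibration checks use the package defaults.

# A compact field holding one small nucleus.
tiny_spec <- function(seed = 1L, dim = c(72L, 72L, 20L), ...) {
  field_spec(dim = dim, seed = seed, ...)
}

tiny_field <- function(seed = 1L, dose = 0, n = 1L, dim = c(72L, 72L, 20L),
                       ...) {
  spec <- field_spec(dim = dim, n_nuclei = n, seed = seed)
  generate_field(spec, dose = dose, semi_axes_range = c(2.0, 2.4), ...)
}

tiny_seg_config <- function(...) segmentation_config(min_volume = 5, ...)

# Hand-built nucleus_region over an arbitrary mask, for tests that bypass
# segmentation.
fake_region <- function(mask, stack, label = 1L) {
  vox <- which(mask)
  structure(list(
    label = as.integer(label), voxels = as.integer(vox),
    dim = dim(mask), volume_voxels = length(vox),
    volume_um3 = length(vox) * prod(stack$voxel_size),
    touches_border = FALSE, voxel_size = stack$voxel_size,
    signals = cbind(mec = as.numeric(stack$mec[vox]),
                    dapi = as.numeric(stack$dapi[vox]))
  ), class = "nucleus_region")
}

# Random blobby 3D mask (union of a few solid ellipsoids), always non-empty.
random_mask <- function(dim = c(24L, 24L, 12L)) {
  m <- array(FALSE, dim = dim)
  for (b in seq_len(sample(1:3, 1))) {
    ctr <- sapply(dim, function(d) runif(1, d * 0.3, d * 0.7))
    ax <- sapply(dim, function(d) runif(1, d * 0.12, d * 0.3))
    x <- ((1:dim[1]) - ctr[1]) / ax[1]
    y <- ((1:dim[2]) - ctr[2]) / ax[2]
    z <- ((1:dim[3]) - ctr[3]) / ax[3]
    m <- m | (outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1)
  }
  if (!any(m)) m[dim[1] %/% 2, dim[2] %/% 2, dim[3] %/% 2] <- TRUE
  m
}

# Codistribution from a bare count matrix (for KL closed-form checks).
hist_from_counts <- function(counts, range = list(mec = c(0, 1),
                                                  dapi = c(0, 1))) {
  counts <- as.matrix(counts)
  structure(list(counts = counts, mass = counts / sum(counts),
                 bins = dim(counts), range = range,
                 n_voxels = sum(counts)),
            class = "codistribution")
}
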