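# Synthetic two-channel (MeC / DAPI) 3D nucleus-image generator with ground
# truth. The forward model is an axis-aligned ellipsoid with a shared radial
# intensity gradient, multiplicative chromatin texture, heterochromatin blobs
# present in both channels, and channel-specific demethylation attenuation:
# at dose 0 only the outermost rim_low_fraction of the nuclear volume carries
# attenuated MeC/DAPI; as the abstract dose grows toward 1 the attenuated
# region spreads inward, with heterochromatin blob MeC attenuated last.

#' Nucleus model for the synthetic generator
#'
#' Describes one nucleus to be rendered into a field: geometry, base channel
#' intensities, heterochromatin blob texture, the untreated low-intensity rim,
#' and the abstract demethylation dose in \code{[0, 1]}.
#'
#' @param center voxel coordinates (x, y, z) of the nucleus center.
#' @param semi_axes ellipsoid semi-axes in micrometers (x, y, z); all > 0.
#' @param base_mec,base_dapi base channel intensity levels (counts) before
#'   noise; must fit the configured bit depth after noise.
#' @param blob_count number of heterochromatin blobs.
#' @param blob_radius blob radius in micrometers.
#' @param blob_intensity multiplicative blob intensity (applied to both
#'   channels, so the MeC/DAPI ratio is blob-free in the untreated state).
#' @param rim_low_fraction fraction of nuclear volume (outermost) carrying
#'   reduced MeC/DAPI in the untreated state; in \code{[0, 1]}.
#' @param dose abstract demethylation dose in \code{[0, 1]}; 0 = untreated.
#' @param texture_sd sd (log scale) of the shared multiplicative chromatin
#'   texture.
#' @param grad_strength strength of the shared radial intensity decline
#'   (fractional drop at the nuclear border before attenuation).
#' @param grad_power radial power of that decline; higher values flatten the
#'   interior and concentrate the drop near the border.
#' @param mec_low_factor MeC attenuation floor: fully demethylated voxels
#'   retain this fraction of their untreated intensity.
#' @param dapi_low_factor analogous floor for the DAPI (LID) attenuation.
#' @param patch_prob maximum per-voxel probability of discrete demethylation
#'   patches inside the attenuated region.
#' @param patch_depth fractional intensity drop of a patch voxel.
#' @param lid_gain fraction of the non-rim volume that the DAPI-attenuated
#'   region gains at saturating dose.
#' @param lid_dose_sat dose at which the DAPI attenuation saturates (the DAPI
#'   reorganization happens at low doses and then plateaus).
#' @param blob_dose_delay dose below which heterochromatin blob MeC is
#'   protected from attenuation (blobs are attenuated last).
#' @param ramp_flatten how strongly the radial attenuation ramp flattens
#'   toward spatially uniform demethylation as dose approaches 1.
#' @param atten_volume_max volume fraction the MeC-attenuated region reaches
#'   at dose 1; below 1 a bright core survives the highest dose (compact
#'   heterochromatin retains its conformation at cytotoxic doses).
#' @return an object of class \code{nucleus_model}.
#' @export
nucleus_model <- function(center,
                          semi_axes = c(6.4, 6.4, 2.8),
                          base_mec = 900,
                          base_dapi = 1100,
                          blob_count = 12L,
                          blob_radius = 0.5,
                          blob_intensity = 1.8,
                          rim_low_fraction = 0.15,
                          dose = 0,
                          texture_sd = 0.05,
                          grad_strength = 0.5,
                          grad_power = 3,
                          mec_low_factor = 0.35,
                          dapi_low_factor = 0.8,
                          patch_prob = 0.55,
                          patch_depth = 0.45,
                          lid_gain = 0.4,
                          lid_dose_sat = 0.25,
                          blob_dose_delay = 0.5,
                          ramp_flatten = 0.45,
                          atten_volume_max = 0.85) {
  stopifnot(length(center) == 3, length(semi_axes) == 3)
  if (any(semi_axes <= 0)) stop("semi_axes must all be > 0")
  if (rim_low_fraction < 0 || rim_low_fraction > 1) {
    stop("rim_low_fraction must lie in [0, 1]")
  }
  if (dose < 0 || dose > 1) stop("dose must lie in [0, 1]")
  if (base_mec <= 0 || base_dapi <= 0) stop("base levels must be > 0")
  structure(list(
    center = as.numeric(center), semi_axes = as.numeric(semi_axes),
    base_mec = base_mec, base_dapi = base_dapi,
    blob_count = as.integer(blob_count), blob_radius = blob_radius,
    blob_intensity = blob_intensity,
    rim_low_fraction = rim_low_fraction, dose = dose,
    texture_sd = texture_sd, grad_strength = grad_strength,
    grad_power = grad_power,
    mec_low_factor = mec_low_factor, dapi_low_factor = dapi_low_factor,
    patch_prob = patch_prob, patch_depth = patch_depth,
    lid_gain = lid_gain, lid_dose_sat = lid_dose_sat,
    blob_dose_delay = blob_dose_delay, ramp_flatten = ramp_flatten,
    atten_volume_max = atten_volume_max
  ), class = "nucleus_model")
}

#' Field specification for the synthetic generator
#'
#' @param dim field extent in voxels (x, y, z).
#' @param voxel_size physical voxel size in micrometers (x, y, z). Default is
#'   the confocal acquisition geometry the analysis targets:
#'   0.116 x 0.116 x 0.2305 um.
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param min_separation minimum pairwise centroid distance in micrometers.
#' @param background mean background intensity (counts).
#' @param read_noise_sd sd of the additive Gaussian read noise (counts).
#' @param poisson apply Poisson shot noise to the signal.
#' @param bit_depth effective bit depth; intensities are clipped to
#'   \code{[0, 2^bit_depth - 1]} and stored as integers (16-bit containers).
#' @param seed integer seed; a fixed seed reproduces the field bit-exactly.
#' @return an object of class \code{field_spec}.
#' @export
field_spec <- function(dim = c(128L, 128L, 32L),
                       voxel_size = c(0.116, 0.116, 0.2305),
                       n_nuclei = 1L,
                       min_separation = 2,
                       background = 30,
                       read_noise_sd = 8,
                       poisson = TRUE,
                       bit_depth = 12L,
                       seed = 1L) {
  stopifnot(length(dim) == 3, length(voxel_size) == 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be strictly positive")
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  structure(list(
    dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
    n_nuclei = as.integer(n_nuclei), min_separation = min_separation,
    background = background, read_noise_sd = read_noise_sd,
    poisson = isTRUE(poisson), bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  ), class = "field_spec")
}

# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Attenuation ramp: inner radius of the attenuated region for a volume
# fraction f, and the per-voxel demethylation degree S in [0, 1] rising
# linearly from the region's inner edge to the nuclear surface.
atten_ramp <- function(r, vol_fraction) {
  if (vol_fraction <= 0) return(numeric(length(r)) * 0)
  rho <- (1 - vol_fraction)^(1 / 3)
  if (rho >= 1) return(numeric(length(r)) * 0)
  clamp01((r - rho) / (1 - rho))
}

#' Render one nucleus into clean (noise-free) channel subvolumes
#'
#' Computes the noiseless truth for a single nucleus on its bounding box:
#' both channel intensities, the voxel mask, the LIM/LID attenuation truth
#' labels, and summary truth statistics. Randomness (texture, blob placement,
#' demethylation patches) is drawn from the current RNG stream.
#'
#' @param model a [nucleus_model()].
#' @param spec a [field_spec()] (supplies voxel size, field bounds, bit depth).
#' @return list with elements \code{bbox} (6 integers: x0,x1,y0,y1,z0,z1),
#'   \code{mask}, \code{mec}, \code{dapi} (arrays on the bounding box),
#'   \code{lim_truth}, \code{lid_truth} (logical arrays), \code{r}
#'   (normalized ellipsoidal radius), and \code{stats} (true mean MeC/DAPI,
#'   volume, truth interior-LIM fraction).
#' @export
render_nucleus <- function(model, spec) {
  v <- spec$voxel_size
  a <- model$semi_axes
  c_vox <- model$center
  half <- ceiling(a / v) + 1L
  lo <- floor(c_vox - half)
  hi <- ceiling(c_vox + half)
  if (any(lo < 1L) || any(hi > spec$dim)) {
    stop("nucleus ellipsoid does not fit within field bounds")
  }
  nx <- hi[1] - lo[1] + 1L; ny <- hi[2] - lo[2] + 1L; nz <- hi[3] - lo[3] + 1L
  xs <- ((lo[1]:hi[1]) - c_vox[1]) * v[1] / a[1]
  ys <- ((lo[2]:hi[2]) - c_vox[2]) * v[2] / a[2]
  zs <- ((lo[3]:hi[3]) - c_vox[3]) * v[3] / a[3]
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  r <- sqrt(r2)
  mask <- r <= 1
  n_in <- sum(mask)
  if (n_in == 0L) stop("nucleus contains no voxels at this voxel size")
  rin <- r[mask]

  # shared structure: radial gradient, soft optical edge, chromatin texture
  G <- 1 - model$grad_strength * rin^model$grad_power
  E <- clamp01((1 - rin) / 0.03)
  Tx <- exp(stats::rnorm(n_in, 0, model$texture_sd))

  # heterochromatin blobs, interior (r < 0.55), identical in both channels
  beta <- numeric(n_in)
  if (model$blob_count > 0L) {
    idx <- which(mask)
    coord <- arrayInd(idx, dim(mask))
    pos_um <- cbind((coord[, 1] + lo[1] - 1 - c_vox[1]) * v[1],
                    (coord[, 2] + lo[2] - 1 - c_vox[2]) * v[2],
                    (coord[, 3] + lo[3] - 1 - c_vox[3]) * v[3])
    placed <- 0L
    sigma <- model$blob_radius * 0.6
    while (placed < model$blob_count) {
      p <- stats::runif(3, -1, 1)
      if (sum(p^2) > 1) next
      ctr <- p * 0.55 * a
      d2 <- (pos_um[, 1] - ctr[1])^2 + (pos_um[, 2] - ctr[2])^2 +
        (pos_um[, 3] - ctr[3])^2
      beta <- pmax(beta, exp(-d2 / (2 * sigma^2)))
      placed <- placed + 1L
    }
  }
  B <- 1 + (model$blob_intensity - 1) * beta

  base <- G * E * Tx * B
  d <- model$dose
  rim <- model$rim_low_fraction

  # MeC attenuation: region grows inward with dose and its radial ramp
  # flattens toward uniform coverage at saturating dose; blobs are delayed
  ramp_power <- function(dd) 1 - model$ramp_flatten * dd
  fmax <- model$atten_volume_max
  f_mec <- rim + d * (fmax - rim)
  S_plain <- atten_ramp(rin, f_mec)^ramp_power(d)
  d_blob <- clamp01((d - model$blob_dose_delay) / (1 - model$blob_dose_delay))
  S_blob <- atten_ramp(rin, rim + d_blob * (fmax - rim))^ramp_power(d_blob)
  S <- S_plain * (1 - beta) + S_blob * beta
  U <- stats::runif(n_in)
  patch <- U < model$patch_prob * S
  mec_in <- model$base_mec * base *
    (1 - (1 - model$mec_low_factor) * S) *
    ifelse(patch, 1 - model$patch_depth, 1)

  # DAPI attenuation: saturates at low dose, then plateaus
  f_dapi <- rim + model$lid_gain * (1 - rim) * clamp01(d / model$lid_dose_sat)
  S_D <- atten_ramp(rin, f_dapi)
  U_D <- stats::runif(n_in)
  patch_d <- U_D < model$patch_prob * S_D
  dapi_in <- model$base_dapi * base *
    (1 - (1 - model$dapi_low_factor) * S_D) *
    ifelse(patch_d, 1 - model$patch_depth * 0.7, 1)

  mec <- array(0, dim = c(nx, ny, nz)); mec[mask] <- mec_in
  dapi <- array(0, dim = c(nx, ny, nz)); dapi[mask] <- dapi_in
  lim_truth <- array(FALSE, dim = c(nx, ny, nz)); lim_truth[mask] <- S > 0
  lid_truth <- array(FALSE, dim = c(nx, ny, nz)); lid_truth[mask] <- S_D > 0

  interior <- rin < 0.5^(1 / 3)  # inner half of the nuclear volume
  n_lim <- sum(S > 0)
  list(
    bbox = c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3]),
    mask = mask, mec = mec, dapi = dapi,
    lim_truth = lim_truth, lid_truth = lid_truth, r = r,
    stats = list(
      volume_voxels = n_in,
      true_mean_mec = mean(mec_in),
      true_mean_dapi = mean(dapi_in),
      lim_truth_voxels = n_lim,
      interior_lim_fraction = if (n_lim > 0) sum(S > 0 & interior) / n_lim else NA_real_
    )
  )
}

#' Sample nucleus models with placement for a field
#'
#' Draws per-nucleus geometry and base-level variability and places the
#' nuclei so that every ellipsoid fits the field and pairwise centroid
#' distances respect \code{spec$min_separation} plus per-axis bounding-box
#' non-overlap. Placement failure after \code{max_retries} attempts raises an
#' error naming the failing nucleus index.
#'
#' @param spec a [field_spec()].
#' @param n number of nuclei (defaults to \code{spec$n_nuclei}).
#' @param dose demethylation dose applied to all nuclei.
#' @param semi_axes_range range (um) for the in-plane semi-axes; the axial
#'   semi-axis is drawn at 0.55-0.65 of the in-plane value.
#' @param base_mec,base_dapi population-mean base levels (counts).
#' @param base_cv lognormal coefficient of variation of per-nucleus base
#'   levels.
#' @param max_retries placement attempts per nucleus.
#' @param ... passed to [nucleus_model()].
#' @return list of [nucleus_model()] objects.
#' @export
sample_nucleus_models <- function(spec, n = spec$n_nuclei, dose = 0,
                                  semi_axes_range = c(6.3, 6.5),
                                  base_mec = 900, base_dapi = 1100,
                                  base_cv = 0.08, max_retries = 200L, ...) {
  v <- spec$voxel_size
  models <- vector("list", n)
  centers <- matrix(numeric(0), ncol = 3)
  axes <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      ax_xy <- stats::runif(1, semi_axes_range[1], semi_axes_range[2])
      ax <- c(ax_xy, ax_xy * stats::runif(1, 0.97, 1.03),
              ax_xy * stats::runif(1, 0.42, 0.45))
      margin <- ceiling(ax / v) + 2L
      if (any(spec$dim - 2 * margin < 1)) {
        stop(sprintf("nucleus %d cannot fit: field too small for semi-axes", i))
      }
      ctr <- mapply(function(m, d) stats::runif(1, m + 1, d - m),
                    margin, spec$dim)
      sep_ok <- TRUE
      if (nrow(centers) > 0) {
        d_um <- sqrt(colSums((t(centers) - ctr)^2 * v^2))
        box_gap <- vapply(seq_len(nrow(centers)), function(j) {
          any(abs(centers[j, ] - ctr) * v > (axes[j, ] + ax))
        }, logical(1))
        sep_ok <- all(d_um >= spec$min_separation) && all(box_gap)
      }
      if (sep_ok) {
        centers <- rbind(centers, ctr)
        axes <- rbind(axes, ax)
        lvl <- exp(stats::rnorm(1, 0, base_cv))
        models[[i]] <- nucleus_model(center = ctr, semi_axes = ax,
                                     base_mec = base_mec * lvl,
                                     base_dapi = base_dapi * lvl,
                                     dose = dose, ...)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("placement failed for nucleus %d after %d retries",
                   i, max_retries))
    }
  }
  models
}

#' Generate a full synthetic two-channel field with ground truth
#'
#' Renders all nuclei into a field, adds the background and the configured
#' noise (Poisson shot noise on the signal plus Gaussian read noise), and
#' quantizes to integers within the configured bit depth. The same
#' \code{spec$seed} reproduces the field bit-exactly.
#'
#' @param spec a [field_spec()].
#' @param models optional list of [nucleus_model()]; drawn via
#'   [sample_nucleus_models()] when omitted.
#' @param dose dose forwarded to [sample_nucleus_models()] when models are
#'   drawn here.
#' @param store_clean keep the noiseless truth channels in the result.
#' @param ... passed to [sample_nucleus_models()].
#' @return list with \code{stack} (a [volume_stack()]) and \code{truth}
#'   (label array, per-nucleus truth table, LIM/LID truth label arrays, the
#'   models, and optionally the clean channels).
#' @export
generate_field <- function(spec, models = NULL, dose = 0,
                           store_clean = TRUE, ...) {
  with_seed(spec$seed, {
    if (is.null(models)) {
      models <- sample_nucleus_models(spec, dose = dose, ...)
    }
    clean <- generate_field_clean(spec, models)
    noisify <- function(x) {
      y <- if (spec$poisson) {
        array(stats::rpois(length(x), lambda = x), dim = dim(x))
      } else x
      y <- y + round(stats::rnorm(length(x), 0, spec$read_noise_sd))
      array(as.integer(pmin(2^spec$bit_depth - 1, pmax(0, y))), dim = dim(x))
    }
    stack <- volume_stack(mec = noisify(clean$clean_mec),
                          dapi = noisify(clean$clean_dapi),
                          voxel_size = spec$voxel_size,
                          bit_depth = spec$bit_depth)
    truth <- clean$truth
    if (!store_clean) {
      truth$clean_mec <- NULL
      truth$clean_dapi <- NULL
    }
    list(stack = stack, truth = truth)
  })
}

#' Generate a synthetic dose series with a recovery manifest
#'
#' One condition per dose; each condition accumulates
#' \code{n_nuclei_per_dose} nuclei over as many fields as needed (with the
#' default geometry a 128 x 128 x 32 field holds one nucleus). Nucleus
#' geometry, texture and demethylation-patch draws are re-seeded per nucleus
#' index so that conditions share placements: across doses the noiseless
#' fields differ only through each channel's attenuation truth region.
#'
#' @param doses ascending, duplicate-free dose levels in \code{[0, 1]}.
#' @param n_nuclei_per_dose nuclei per condition.
#' @param spec base [field_spec()]; its seed is combined with dose and
#'   nucleus indices.
#' @param seed integer series seed (overrides \code{spec$seed}).
#' @param outdir optional directory; when given, every field is written as
#'   per-channel multi-page TIFFs plus a label TIFF, and the manifest as JSON.
#' @param vary_noise_by_dose draw a different noise realization per dose
#'   (placements still shared); when FALSE the noise substream is also shared.
#' @param keep_arrays keep the full truth arrays (labels, LIM/LID truth,
#'   clean channels) on every field; disable for long series to save memory.
#' @param ... forwarded to [sample_nucleus_models()] /[nucleus_model()].
#' @return list with \code{fields} (list of per-dose lists of
#'   [generate_field()] results) and \code{manifest} (per-dose truth: true
#'   mean MeC, normalized true mean MeC, truth interior-LIM fraction).
#' @export
generate_dose_series <- function(doses, n_nuclei_per_dose = 30L,
                                 spec = field_spec(), seed = spec$seed,
                                 outdir = NULL, vary_noise_by_dose = TRUE,
                                 keep_arrays = TRUE, ...) {
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be sorted ascending without duplicates")
  }
  if (any(doses < 0 | doses > 1)) stop("doses must lie in [0, 1]")
  fields <- vector("list", length(doses))
  names(fields) <- paste0("dose_", doses)
  man_rows <- vector("list", length(doses))
  for (k in seq_along(doses)) {
    per <- vector("list", n_nuclei_per_dose)
    truths <- vector("list", n_nuclei_per_dose)
    for (i in seq_len(n_nuclei_per_dose)) {
      f <- dose_series_field(spec, seed, k, i, doses[k],
                             vary_noise_by_dose = vary_noise_by_dose, ...)
      truths[[i]] <- f$truth$per_nucleus
      if (!is.null(outdir)) {
        dir <- file.path(outdir, sprintf("dose_%g", doses[k]))
        write_field(f, dir, prefix = sprintf("nucleus_%03d", i))
      }
      if (!keep_arrays) {
        f$truth[c("labels", "lim_truth", "lid_truth",
                  "clean_mec", "clean_dapi")] <- NULL
      }
      per[[i]] <- f
    }
    tt <- do.call(rbind, truths)
    man_rows[[k]] <- data.frame(
      dose = doses[k], n_nuclei = n_nuclei_per_dose,
      true_mean_mec = mean(tt$true_mean_mec),
      true_mean_dapi = mean(tt$true_mean_dapi),
      true_interior_lim_fraction =
        mean(tt$interior_lim_fraction, na.rm = TRUE)
    )
    fields[[k]] <- per
  }
  manifest <- do.call(rbind, man_rows)
  manifest$true_norm_mean_mec <-
    manifest$true_mean_mec / manifest$true_mean_mec[1]
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(fields = fields, manifest = manifest)
}

#' Generate one nucleus field of a dose series
#'
#' Deterministic addressing of the series: nucleus \code{i} of dose index
#' \code{k} draws its geometry, texture and demethylation patches from a
#' substream keyed by \code{(seed, i)} only, so the same nucleus is rendered
#' with identical placement at every dose and the noiseless channels differ
#' across doses only inside the attenuation truth regions. Noise is keyed by
#' \code{(seed, i, k)} (or by \code{(seed, i)} when
#' \code{vary_noise_by_dose = FALSE}).
#'
#' @param spec base [field_spec()].
#' @param seed series seed.
#' @param k dose index (1-based).
#' @param i nucleus index within the dose (1-based).
#' @param dose dose level in \code{[0, 1]}.
#' @param vary_noise_by_dose see [generate_dose_series()].
#' @param ... forwarded to [sample_nucleus_models()].
#' @return a [generate_field()]-shaped list.
#' @export
dose_series_field <- function(spec, seed, k, i, dose,
                              vary_noise_by_dose = TRUE, ...) {
  sp <- spec
  sp$seed <- as.integer((seed + 131L * i) %% 2147483647L)
  noise_seed <- if (vary_noise_by_dose) {
    as.integer((seed + 131L * i + 7919L * k) %% 2147483647L)
  } else sp$seed
  with_seed(sp$seed, {
    models <- sample_nucleus_models(sp, n = 1L, dose = dose, ...)
    field_from_models(sp, models, noise_seed)
  })
}

# Render given models (already drawn) and apply noise with its own seed, so
# the geometry stream and the noise stream are decoupled.
field_from_models <- function(spec, models, noise_seed) {
  sp <- spec
  sp$seed <- as.integer(noise_seed)
  # generate_field re-seeds internally; geometry draws happen in render order,
  # so rendering must consume the same stream regardless of noise seed. We
  # render the clean field under the geometry seed, then add noise under the
  # noise seed.
  clean <- with_seed(spec$seed, {
    generate_field_clean(spec, models)
  })
  with_seed(noise_seed, {
    noisify <- function(x) {
      y <- if (spec$poisson) {
        array(stats::rpois(length(x), lambda = x), dim = dim(x))
      } else x
      y <- y + round(stats::rnorm(length(x), 0, spec$read_noise_sd))
      array(as.integer(pmin(2^spec$bit_depth - 1, pmax(0, y))), dim = dim(x))
    }
    stack <- volume_stack(mec = noisify(clean$clean_mec),
                          dapi = noisify(clean$clean_dapi),
                          voxel_size = spec$voxel_size,
                          bit_depth = spec$bit_depth)
    list(stack = stack, truth = clean$truth)
  })
}

# Noise-free rendering shared by generate_field / field_from_models.
generate_field_clean <- function(spec, models) {
  mec <- array(0, dim = spec$dim)
  dapi <- array(0, dim = spec$dim)
  labels <- array(0L, dim = spec$dim)
  lim_truth <- array(FALSE, dim = spec$dim)
  lid_truth <- array(FALSE, dim = spec$dim)
  rows <- vector("list", length(models))
  for (i in seq_along(models)) {
    rn <- render_nucleus(models[[i]], spec)
    b <- rn$bbox
    sx <- b[1]:b[2]; sy <- b[3]:b[4]; sz <- b[5]:b[6]
    mec[sx, sy, sz] <- mec[sx, sy, sz] + rn$mec
    dapi[sx, sy, sz] <- dapi[sx, sy, sz] + rn$dapi
    lab_sub <- labels[sx, sy, sz]; lab_sub[rn$mask] <- i
    labels[sx, sy, sz] <- lab_sub
    lim_truth[sx, sy, sz] <- lim_truth[sx, sy, sz] | rn$lim_truth
    lid_truth[sx, sy, sz] <- lid_truth[sx, sy, sz] | rn$lid_truth
    rows[[i]] <- data.frame(label = i, dose = models[[i]]$dose,
                            as.data.frame(rn$stats))
  }
  per_nucleus <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), dose = numeric(),
               volume_voxels = integer(), true_mean_mec = numeric(),
               true_mean_dapi = numeric(), lim_truth_voxels = integer(),
               interior_lim_fraction = numeric())
  list(
    clean_mec = mec + spec$background,
    clean_dapi = dapi + spec$background,
    truth = list(labels = labels,
                 per_nucleus = per_nucleus,
                 lim_truth = lim_truth, lid_truth = lid_truth,
                 models = models,
                 clean_mec = mec + spec$background,
                 clean_dapi = dapi + spec$background)
  )
}

#' Target band for the untreated peripheral LIM fraction
#'
#' The generator defaults are calibrated so that an untreated population,
#' run through segmentation, site detection and erosion-shell profiling at
#' the package defaults, recovers a population-mean LIM half-fraction
#' (fraction of LIM sites in the peripheral half of the nuclear volume)
#' inside this band.
#'
#' @return numeric length-2 vector (lower, upper).
#' @export
lim_half_target <- function() c(0.80, 0.85)
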