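# Low-intensity site (LIM/LID) detection and radial shell profiling via
# iterative anisotropic morphological erosion. LIM uses the MeC channel and
# LID the DAPI channel through the same machinery.

#' Per-channel low-intensity-site thresholds
#'
#' \code{t_bcg} separates background-level from signal voxels; \code{t_Q}
#' separates low-amplitude from high-amplitude signal. Low-intensity sites
#' are the voxels strictly between the two.
#'
#' @param x in-nucleus intensities of one channel (>= 2 distinct values).
#' @param t_bcg_method \code{"otsu"} or a number used as-is.
#' @param t_q_method \code{"quantile"} of the above-background voxels.
#' @param t_q_quantile quantile used for \code{t_Q} (default the median).
#' @param background_reference intensities used for the Otsu background
#'   split. \code{t_bcg} plays the role of a background/signal separator, so
#'   its histogram must contain background: pass a sample that includes local
#'   background (e.g. the nucleus bounding box, as [nucleus_topology()]
#'   does). Defaults to \code{x} itself, which only works if \code{x} reaches
#'   down to background level.
#' @return list of class \code{threshold_pair}: \code{t_bcg}, \code{t_Q},
#'   with \code{0 <= t_bcg < t_Q} enforced.
#' @export
compute_thresholds <- function(x, t_bcg_method = "otsu",
                               t_q_method = "quantile",
                               t_q_quantile = 0.5,
                               background_reference = x) {
  x <- as.numeric(x)
  if (length(unique(x)) < 2) {
    stop("degenerate intensity distribution")
  }
  t_bcg <- if (is.numeric(t_bcg_method)) {
    t_bcg_method
  } else if (identical(t_bcg_method, "otsu")) {
    otsu_threshold(as.numeric(background_reference))
  } else stop("unknown t_bcg method")
  above <- x[x > t_bcg]
  if (length(above) < 2) stop("no above-background voxels for t_Q")
  t_q <- if (identical(t_q_method, "quantile")) {
    as.numeric(stats::quantile(above, t_q_quantile, type = 7))
  } else stop("unknown t_Q method")
  if (!(t_bcg < t_q)) stop("t_bcg < t_Q could not be established")
  structure(list(t_bcg = t_bcg, t_Q = t_q,
                 method = list(t_bcg = t_bcg_method, t_Q = t_q_method,
                               q = t_q_quantile)),
            class = "threshold_pair")
}

#' Detect low-intensity sites within a nucleus
#'
#' Site voxels are exactly the in-mask voxels with intensity strictly inside
#' the open interval \code{(t_bcg, t_Q)}.
#'
#' @param channel 3D intensity array.
#' @param mask logical 3D mask on the same grid.
#' @param thresholds a [compute_thresholds()] result (or list with
#'   \code{t_bcg}, \code{t_Q}).
#' @return logical 3D site volume.
#' @export
detect_sites <- function(channel, mask, thresholds) {
  if (!identical(dim(channel), dim(mask))) stop("mask/grid mismatch")
  mask & channel > thresholds$t_bcg & channel < thresholds$t_Q
}

#' Erosion step size in voxels
#'
#' Converts the physical per-axis erosion rate to voxel extents:
#' \code{round(step_um / voxel_size)} per axis with a minimum of 1.
#'
#' @param step_um physical erosion step per axis (micrometers); default the
#'   1.32 x 1.3 x 0.25 um rate used for confocal nuclei.
#' @param voxel_size voxel size per axis (micrometers).
#' @return integer per-axis extents.
#' @export
erosion_extent <- function(step_um = c(1.32, 1.3, 0.25),
                           voxel_size = c(0.116, 0.116, 0.2305)) {
  e <- as.integer(round(step_um / voxel_size))
  if (all(e < 1L)) {
    warning("erosion step below one voxel on every axis; clamped to 1")
  }
  pmax(e, 1L)
}

#' Iterative anisotropic erosion shells
#'
#' Erodes the nucleus mask with an axis-aligned box structuring element of
#' the per-axis voxel extents implied by the physical step, until the mask is
#' empty. Shell k is the set difference between erosion k-1 and erosion k
#' (outermost first); the shells partition the mask.
#'
#' @param mask logical 3D nucleus mask (non-empty).
#' @param step_um physical erosion step per axis.
#' @param voxel_size voxel size per axis.
#' @return list of class \code{erosion_shells}: \code{shells} (list of
#'   logical arrays, outermost first), \code{volumes} (voxel counts),
#'   \code{v_total}, \code{extent}.
#' @export
erode_shells <- function(mask, step_um = c(1.32, 1.3, 0.25),
                         voxel_size = c(0.116, 0.116, 0.2305)) {
  if (!any(mask)) stop("empty mask")
  ext <- erosion_extent(step_um, voxel_size)
  shells <- list()
  current <- mask
  while (any(current)) {
    eroded <- erode_box(current, ext)
    shell <- current & !eroded
    shells[[length(shells) + 1L]] <- shell
    current <- eroded
  }
  structure(list(shells = shells,
                 volumes = vapply(shells, sum, numeric(1)),
                 v_total = sum(mask),
                 extent = ext),
            class = "erosion_shells")
}

#' Cumulative radial site profile over erosion shells
#'
#' Cumulative site fraction versus cumulative volume fraction (V/V_tot),
#' periphery inward. The \code{half_fraction} is the cumulative site fraction
#' linearly interpolated at V/V_tot = 0.5: the fraction of sites in the
#' peripheral half of the nuclear volume (the LIM_0.5 / LID_0.5 statistic).
#' On the diagonal the sites are uniformly dense across the nucleus.
#'
#' @param shells an [erode_shells()] result.
#' @param sites logical site volume (subset of the nucleus mask).
#' @return object of class \code{shell_profile}: per-shell table, cumulative
#'   \code{curve} (\code{v_frac}, \code{site_frac}, starting at (0,0) and
#'   ending at (1,1)), \code{half_fraction}, \code{n_sites}, \code{no_sites}.
#'   With zero sites the profile is flagged \code{no_sites} and
#'   \code{half_fraction} is \code{NA} (missing, not 0).
#' @export
shell_profile <- function(shells, sites) {
  stopifnot(inherits(shells, "erosion_shells"))
  site_counts <- vapply(shells$shells, function(s) sum(s & sites), numeric(1))
  n_sites <- sum(site_counts)
  v_frac <- cumsum(shells$volumes) / shells$v_total
  if (n_sites == 0) {
    curve <- data.frame(v_frac = c(0, v_frac),
                        site_frac = rep(NA_real_, length(v_frac) + 1))
    return(structure(list(
      shells = data.frame(shell = seq_along(shells$volumes),
                          shell_volume_voxels = shells$volumes,
                          site_count = site_counts),
      v_total = shells$v_total, curve = curve,
      half_fraction = NA_real_, n_sites = 0, no_sites = TRUE
    ), class = "shell_profile"))
  }
  site_frac <- cumsum(site_counts) / n_sites
  curve <- data.frame(v_frac = c(0, v_frac), site_frac = c(0, site_frac))
  half <- stats::approx(curve$v_frac, curve$site_frac, xout = 0.5,
                        ties = "ordered")$y
  structure(list(
    shells = data.frame(shell = seq_along(shells$volumes),
                        shell_volume_voxels = shells$volumes,
                        site_count = site_counts),
    v_total = shells$v_total, curve = curve,
    half_fraction = half, n_sites = n_sites, no_sites = FALSE
  ), class = "shell_profile")
}

#' Interior site fraction
#'
#' Complement of the peripheral half-fraction: the fraction of sites in the
#' interior half of the nuclear volume.
#'
#' @param profile a [shell_profile()] result.
#' @return scalar in \code{[0, 1]}, or \code{NA} for a no-sites profile.
#' @export
interior_fraction <- function(profile) {
  stopifnot(inherits(profile, "shell_profile"))
  if (isTRUE(profile$no_sites)) return(NA_real_)
  1 - profile$half_fraction
}

#' Full LIM/LID topology of one nucleus
#'
#' Computes per-channel thresholds on the in-mask intensities, detects sites,
#' erodes shells once, and profiles both channels.
#'
#' @param stack a [volume_stack()].
#' @param region a \code{nucleus_region}.
#' @param step_um erosion step, see [erode_shells()].
#' @param t_q_quantile see [compute_thresholds()].
#' @return list with \code{lim} and \code{lid} (each: thresholds, profile)
#'   plus the shared \code{shells}.
#' @export
nucleus_topology <- function(stack, region, step_um = c(1.32, 1.3, 0.25),
                             t_q_quantile = 0.5) {
  m <- region_mask(region, crop = TRUE)
  off <- attr(m, "offset")
  d <- dim(m)
  sub <- function(a) a[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
                       off[3] + seq_len(d[3]), drop = FALSE]
  mec <- sub(stack$mec); dapi <- sub(stack$dapi)
  shells <- erode_shells(m, step_um, stack$voxel_size)
  one <- function(ch) {
    thr <- compute_thresholds(ch[m], t_q_quantile = t_q_quantile,
                              background_reference = ch)
    sites <- detect_sites(ch, m, thr)
    prof <- shell_profile(shells, sites)
    list(thresholds = thr, sites = sites, profile = prof)
  }
  list(lim = one(mec), lid = one(dapi), shells = shells)
}
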