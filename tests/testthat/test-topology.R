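test_that("Otsu threshold matches an exhaustive between-class search", {
  # hand-specified 8-level histogram
  x <- rep(c(0, 10, 20, 30, 100, 110, 120, 130),
           times = c(20, 30, 25, 10, 5, 12, 18, 9))
  t_pkg <- otsu_threshold(x, levels = 64)
  # brute force: candidate thresholds between sorted unique values, maximize
  # w0 * w1 * (mu0 - mu1)^2 directly on the data
  cand <- sort(unique(x))
  best <- -Inf; t_bf <- NA
  for (k in seq_len(length(cand) - 1)) {
    t <- (cand[k] + cand[k + 1]) / 2
    lo <- x[x <= t]; hi <- x[x > t]
    v <- (length(lo) / length(x)) * (length(hi) / length(x)) *
      (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; t_bf <- t }
  }
  # same induced partition
  expect_identical(x <= t_pkg, x <= t_bf)
  expect_error(otsu_threshold(rep(5, 10)), "degenerate")
})

test_that("threshold pair separates background and low amplitudes", {
  x <- c(rep(0, 50), rep(1000, 50))
  thr <- compute_thresholds(x)
  expect_gt(thr$t_bcg, 0)
  expect_lt(thr$t_bcg, 1000)
  expect_lt(thr$t_bcg, thr$t_Q)
  # t_Q median rule on above-background values {10, 20, 30, 40}
  thr2 <- compute_thresholds(c(0, 0, 10, 20, 30, 40), t_bcg_method = 5)
  expect_equal(thr2$t_bcg, 5)
  expect_equal(thr2$t_Q, 25)
  expect_error(compute_thresholds(rep(7, 4)), "degenerate")
})

test_that("site detection is the strict open interval (t_bcg, t_Q)", {
  ch <- array(0, dim = c(3, 3, 1))
  ch[1:3, 1, 1] <- c(5, 15, 25)
  mask <- array(FALSE, dim = c(3, 3, 1)); mask[1:3, 1, 1] <- TRUE
  sites <- detect_sites(ch, mask, list(t_bcg = 10, t_Q = 20))
  expect_equal(which(sites), 2L)  # only the 15-valued voxel
  # boundary values are excluded (open interval)
  sites2 <- detect_sites(ch, mask, list(t_bcg = 5, t_Q = 25))
  expect_equal(which(sites2), 2L)
  # everything at or above t_Q -> empty
  expect_equal(sum(detect_sites(ch, mask, list(t_bcg = 1, t_Q = 5))), 0)
  expect_error(detect_sites(ch, array(TRUE, dim = c(2, 2, 1)),
                            list(t_bcg = 1, t_Q = 5)), "mismatch")
})

test_that("physical erosion step converts to voxel extents", {
  expect_identical(erosion_extent(c(1.32, 1.3, 0.25),
                                  c(0.116, 0.116, 0.2305)),
                   c(11L, 11L, 1L))
  expect_warning(e <- erosion_extent(c(0.01, 0.01, 0.01), c(1, 1, 1)),
                 "clamped")
  expect_identical(e, c(1L, 1L, 1L))
})

test_that("erosion shells partition the mask", {
  single <- array(FALSE, dim = c(5, 5, 3)); single[3, 3, 2] <- TRUE
  sh <- erode_shells(single, voxel_size = c(0.116, 0.116, 0.2305))
  expect_length(sh$shells, 1)
  expect_equal(sh$volumes, 1)
  expect_error(erode_shells(array(FALSE, dim = c(3, 3, 3))), "empty")
  set.seed(99)
  for (i in 1:100) {
    m <- random_mask()
    sh <- erode_shells(m, step_um = c(0.3, 0.3, 0.25),
                       voxel_size = c(0.116, 0.116, 0.2305))
    expect_equal(sum(sh$volumes), sum(m))
    # disjoint union equals the mask, voxelwise
    acc <- array(0L, dim = dim(m))
    for (s in sh$shells) acc <- acc + s
    expect_true(all(acc[m] == 1L) && all(acc[!m] == 0L))
  }
})

test_that("shell profile follows uniform and rim-concentrated site layouts", {
  m <- array(TRUE, dim = c(40, 40, 8))
  sh <- erode_shells(m, step_um = c(0.3, 0.3, 0.25),
                     voxel_size = c(0.116, 0.116, 0.2305))
  # uniform density: every voxel a site -> curve exactly on the diagonal
  prof_u <- shell_profile(sh, m)
  expect_equal(prof_u$curve$site_frac, prof_u$curve$v_frac)
  expect_equal(prof_u$half_fraction, 0.5)
  expect_equal(prof_u$curve$v_frac[nrow(prof_u$curve)], 1)
  expect_equal(prof_u$curve$site_frac[nrow(prof_u$curve)], 1)
  # all sites in the outermost shell: cumulative curve saturates at v1
  prof_r <- shell_profile(sh, sh$shells[[1]])
  expect_equal(prof_r$curve$site_frac[2], 1)
  expect_equal(prof_r$half_fraction, 1)
  expect_true(all(diff(prof_r$curve$site_frac) >= 0))
  # no sites: flagged, half fraction missing (not 0)
  prof_0 <- shell_profile(sh, array(FALSE, dim = dim(m)))
  expect_true(prof_0$no_sites)
  expect_true(is.na(prof_0$half_fraction))
  expect_true(is.na(interior_fraction(prof_0)))
})

test_that("hand-built two-shell profile reaches 1 at 30% volume", {
  shells <- structure(list(
    shells = list(NULL, NULL), volumes = c(30, 70), v_total = 100,
    extent = c(1L, 1L, 1L)), class = "erosion_shells")
  # bypass the mask arithmetic: site counts per shell given directly
  sh1 <- array(FALSE, dim = c(10, 10, 1)); sh1[1:30] <- TRUE
  sh2 <- array(FALSE, dim = c(10, 10, 1)); sh2[31:100] <- TRUE
  shells$shells <- list(sh1, sh2)
  prof <- shell_profile(shells, sh1)  # all sites in the outermost shell
  expect_equal(prof$curve$v_frac, c(0, 0.3, 1))
  expect_equal(prof$curve$site_frac, c(0, 1, 1))
  expect_equal(prof$half_fraction, 1)
  expect_equal(interior_fraction(prof), 0)
})

test_that("half fraction equals a brute-force shell-index count", {
  set.seed(17)
  for (i in 1:10) {
    m <- random_mask(dim = c(12L, 12L, 8L))  # about 10^2-10^3 voxels
    sh <- erode_shells(m, step_um = c(0.3, 0.3, 0.25),
                       voxel_size = c(0.116, 0.116, 0.2305))
    sites <- m & array(runif(length(m)) < 0.3, dim = dim(m))
    if (sum(sites) == 0) next
    prof <- shell_profile(sh, sites)
    # oracle: recompute the interpolated cumulative fraction at half volume
    # from raw per-shell counts, from scratch
    vol <- vapply(sh$shells, sum, numeric(1))
    cnt <- vapply(sh$shells, function(s) sum(s & sites), numeric(1))
    cv <- c(0, cumsum(vol)) / sum(vol)
    cs <- c(0, cumsum(cnt)) / sum(cnt)
    j <- max(which(cv <= 0.5))
    oracle <- cs[j] + (cs[j + 1] - cs[j]) * (0.5 - cv[j]) / (cv[j + 1] - cv[j])
    expect_equal(prof$half_fraction, oracle)
    expect_equal(interior_fraction(prof), 1 - oracle)
  }
})

test_that("treatment increases low-intensity sites at fixed thresholds", {
  spec <- tiny_spec()
  # shallow attenuation keeps demethylated voxels inside the untreated
  # low-intensity band (deeper attenuation would push them below t_bcg,
  # where they no longer count as sites at all)
  args <- list(semi_axes_range = c(2.0, 2.4), mec_low_factor = 0.75,
               patch_depth = 0.15, grad_strength = 0.3)
  f0 <- do.call(dose_series_field, c(list(spec, 55L, 1, 1, 0), args))
  f1 <- do.call(dose_series_field, c(list(spec, 55L, 2, 1, 1), args))
  mask <- f0$truth$labels == 1L  # shared placement
  thr <- compute_thresholds(f0$stack$mec[mask],
                            background_reference = f0$stack$mec)
  s0 <- sum(detect_sites(f0$stack$mec, mask, thr))
  s1 <- sum(detect_sites(f1$stack$mec, mask, thr))
  expect_gt(s1, s0)
})
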