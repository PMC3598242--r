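sig <- function(mec, dapi) cbind(mec = mec, dapi = dapi)

test_that("joint histogram bins half-open with inclusive top edge", {
  rng <- list(mec = c(0, 10), dapi = c(0, 10))
  h <- joint_histogram(sig(rep(3, 4), rep(7, 4)), bins = 2, range = rng)
  expect_equal(sum(h$mass), 1)
  expect_equal(h$mass[1, 2], 1)  # single occupied bin holds all mass
  corners <- sig(c(0, 0, 10, 10), c(0, 10, 0, 10))
  h2 <- joint_histogram(corners, bins = 2, range = rng)
  expect_equal(as.numeric(h2$mass), rep(0.25, 4))  # top edges kept
  expect_error(joint_histogram(sig(numeric(0), numeric(0))), "empty")
  expect_error(joint_histogram(sig(1, 1),
                               range = list(mec = c(2, 2), dapi = c(0, 1))),
               "zero width")
  expect_error(joint_histogram(sig(12, 1), bins = 2, range = rng),
               "outside")
  clipped <- joint_histogram(sig(12, 1), bins = 2, range = rng, clip = TRUE)
  expect_equal(clipped$counts[2, 1], 1)
})

test_that("hand-enumerated 4x4 binning over [0, 16) is exact", {
  pairs <- sig(c(0, 1, 4, 5, 8, 9, 12, 15, 15, 16),
               c(0, 5, 2, 6, 10, 14, 3, 15, 13, 16))
  h <- joint_histogram(pairs, bins = 4,
                       range = list(mec = c(0, 16), dapi = c(0, 16)))
  # bin index = floor(v / 4) + 1, value 16 lands in the top bin
  expected <- matrix(0, 4, 4)
  bm <- pmin(4, floor(pairs[, "mec"] / 4) + 1)
  bd <- pmin(4, floor(pairs[, "dapi"] / 4) + 1)
  for (i in seq_len(nrow(pairs))) {
    expected[bm[i], bd[i]] <- expected[bm[i], bd[i]] + 1
  }
  expect_equal(h$counts, expected)
  expect_equal(h$n_voxels, 10)
})

test_that("reference codistribution is the count-weighted pool", {
  rng <- list(mec = c(0, 4), dapi = c(0, 4))
  h1 <- joint_histogram(sig(rep(1, 100), rep(1, 100)), bins = 2, range = rng)
  expect_equal(reference_codistribution(list(h1))$mass, h1$mass)
  h2 <- joint_histogram(sig(rep(3, 100), rep(3, 100)), bins = 2, range = rng)
  ref <- reference_codistribution(list(h1, h2))
  expect_equal(ref$mass[1, 1], 0.5)
  expect_equal(ref$mass[2, 2], 0.5)
  # counts 100 / 300 / 600 -> raw-count weighting (1 H1 + 3 H2 + 6 H3) / 10
  h3 <- joint_histogram(sig(rep(3, 600), rep(1, 600)), bins = 2, range = rng)
  h2b <- joint_histogram(sig(rep(3, 300), rep(3, 300)), bins = 2, range = rng)
  ref2 <- reference_codistribution(list(h1, h2b, h3))
  expect_equal(ref2$mass[1, 1], 0.1)
  expect_equal(ref2$mass[2, 2], 0.3)
  expect_equal(ref2$mass[2, 1], 0.6)
  bad <- joint_histogram(sig(1, 1), bins = 4, range = rng)
  expect_error(reference_codistribution(list(h1, bad)), "mixed binning")
})

test_that("KL divergence matches closed forms and axioms", {
  p <- hist_from_counts(c(1, 0))
  q <- hist_from_counts(c(1, 1))
  # pseudocount -> 0 limit of D((1,0) || (0.5,0.5)) is ln 2
  expect_equal(kl_divergence(p, q, pseudocount = 1e-9), log(2),
               tolerance = 1e-6)
  p2 <- hist_from_counts(c(9, 1) * 1e7)
  expect_equal(kl_divergence(p2, q, pseudocount = 1e-9),
               0.9 * log(1.8) + 0.1 * log(0.2), tolerance = 1e-6)
  expect_equal(kl_divergence(p, p), 0)
  expect_error(kl_divergence(p, q, pseudocount = 0), "pseudocount")
  expect_error(kl_divergence(p, hist_from_counts(c(1, 1, 1))), "mismatch")
  # non-negativity, identity of indiscernibles, and count-scale stability
  # on randomized histograms
  set.seed(42)
  for (i in 1:25) {
    a <- hist_from_counts(matrix(rpois(16, 40), 4, 4))
    b <- hist_from_counts(matrix(rpois(16, 40), 4, 4))
    expect_gte(kl_divergence(a, b), 0)
    expect_equal(kl_divergence(a, a), 0)
    a2 <- hist_from_counts(a$counts * 2)
    b2 <- hist_from_counts(b$counts * 2)
    # doubling counts only halves the pseudocount weight; KL is stable
    expect_lt(abs(kl_divergence(a2, b2) - kl_divergence(a, b)), 0.002)
  }
})

test_that("KL categories follow the printed half-open intervals", {
  expect_equal(as.character(classify_kl(c(0, 0.3, 0.5, 1.99, 2, 4.49, 4.5, 99))),
               c("similar", "similar", "likely_similar", "likely_similar",
                 "unlikely_similar", "unlikely_similar", "dissimilar",
                 "dissimilar"))
  expect_error(classify_kl(-0.1), ">= 0")
  expect_error(classify_kl(1, boundaries = c(2, 1, 3)), "increasing")
})

test_that("population homogeneity pools the similar categories", {
  all0 <- population_homogeneity(rep(0, 10))
  expect_equal(all0$pooled_similar, 1.0)
  mix <- population_homogeneity(c(0.1, 1.0, 3.0, 5.0))
  expect_equal(unname(mix$fractions), rep(0.25, 4))
  expect_equal(mix$pooled_similar, 0.75)
  expect_equal(sum(mix$fractions), 1)
  expect_error(population_homogeneity(numeric(0)), "empty")
})

test_that("a nucleus inside the reference scores lower KL than one outside", {
  rng <- list(mec = c(0, 4), dapi = c(0, 4))
  a <- joint_histogram(sig(rep(1, 900), rep(1, 900)), bins = 2, range = rng)
  c_ <- joint_histogram(sig(rep(3, 100), rep(3, 100)), bins = 2, range = rng)
  ref <- reference_codistribution(list(a, c_))
  # b has a's shape (one occupied bin) but occupies a bin absent from ref
  b <- joint_histogram(sig(rep(3, 900), rep(1, 900)), bins = 2, range = rng)
  expect_lt(kl_divergence(a, ref), kl_divergence(b, ref))
})

test_that("per-nucleus binning makes phenotyping scale-invariant", {
  set.seed(8)
  sigs <- lapply(1:6, function(i) {
    n <- 400
    sig(rpois(n, 600), rpois(n, 800))
  })
  doubled <- lapply(sigs, function(s) s * 2)
  ph1 <- phenotype_population(sigs, normalize = "per_nucleus")
  ph2 <- phenotype_population(c(sigs, doubled), normalize = "per_nucleus")
  # the doubled copies bin identically to their originals, so the merged
  # population assigns them identical KL values
  expect_equal(ph2$table$kl_value[7:12], ph2$table$kl_value[1:6])
  expect_equal(ph1$homogeneity$pooled_similar, 1.0)
  expect_equal(ph2$homogeneity$pooled_similar, 1.0)
})
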