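# Per-nucleus MeC-vs-DAPI joint histograms, Kullback-Leibler divergence
# against a population reference, and the four similarity categories.

#' Joint MeC/DAPI intensity histogram
#'
#' Builds the normalized 2D codistribution of a nucleus: bins are half-open
#' \code{[lo, hi)} with the top edge inclusive, so the full range is covered
#' without losing the maximum.
#'
#' @param signals matrix with columns \code{mec}, \code{dapi} (one row per
#'   voxel), as returned by [extract_signals()].
#' @param bins bin count per axis (scalar or length-2: mec, dapi).
#' @param range intensity bounds: list with \code{mec} and \code{dapi}
#'   length-2 vectors. Values outside the range are an error unless
#'   \code{clip = TRUE}.
#' @param clip clamp out-of-range values into the boundary bins.
#' @return object of class \code{codistribution}: raw \code{counts},
#'   normalized \code{mass} (sums to 1), \code{bins}, \code{range},
#'   \code{n_voxels}.
#' @export
joint_histogram <- function(signals, bins = 64L,
                            range = list(mec = c(0, 4095),
                                         dapi = c(0, 4095)),
                            clip = FALSE) {
  if (is.null(dim(signals)) || nrow(signals) == 0) {
    stop("empty signal list")
  }
  bins <- rep(as.integer(bins), length.out = 2)
  if (any(bins < 1)) stop("bins must be >= 1")
  rg_m <- as.numeric(range$mec); rg_d <- as.numeric(range$dapi)
  if (diff(rg_m) <= 0 || diff(rg_d) <= 0) stop("range of zero width")
  bin_of <- function(x, rg, nb) {
    if (clip) x <- pmin(pmax(x, rg[1]), rg[2])
    if (any(x < rg[1] | x > rg[2])) {
      stop("values outside histogram range (set clip = TRUE to clamp)")
    }
    b <- floor((x - rg[1]) / (rg[2] - rg[1]) * nb) + 1L
    pmin(b, nb)  # top edge inclusive
  }
  bm <- bin_of(signals[, "mec"], rg_m, bins[1])
  bd <- bin_of(signals[, "dapi"], rg_d, bins[2])
  counts <- matrix(0, bins[1], bins[2])
  tab <- table(factor(bm, levels = seq_len(bins[1])),
               factor(bd, levels = seq_len(bins[2])))
  counts[] <- as.numeric(tab)
  structure(list(counts = counts, mass = counts / sum(counts),
                 bins = bins, range = list(mec = rg_m, dapi = rg_d),
                 n_voxels = nrow(signals)),
            class = "codistribution")
}

same_binning <- function(p, q) {
  identical(p$bins, q$bins) &&
    isTRUE(all.equal(p$range$mec, q$range$mec)) &&
    isTRUE(all.equal(p$range$dapi, q$range$dapi))
}

#' Population reference codistribution
#'
#' The cumulative plot from all nuclei of one condition: the voxel-count
#' weighted sum of the raw count histograms, renormalized to mass 1.
#'
#' @param hists list of [joint_histogram()] results sharing bins and range.
#' @return a \code{codistribution}.
#' @export
reference_codistribution <- function(hists) {
  if (length(hists) == 0) stop("no histograms supplied")
  h1 <- hists[[1]]
  counts <- matrix(0, h1$bins[1], h1$bins[2])
  n <- 0L
  for (h in hists) {
    if (!same_binning(h1, h)) stop("mixed binning across histograms")
    counts <- counts + h$counts
    n <- n + h$n_voxels
  }
  structure(list(counts = counts, mass = counts / sum(counts),
                 bins = h1$bins, range = h1$range, n_voxels = n),
            class = "codistribution")
}

#' Kullback-Leibler divergence between codistributions
#'
#' \code{D(P || Q) = sum p log(p / q)} in nats, computed after adding a
#' pseudocount to every bin of both raw-count histograms and renormalizing
#' (Laplace regularization; KL is undefined on zero-support bins).
#'
#' @param p,q \code{codistribution} objects on identical binning; by
#'   convention \code{p} is the nucleus and \code{q} the population
#'   reference.
#' @param pseudocount raw counts added per bin (> 0).
#' @param base logarithm base; the default (\code{exp(1)}) reports nats, the
#'   scale on which the category boundaries are interpreted.
#' @return scalar KL divergence (>= 0; 0 iff equal histograms).
#' @export
kl_divergence <- function(p, q, pseudocount = 1, base = exp(1)) {
  if (!same_binning(p, q)) stop("histogram shape/binning mismatch")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  ps <- p$counts + pseudocount
  qs <- q$counts + pseudocount
  pm <- ps / sum(ps)
  qm <- qs / sum(qs)
  sum(pm * (log(pm) - log(qm))) / log(base)
}

#' Classify a nucleus by its KL divergence
#'
#' Half-open intervals, left-closed: similar \code{[0, 0.5)}, likely_similar
#' \code{[0.5, 2)}, unlikely_similar \code{[2, 4.5)}, dissimilar
#' \code{[4.5, Inf)}.
#'
#' @param kl_value KL divergence(s), >= 0.
#' @param boundaries strictly increasing category boundaries.
#' @return factor with levels similar, likely_similar, unlikely_similar,
#'   dissimilar.
#' @export
classify_kl <- function(kl_value, boundaries = c(0.5, 2, 4.5)) {
  if (any(kl_value < 0)) stop("KL divergence must be >= 0")
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("category boundaries must be strictly increasing")
  }
  lv <- c("similar", "likely_similar", "unlikely_similar", "dissimilar")
  cut(kl_value, breaks = c(0, boundaries, Inf), labels = lv,
      right = FALSE, include.lowest = TRUE)
}

#' Population homogeneity from per-nucleus KL values
#'
#' @param kl_values numeric vector of per-nucleus KL divergences.
#' @param boundaries category boundaries (see [classify_kl()]).
#' @return list with \code{fractions} (named, sums to 1) and
#'   \code{pooled_similar} (fraction with KL below the dissimilar boundary,
#'   i.e. 1 - dissimilar fraction).
#' @export
population_homogeneity <- function(kl_values, boundaries = c(0.5, 2, 4.5)) {
  if (length(kl_values) == 0) stop("empty KL list")
  cats <- classify_kl(kl_values, boundaries)
  fr <- as.numeric(table(cats)) / length(kl_values)
  names(fr) <- levels(cats)
  list(fractions = fr, pooled_similar = 1 - fr[["dissimilar"]])
}

#' Phenotype a population of nuclei by MeC/DAPI codistribution
#'
#' Builds one joint histogram per nucleus, the population reference, and the
#' per-nucleus KL divergence and similarity category.
#'
#' Histogram range: with \code{normalize = "global"} one shared range
#' \code{[0, max]} over all nuclei of the condition (the within-experiment
#' convention); with \code{normalize = "per_nucleus"} each nucleus is binned
#' on \code{[0, its own max]}, which makes the classification invariant to
#' per-cell global intensity scaling (e.g. the G1 vs G2 DNA-content
#' doubling).
#'
#' @param signal_list list of signal matrices (see [extract_signals()]).
#' @param bins bins per axis.
#' @param pseudocount see [kl_divergence()].
#' @param boundaries see [classify_kl()].
#' @param normalize range convention, see Details.
#' @return list with \code{table} (data frame: label, n_voxels, kl_value,
#'   category), \code{reference}, \code{histograms}, \code{homogeneity}, and
#'   the resolved settings.
#' @export
phenotype_population <- function(signal_list, bins = 64L, pseudocount = 1,
                                 boundaries = c(0.5, 2, 4.5),
                                 normalize = c("global", "per_nucleus")) {
  normalize <- match.arg(normalize)
  if (length(signal_list) == 0) stop("no nuclei supplied")
  if (normalize == "global") {
    top_m <- max(vapply(signal_list, function(s) max(s[, "mec"]), numeric(1)))
    top_d <- max(vapply(signal_list, function(s) max(s[, "dapi"]), numeric(1)))
    rng <- list(mec = c(0, top_m), dapi = c(0, top_d))
    hists <- lapply(signal_list, joint_histogram, bins = bins, range = rng)
  } else {
    # bin each nucleus on [0, its own max] per channel; scaling the signals
    # onto a common [0, 1] grid keeps all histograms poolable and makes the
    # binning invariant to per-cell global intensity factors
    hists <- lapply(signal_list, function(s) {
      sn <- cbind(mec = s[, "mec"] / max(s[, "mec"]),
                  dapi = s[, "dapi"] / max(s[, "dapi"]))
      joint_histogram(sn, bins = bins,
                      range = list(mec = c(0, 1), dapi = c(0, 1)))
    })
  }
  ref <- reference_codistribution(hists)
  kl <- vapply(hists, kl_divergence, numeric(1), q = ref,
               pseudocount = pseudocount)
  cats <- classify_kl(kl, boundaries)
  labels <- if (!is.null(names(signal_list))) names(signal_list) else
    as.character(seq_along(signal_list))
  tab <- data.frame(label = labels,
                    n_voxels = vapply(hists, function(h) h$n_voxels,
                                      numeric(1)),
                    kl_value = kl, category = cats,
                    row.names = NULL)
  list(table = tab, reference = ref, histograms = hists,
       homogeneity = population_homogeneity(kl, boundaries),
       settings = list(bins = bins, pseudocount = pseudocount,
                       boundaries = boundaries, normalize = normalize))
}
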