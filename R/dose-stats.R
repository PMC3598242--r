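# Population-level dose-response statistics: normalized mean MeC intensity,
# pairwise Kolmogorov-Smirnov comparisons with Bonferroni correction, and
# correlation of imaging-derived methylation against MethyLight PMR values.

#' Mean channel intensity of a nucleus
#'
#' Arithmetic mean of the in-mask voxel intensities of one channel (I_MeC /
#' I_DAPI).
#'
#' @param signals signal matrix (see [extract_signals()]).
#' @param channel \code{"mec"} or \code{"dapi"}.
#' @return scalar mean intensity.
#' @export
mean_intensity <- function(signals, channel = c("mec", "dapi")) {
  channel <- match.arg(channel)
  if (is.null(dim(signals)) || nrow(signals) == 0) stop("empty signals")
  mean(signals[, channel])
}

#' Normalize per-condition mean intensities to the control
#'
#' Divides every condition's population mean by the control population mean,
#' so the control row is exactly 1.
#'
#' @param dose_table data frame with at least \code{dose} and
#'   \code{mean_mec} columns.
#' @param control value of \code{dose} identifying the control row.
#' @return the table with a \code{norm_mean_mec} column added.
#' @export
normalize_to_control <- function(dose_table, control = 0) {
  i <- which(dose_table$dose == control)
  if (length(i) != 1) stop("control condition missing or ambiguous")
  dose_table$norm_mean_mec <- dose_table$mean_mec / dose_table$mean_mec[i]
  dose_table
}

#' Pairwise two-sample Kolmogorov-Smirnov tests across dose groups
#'
#' Two-sided two-sample KS on every pair of groups; a pair is significant iff
#' its p-value is below the Bonferroni-corrected level \code{beta =
#' alpha / n_tests}. Groups with fewer than 2 observations make their pairs
#' untestable (reported \code{NA}, not significant).
#'
#' @param groups named list of numeric vectors (per-dose I_MeC samples).
#' @param alpha family-wise significance level.
#' @param n_tests Bonferroni divisor; defaults to the number of groups (the
#'   number of dose levels in the series).
#' @return list with \code{D}, \code{p} (matrices), \code{significant}
#'   (logical matrix), and \code{beta}.
#' @export
ks_pairwise <- function(groups, alpha = 0.05, n_tests = length(groups)) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  nm <- if (!is.null(names(groups))) names(groups) else as.character(seq_len(k))
  D <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  sig <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  beta <- alpha / n_tests
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      a <- groups[[i]]; b <- groups[[j]]
      if (length(a) < 2 || length(b) < 2) next
      kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
      D[i, j] <- unname(kt$statistic)
      p[i, j] <- kt$p.value
      sig[i, j] <- kt$p.value < beta
    }
  }
  diag(D) <- 0; diag(p) <- 1
  list(D = D, p = p, significant = sig, beta = beta,
       alpha = alpha, n_tests = n_tests)
}

#' Packaged MethyLight PMR dose-response table
#'
#' Normalized MeC mean intensity (imaging) and normalized percent-of-
#' methylated-reference (PMR) values per repeat class (Alu, Sat2, Satalpha)
#' for Huh-7 cells across a 5-azacytidine concentration series, all
#' normalized to the untreated control. Ships as a plain CSV fixture.
#'
#' @return data frame with columns \code{dose_label}, \code{aza_um},
#'   \code{mec_intensity}, \code{alu_pmr}, \code{sat2_pmr}, \code{sata_pmr}.
#' @export
methylight_table <- function() {
  path <- system.file("extdata", "methylight_pmr_huh7_aza.csv",
                      package = "qdmi3d", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Correlate imaging-derived methylation with MethyLight PMR values
#'
#' Sample Pearson correlation between the normalized MeC mean intensity and
#' each repeat class's normalized PMR, across the selected doses. The default
#' dose subset runs from the untreated control through 10 uM: the topmost
#' concentration of the packaged series is excluded because survivor
#' selection at cytotoxic doses re-raises PMR in the surviving cells.
#'
#' @param pmr a PMR table shaped like [methylight_table()].
#' @param imaging optional numeric vector of normalized MeC intensities
#'   aligned with \code{pmr} rows; defaults to \code{pmr$mec_intensity}.
#' @param dose_max doses (in \code{aza_um}) above this are excluded.
#' @param classes PMR columns to correlate against.
#' @return data frame: class, n, r (full precision), r_rounded (2 decimals,
#'   half-up, for report parity).
#' @export
correlate_imaging_vs_pmr <- function(pmr = methylight_table(),
                                     imaging = pmr$mec_intensity,
                                     dose_max = 10,
                                     classes = c("alu_pmr", "sat2_pmr",
                                                 "sata_pmr")) {
  keep <- pmr$aza_um <= dose_max
  if (sum(keep) < 3) stop("need at least 3 paired doses")
  x <- imaging[keep]
  if (stats::sd(x) == 0) stop("zero variance in imaging column")
  rows <- lapply(classes, function(cl) {
    y <- pmr[[cl]][keep]
    if (stats::sd(y) == 0) stop("zero variance in PMR column ", cl)
    r <- stats::cor(x, y)
    data.frame(class = sub("_pmr$", "", cl), n = sum(keep),
               r = r, r_rounded = round_half_up(r, 2))
  })
  do.call(rbind, rows)
}

#' Build per-nucleus summaries for one condition
#'
#' @param regions list of \code{nucleus_region} from one field/condition.
#' @param stack the [volume_stack()] the regions came from.
#' @param dose dose label for the condition.
#' @param topology compute LIM/LID half-fractions (slower).
#' @param ... forwarded to [nucleus_topology()].
#' @return data frame (one row per nucleus): label, dose, n_voxels, mean_mec,
#'   mean_dapi, and if requested lim/lid half fractions and site counts.
#' @export
summarize_nuclei <- function(regions, stack, dose = 0, topology = TRUE, ...) {
  rows <- lapply(regions, function(r) {
    base <- data.frame(label = r$label, dose = dose,
                       n_voxels = r$volume_voxels,
                       volume_um3 = r$volume_um3,
                       mean_mec = mean_intensity(r$signals, "mec"),
                       mean_dapi = mean_intensity(r$signals, "dapi"))
    if (topology) {
      tp <- nucleus_topology(stack, r, ...)
      base$lim_half_fraction <- tp$lim$profile$half_fraction
      base$lid_half_fraction <- tp$lid$profile$half_fraction
      base$lim_sites <- tp$lim$profile$n_sites
      base$lid_sites <- tp$lid$profile$n_sites
      base$t_bcg_mec <- tp$lim$thresholds$t_bcg
      base$t_q_mec <- tp$lim$thresholds$t_Q
    }
    base
  })
  do.call(rbind, rows)
}

#' Aggregate per-nucleus summaries into a dose table
#'
#' @param summaries per-nucleus summary rows (possibly several conditions;
#'   see [summarize_nuclei()]) with columns \code{dose}, \code{mean_mec} and
#'   optionally \code{kl_value}, \code{lim_half_fraction},
#'   \code{lid_half_fraction}.
#' @param control control dose (normalization anchor).
#' @param boundaries KL category boundaries for the category fractions.
#' @return data frame keyed by dose: n_nuclei, mean and sd of I_MeC,
#'   normalized mean, pooled-similar fraction (when KL values are present),
#'   mean half-fractions (when present).
#' @export
dose_table <- function(summaries, control = 0, boundaries = c(0.5, 2, 4.5)) {
  if (nrow(summaries) == 0) stop("no summaries")
  sp <- split(summaries, summaries$dose)
  rows <- lapply(sp, function(s) {
    out <- data.frame(dose = s$dose[1], n_nuclei = nrow(s),
                      mean_mec = mean(s$mean_mec),
                      sd_mec = stats::sd(s$mean_mec),
                      mean_dapi = mean(s$mean_dapi))
    if ("kl_value" %in% names(s)) {
      hom <- population_homogeneity(s$kl_value, boundaries)
      out$pooled_similar <- hom$pooled_similar
      out$similar <- hom$fractions[["similar"]]
      out$dissimilar <- hom$fractions[["dissimilar"]]
    }
    if ("lim_half_fraction" %in% names(s)) {
      out$lim_half_fraction <- mean(s$lim_half_fraction, na.rm = TRUE)
      out$lim_interior_fraction <- 1 - out$lim_half_fraction
    }
    if ("lid_half_fraction" %in% names(s)) {
      out$lid_half_fraction <- mean(s$lid_half_fraction, na.rm = TRUE)
      out$lid_interior_fraction <- 1 - out$lid_half_fraction
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$dose), , drop = FALSE]
  rownames(tab) <- NULL
  normalize_to_control(tab, control)
}

#' Machine-readable condition report
#'
#' Deterministic aggregation of per-nucleus summaries plus every analysis
#' constant that shaped them, so a report is reproducible from itself.
#'
#' @param summaries see [dose_table()].
#' @param settings named list of resolved analysis settings to embed.
#' @param control control dose.
#' @param path optional JSON output path.
#' @return list with \code{table} (the [dose_table()]), \code{per_nucleus},
#'   \code{settings}, \code{package_version}.
#' @export
condition_report <- function(summaries, settings = list(), control = 0,
                             path = NULL) {
  report <- list(
    table = dose_table(summaries, control),
    per_nucleus = summaries,
    settings = settings,
    package_version =
      as.character(utils::packageVersion("qdmi3d"))
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}
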