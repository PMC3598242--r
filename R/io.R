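# TIFF I/O and the end-to-end pipeline driver.
#
# TIFF dialect: plain multi-page grayscale TIFF, one file per channel, page
# order = ascending z; 12-bit data stored in 16-bit containers.

#' Read a two-channel stack from per-channel multi-page TIFFs
#'
#' @param mec_path,dapi_path multi-page grayscale TIFF files (page =
#'   z-slice).
#' @param voxel_size physical voxel size in micrometers.
#' @param bit_depth effective bit depth of the data (container is 16-bit).
#' @return a [volume_stack()].
#' @export
read_stack <- function(mec_path, dapi_path,
                       voxel_size = c(0.116, 0.116, 0.2305),
                       bit_depth = 12L) {
  read_one <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d2 <- dim(pages[[1]])
    if (length(d2) != 2) stop("expected grayscale pages in ", path)
    arr <- array(0L, dim = c(d2[1], d2[2], length(pages)))
    for (z in seq_along(pages)) {
      if (!identical(dim(pages[[z]]), d2)) {
        stop("page dimension mismatch within ", path)
      }
      arr[, , z] <- as.integer(pages[[z]])
    }
    arr
  }
  mec <- read_one(mec_path)
  dapi <- read_one(dapi_path)
  if (!identical(dim(mec), dim(dapi))) {
    stop("channel dimension mismatch between TIFF files")
  }
  if (max(mec) >= 2^16 || max(dapi) >= 2^16) stop("more than 16-bit data")
  volume_stack(mec, dapi, voxel_size, bit_depth)
}

write_channel_tiff <- function(arr, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(seq_len(dim(arr)[3]), function(z) arr[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write a two-channel stack as per-channel multi-page TIFFs
#'
#' @param stack a [volume_stack()].
#' @param mec_path,dapi_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_stack <- function(stack, mec_path, dapi_path) {
  write_channel_tiff(stack$mec, mec_path)
  write_channel_tiff(stack$dapi, dapi_path)
  invisible(c(mec_path, dapi_path))
}

#' Write a generated field (channels, labels, truth manifest)
#'
#' @param field a [generate_field()] result.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the directory.
#' @export
write_field <- function(field, dir, prefix = "field") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(field$stack,
              file.path(dir, paste0(prefix, "_mec.tif")),
              file.path(dir, paste0(prefix, "_dapi.tif")))
  if (!is.null(field$truth$labels)) {
    write_channel_tiff(field$truth$labels,
                       file.path(dir, paste0(prefix, "_labels.tif")))
  }
  jsonlite::write_json(
    list(voxel_size = field$stack$voxel_size,
         bit_depth = field$stack$bit_depth,
         per_nucleus = field$truth$per_nucleus),
    file.path(dir, paste0(prefix, "_truth.json")),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Pipeline configuration
#'
#' All knobs of the end-to-end analysis in one resolved object; every report
#' embeds it.
#'
#' @param voxel_size micrometers per voxel (x, y, z).
#' @param segmentation a [segmentation_config()].
#' @param bins joint-histogram bins per axis.
#' @param pseudocount KL pseudocount.
#' @param normalize histogram range convention (see
#'   [phenotype_population()]).
#' @param boundaries KL category boundaries.
#' @param erosion_step_um physical erosion step.
#' @param t_q_quantile low/high separator quantile.
#' @param alpha,n_tests KS/Bonferroni settings (\code{n_tests = NULL} uses
#'   the number of dose levels).
#' @param seed integer seed for any simulation involved.
#' @param outdir optional output directory for reports.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(voxel_size = c(0.116, 0.116, 0.2305),
                            segmentation = segmentation_config(),
                            bins = 64L, pseudocount = 1,
                            normalize = "global",
                            boundaries = c(0.5, 2, 4.5),
                            erosion_step_um = c(1.32, 1.3, 0.25),
                            t_q_quantile = 0.5,
                            alpha = 0.05, n_tests = NULL,
                            seed = 1L, outdir = NULL) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("category boundaries must be strictly increasing")
  }
  if (any(voxel_size <= 0) || any(erosion_step_um <= 0)) {
    stop("physical sizes must be > 0")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Analyze one condition (a set of fields at one dose)
#'
#' Segments every field, pools the per-nucleus signals of the condition,
#' phenotypes the population against its own reference, and profiles LIM/LID
#' topology per nucleus.
#'
#' @param fields list of [generate_field()]-shaped lists (or bare
#'   [volume_stack()] objects).
#' @param dose dose label.
#' @param config a [pipeline_config()].
#' @return data frame of per-nucleus summaries with KL values and categories.
#' @export
analyze_condition <- function(fields, dose, config = pipeline_config()) {
  summaries <- list()
  signals <- list()
  for (f in fields) {
    stack <- if (inherits(f, "volume_stack")) f else f$stack
    regions <- segment_nuclei(stack, config$segmentation)
    if (length(regions) == 0) next
    s <- summarize_nuclei(regions, stack, dose = dose,
                          step_um = config$erosion_step_um,
                          t_q_quantile = config$t_q_quantile)
    s$field <- length(summaries) + 1L
    summaries[[length(summaries) + 1L]] <- s
    signals <- c(signals, lapply(regions, function(r) r$signals))
  }
  if (length(signals) == 0) {
    return(data.frame())
  }
  out <- do.call(rbind, summaries)
  ph <- phenotype_population(signals, bins = config$bins,
                             pseudocount = config$pseudocount,
                             boundaries = config$boundaries,
                             normalize = config$normalize)
  out$kl_value <- ph$table$kl_value
  out$category <- ph$table$category
  out
}

#' Run the full pipeline on a synthetic dose series
#'
#' Streaming end-to-end driver: for every dose and nucleus index it generates
#' the field exactly as [generate_dose_series()] would (same substream
#' addressing), analyzes it, and discards the voxel data; per-nucleus
#' summaries, the dose table and the generator's truth manifest are returned
#' and optionally written.
#'
#' @param doses ascending dose levels in \code{[0, 1]}.
#' @param n_nuclei_per_dose nuclei per condition.
#' @param spec base [field_spec()].
#' @param config a [pipeline_config()].
#' @param seed series seed (defaults to \code{config$seed}).
#' @param ... forwarded to [dose_series_field()].
#' @return list: \code{summaries} (per nucleus), \code{table} (per dose,
#'   normalized to the lowest dose), \code{manifest} (generator truth),
#'   \code{ks} (pairwise KS on per-nucleus I_MeC), \code{config}.
#' @export
run_pipeline <- function(doses = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                         n_nuclei_per_dose = 30L,
                         spec = field_spec(),
                         config = pipeline_config(),
                         seed = config$seed, ...) {
  all_sum <- list()
  man_rows <- list()
  for (k in seq_along(doses)) {
    fields <- vector("list", n_nuclei_per_dose)
    truths <- vector("list", n_nuclei_per_dose)
    for (i in seq_len(n_nuclei_per_dose)) {
      f <- dose_series_field(spec, seed, k, i, doses[k], ...)
      f$truth[c("labels", "lim_truth", "lid_truth",
                "clean_mec", "clean_dapi")] <- NULL
      fields[[i]] <- f
      truths[[i]] <- f$truth$per_nucleus
    }
    cond <- analyze_condition(fields, doses[k], config)
    if (nrow(cond) > 0) all_sum[[length(all_sum) + 1L]] <- cond
    tt <- do.call(rbind, truths)
    man_rows[[k]] <- data.frame(
      dose = doses[k],
      true_mean_mec = mean(tt$true_mean_mec),
      true_interior_lim_fraction = mean(tt$interior_lim_fraction,
                                        na.rm = TRUE))
    rm(fields)
  }
  if (length(all_sum) == 0) stop("no nuclei found in any field")
  summaries <- do.call(rbind, all_sum)
  manifest <- do.call(rbind, man_rows)
  manifest$true_norm_mean_mec <-
    manifest$true_mean_mec / manifest$true_mean_mec[1]
  tab <- dose_table(summaries, control = min(doses),
                    boundaries = config$boundaries)
  groups <- split(summaries$mean_mec, summaries$dose)
  n_tests <- if (is.null(config$n_tests)) length(doses) else config$n_tests
  ks <- if (length(groups) >= 2) {
    ks_pairwise(groups, alpha = config$alpha, n_tests = n_tests)
  } else NULL
  res <- list(summaries = summaries, table = tab, manifest = manifest,
              ks = ks, config = config)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summaries,
                     file.path(config$outdir, "per_nucleus.csv"),
                     row.names = FALSE)
    cfg <- config
    cfg$segmentation <- unclass(cfg$segmentation)
    jsonlite::write_json(
      list(table = tab, manifest = manifest, settings = unclass(cfg),
           package_version = as.character(utils::packageVersion("qdmi3d"))),
      file.path(config$outdir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
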