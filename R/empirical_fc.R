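#' Functional connectivity networks
#'
#' An `fc_network` is a symmetric correlation matrix over labelled regions
#' with unit diagonal and entries in \[-1, 1\], tagged by its provenance
#' (`"empirical"`, `"simulated"`, or `"average"`).
#'
#' @param matrix Symmetric numeric matrix of correlations.
#' @param regions Character vector of unique region labels.
#' @param source One of `"empirical"`, `"simulated"`, `"average"`.
#' @return An object of class `fc_network`.
#' @export
fc_network <- function(matrix, regions,
                       source = c("empirical", "simulated", "average")) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  regions <- as.character(regions)
  if (nrow(matrix) != ncol(matrix))
    stop("FC matrix must be square")
  if (length(regions) != nrow(matrix))
    stop("`regions` length must match matrix dimension")
  if (anyDuplicated(regions)) stop("`regions` must be unique")
  if (max(abs(matrix - t(matrix))) > 1e-8)
    stop("FC matrix must be symmetric")
  matrix <- (matrix + t(matrix)) / 2
  if (max(abs(matrix)) > 1 + 1e-8)
    stop("FC entries must lie in [-1, 1]")
  matrix[matrix > 1] <- 1
  matrix[matrix < -1] <- -1
  diag(matrix) <- 1
  dimnames(matrix) <- list(regions, regions)
  structure(list(matrix = matrix, regions = regions, source = source),
            class = "fc_network")
}

#' @export
print.fc_network <- function(x, ...) {
  ut <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("fc_network (%s): %d regions | mean edge %.3f, sd %.3f\n",
              x$source, length(x$regions), mean(ut), stats::sd(ut)))
  invisible(x)
}

#' Region-level BOLD recording
#'
#' @param series Time-by-region numeric matrix (arbitrary units).
#' @param regions Region labels, one per column.
#' @param voxel_count Per-region positive integer voxel counts.
#' @param subject_id Subject identifier string.
#' @return An object of class `bold_recording`.
#' @export
bold_recording <- function(series, regions, voxel_count, subject_id = "") {
  series <- as.matrix(series)
  regions <- as.character(regions)
  if (ncol(series) != length(regions))
    stop("series column count must equal label count")
  if (length(voxel_count) != length(regions))
    stop("`voxel_count` length must match `regions`")
  if (any(voxel_count < 1)) stop("voxel counts must be >= 1")
  colnames(series) <- regions
  structure(list(series = series, regions = regions,
                 voxel_count = as.integer(voxel_count),
                 subject_id = as.character(subject_id)),
            class = "bold_recording")
}

#' Quality-control filtering of a BOLD recording
#'
#' Applies three sequential filters: (1) keep regions whose labels exactly
#' match the structural connectome's regions; (2) keep regions with voxel
#' count strictly above the median voxel count of the regions surviving
#' filter 1 (ties at the median are excluded); (3) drop regions whose
#' time-series variance is below `variance_floor`.
#'
#' @param rec A [bold_recording()].
#' @param sc_regions Labels of the structural connectome.
#' @param variance_floor Minimum retained time-series variance.
#' @return The filtered `bold_recording`.
#' @export
region_filter <- function(rec, sc_regions, variance_floor = 1e-6) {
  stopifnot(inherits(rec, "bold_recording"))
  keep <- rec$regions %in% sc_regions
  if (!any(keep)) stop("no regions match the structural connectome")
  med <- stats::median(rec$voxel_count[keep])
  keep <- keep & (rec$voxel_count > med)
  if (!any(keep)) stop("all regions removed by the voxel-count filter")
  v <- apply(rec$series, 2, stats::var)
  keep <- keep & (v >= variance_floor)
  if (!any(keep)) stop("all regions removed by the variance filter")
  bold_recording(rec$series[, keep, drop = FALSE], rec$regions[keep],
                 rec$voxel_count[keep], rec$subject_id)
}

#' Compute empirical FC from a BOLD recording
#'
#' Pairwise Pearson correlations between the region time series that
#' remain after quality control.
#'
#' @param rec A [bold_recording()] with at least 3 time points and 2
#'   regions.
#' @return An [fc_network()] with `source = "empirical"`.
#' @export
compute_fc <- function(rec) {
  stopifnot(inherits(rec, "bold_recording"))
  if (nrow(rec$series) < 3) stop("need at least 3 time points")
  if (ncol(rec$series) < 2) stop("need at least 2 regions")
  v <- apply(rec$series, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance region reached compute_fc; run region_filter first")
  fc_network(stats::cor(rec$series), rec$regions, source = "empirical")
}

#' Regions common to a list of FC networks
#'
#' @param fcs List of [fc_network()] objects.
#' @return Character vector of shared labels, ordered as in the first
#'   network. Errors if the intersection is empty.
#' @export
common_regions <- function(fcs) {
  stopifnot(length(fcs) >= 1)
  common <- Reduce(intersect, lapply(fcs, function(f) f$regions))
  common <- fcs[[1]]$regions[fcs[[1]]$regions %in% common]
  if (!length(common)) stop("no regions common to all networks")
  common
}

#' Average FC network over common regions
#'
#' Elementwise mean of the common-region submatrices of the supplied FC
#' networks.
#'
#' @param fcs List of [fc_network()] objects.
#' @return An [fc_network()] with `source = "average"`.
#' @export
average_fc <- function(fcs) {
  common <- common_regions(fcs)
  mats <- lapply(fcs, function(f) f$matrix[common, common, drop = FALSE])
  fc_network(Reduce(`+`, mats) / length(mats), common, source = "average")
}

#' Edge-strength similarity between two FC networks
#'
#' Pearson correlation over the strictly-upper-triangle edge strengths of
#' the common-region submatrices. Applied to a (simulated, empirical) pair
#' this is the model's predictive power.
#'
#' @param fc1,fc2 [fc_network()] objects sharing at least 3 regions.
#' @return Pearson correlation in \[-1, 1\].
#' @export
fc_similarity <- function(fc1, fc2) {
  common <- common_regions(list(fc1, fc2))
  if (length(common) < 3) stop("need at least 3 common regions")
  m1 <- fc1$matrix[common, common]
  m2 <- fc2$matrix[common, common]
  e1 <- m1[upper.tri(m1)]
  e2 <- m2[upper.tri(m2)]
  if (stats::sd(e1) == 0 || stats::sd(e2) == 0)
    stop("edge strengths have zero variance")
  stats::cor(e1, e2)
}

#' Mean squared error between two FC networks
#'
#' Mean squared difference over the common strictly-upper-triangle edges.
#'
#' @param fc_sim,fc_emp [fc_network()] objects.
#' @return Nonnegative scalar.
#' @export
fc_mse <- function(fc_sim, fc_emp) {
  common <- common_regions(list(fc_sim, fc_emp))
  m1 <- fc_sim$matrix[common, common]
  m2 <- fc_emp$matrix[common, common]
  mean((m1[upper.tri(m1)] - m2[upper.tri(m2)])^2)
}

#' Read an FC network from a CSV matrix
#'
#' @param file Path to a square CSV with header row and label column.
#' @param source Provenance tag.
#' @return An [fc_network()].
#' @export
read_fc <- function(file, source = "empirical") {
  m <- utils::read.table(file, header = TRUE, sep = ",", row.names = 1,
                         check.names = FALSE)
  fc_network(as.matrix(m), rownames(m), source = source)
}

#' Write an FC network to a CSV matrix
#'
#' @param fc An [fc_network()].
#' @param file Output CSV path.
#' @return Invisibly, `fc`.
#' @export
write_fc <- function(fc, file) {
  df <- data.frame(label = fc$regions, fc$matrix, check.names = FALSE)
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(fc)
}
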