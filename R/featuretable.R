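#' Construct a feature table
#'
#' The container consumed by the pipeline: a feature-by-sample intensity
#' matrix with per-feature m/z, retention time and ion mode, and per-sample
#' metadata.
#'
#' @param features Data frame with columns `feature_id` (unique), `mz` (> 0),
#'   `rt_min`, `ion_mode` (`"positive"`/`"negative"`).
#' @param intensities Numeric matrix, features x samples, non-negative;
#'   rownames are feature ids, colnames sample ids.
#' @param samples Data frame with columns `sample_id`, `group`, `replicate`,
#'   `protein_mg`, `treatment` (`"none"`/`"HCl"`), `matrix`
#'   (`"fibroblast"`/`"plasma"`).
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(features, intensities, samples) {
  stopifnot(is.data.frame(features), is.matrix(intensities),
            is.data.frame(samples))
  if (anyDuplicated(features$feature_id)) stop("feature_ids must be unique")
  if (any(features$mz <= 0)) stop("feature m/z must be positive")
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (nrow(intensities) != nrow(features) ||
      ncol(intensities) != nrow(samples))
    stop("intensity matrix dimensions do not match features/samples")
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- samples$sample_id
  structure(list(features = features, intensities = intensities,
                 samples = samples), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features x ",
      nrow(x$samples), " samples (",
      paste(unique(x$features$ion_mode), collapse = "/"), " mode)\n", sep = "")
  invisible(x)
}

#' Write / read a feature table as TSV
#'
#' The feature TSV holds the feature columns followed by one intensity column
#' per sample; the sample metadata goes to a companion TSV.
#'
#' @param ft A `feature_table`.
#' @param features_path,samples_path Output/input files.
#' @param header Optional comment line(s) written atop each file.
#' @export
write_feature_table <- function(ft, features_path, samples_path,
                                header = NULL) {
  tab <- cbind(ft$features, as.data.frame(ft$intensities))
  for (p in c(features_path, samples_path)) {
    if (!is.null(header)) writeLines(paste0("# ", header), p)
  }
  suppressWarnings({
    utils::write.table(tab, features_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = !is.null(header))
    utils::write.table(ft$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = !is.null(header))
  })
  invisible(ft)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(features_path, samples_path) {
  tab <- utils::read.delim(features_path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  samples <- utils::read.delim(samples_path, comment.char = "#",
                               stringsAsFactors = FALSE)
  feat_cols <- intersect(c("feature_id", "mz", "rt_min", "ion_mode"),
                         names(tab))
  features <- tab[, feat_cols, drop = FALSE]
  ints <- as.matrix(tab[, samples$sample_id, drop = FALSE])
  feature_table(features, ints, samples)
}
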