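# Design matrix of a group: features x species, entries = isotopologue
# fractions summed per (feature, species).
.group_design <- function(group) {
  feats <- group$features
  sp <- group$species
  A <- matrix(0, length(feats), length(sp),
              dimnames = list(feats, as.character(sp)))
  fi <- match(group$map$feature_id, feats)
  si <- match(group$map$db_index, sp)
  for (i in seq_along(fi)) A[fi[i], si[i]] <- A[fi[i], si[i]] +
      group$map$fraction[i]
  A
}

# Solve one group system for one observation vector; shared by
# deconvolute_group and correct_feature_table (which reuses A across
# samples).
.solve_group <- function(A, y, rank_ok) {
  y[is.na(y)] <- 0  # zero-fill: absent means below detection
  n_sp <- ncol(A)
  if (!rank_ok) {
    return(list(x = rep(NA_real_, n_sp), resolved = FALSE,
                residual = sqrt(sum(y^2))))
  }
  x <- NULL
  if (nrow(A) == n_sp) {
    x_exact <- tryCatch(solve(A, y), error = function(e) NULL)
    if (!is.null(x_exact) && all(x_exact >= 0)) x <- x_exact
  }
  if (is.null(x)) x <- pracma::lsqnonneg(A, as.numeric(y))$x
  list(x = x, resolved = TRUE, residual = sqrt(sum((y - A %*% x)^2)))
}

#' Deconvolute one overlap group for one sample
#'
#' Builds the linear system `y = A x`: `y` holds the observed intensities of
#' the group's features, column `s` of `A` holds species `s`'s isotopologue
#' fractions placed at the features they map to, and `x` is the species'
#' total (monoisotopic-equivalent) intensity. Because each observed feature
#' carries `fraction_k` of a species' pattern, the solution is the species'
#' full-pattern intensity directly. Square non-singular systems are solved
#' exactly; otherwise (or when the exact solution goes negative, as happens
#' when noise pushes a peel-off below zero) a non-negative least-squares
#' solution is used. Rank-deficient systems are flagged and the affected
#' species are reported unresolved (`NA`), not silently zeroed.
#'
#' @param group One group from [build_overlap_groups()].
#' @param intensities Named vector of feature intensities for one sample.
#' @return List with `intensity` (named by species db index), `resolved`
#'   (logical), `residual` (L2 norm of `y - A x`).
#' @export
deconvolute_group <- function(group, intensities) {
  A <- .group_design(group)
  sol <- .solve_group(A, intensities[group$features],
                      rank_ok = qr(A)$rank == ncol(A))
  nm <- as.character(group$species)
  list(intensity = stats::setNames(sol$x, nm),
       resolved = stats::setNames(rep(sol$resolved, length(nm)), nm),
       residual = sol$residual)
}

#' Isotope-correct a feature table
#'
#' Applies [deconvolute_group()] to every overlap group in every sample
#' independently, producing a species-by-sample matrix of deconvoluted
#' (monoisotopic-equivalent, full-pattern) intensities.
#'
#' @param ft A [feature_table()].
#' @param groups Overlap groups from [build_overlap_groups()].
#' @param db The annotation database.
#' @return List of class `corrected_matrix`: `values` (species x samples),
#'   `species` (db rows of the resolved species, with `key`), `samples`,
#'   `diagnostics` (per group x sample residuals), `unknown_features`
#'   (feature ids in no group).
#' @export
correct_feature_table <- function(ft, groups, db) {
  sp_all <- sort(unique(unlist(lapply(groups, `[[`, "species"))))
  species <- db[sp_all, , drop = FALSE]
  species$key <- species_key(species)
  n_j <- nrow(ft$samples)
  values <- matrix(NA_real_, length(sp_all), n_j,
                   dimnames = list(species$key, ft$samples$sample_id))
  diags <- list()
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    rows <- match(grp$species, sp_all)
    A <- .group_design(grp)
    rank_ok <- qr(A)$rank == ncol(A)
    yi <- ft$intensities[grp$features, , drop = FALSE]
    for (j in seq_len(n_j)) {
      sol <- .solve_group(A, yi[, j], rank_ok)
      values[rows, j] <- sol$x
      diags[[length(diags) + 1]] <- data.frame(
        group = g, sample_id = ft$samples$sample_id[j],
        n_species = length(grp$species), n_features = length(grp$features),
        residual = sol$residual, resolved = sol$resolved)
    }
  }
  grouped_feats <- unique(unlist(lapply(groups, `[[`, "features")))
  structure(list(
    values = values, species = species, samples = ft$samples,
    diagnostics = do.call(rbind, diags),
    unknown_features = setdiff(ft$features$feature_id, grouped_feats)),
    class = "corrected_matrix")
}

#' @export
print.corrected_matrix <- function(x, ...) {
  cat("<corrected_matrix> ", nrow(x$values), " species x ", ncol(x$values),
      " samples; ", length(x$unknown_features), " unannotated features\n",
      sep = "")
  invisible(x)
}

#' Write a corrected (or abundance) matrix as TSV
#'
#' @param x A `corrected_matrix` or `abundance_matrix`.
#' @param path Output file.
#' @param header Optional comment line(s).
#' @export
write_matrix_tsv <- function(x, path, header = NULL) {
  tab <- cbind(x$species, as.data.frame(x$values))
  if (!is.null(header)) writeLines(paste0("# ", header), path)
  suppressWarnings(
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = !is.null(header)))
  invisible(path)
}
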