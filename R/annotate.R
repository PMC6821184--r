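#' Signed ppm mass error
#'
#' @param observed_mz,theoretical_mz m/z values; the theoretical m/z is the
#'   denominator.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical m/z must be positive")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Match observed features to database entries within a ppm tolerance
#'
#' Every database isotopologue peak (shifts `0..max_shift`) within
#' `tolerance_ppm` of a feature's m/z, in the feature's ion mode, is recorded
#' as a candidate. Per feature, the accepted candidate is the one with
#' minimum absolute ppm error (ties broken by lower double-bond count, then
#' lexical class order, then lower isotopologue shift). Features with no
#' candidate remain unannotated (absent from the output).
#'
#' @param ft A [feature_table()].
#' @param db A `lipid_db` from [build_database()].
#' @param tolerance_ppm Match tolerance (default 3 ppm).
#' @param max_shift Isotopologue shifts considered per entry (default 3).
#' @param rt_window Optional retention-time window (minutes): if supplied, a
#'   candidate is only kept when `|feature rt - db entry rt|` is within it.
#'   Off (`NULL`) by default; the identification step is mass-based.
#' @return Data frame of candidates: `feature_id`, `db_index`, `class`,
#'   `carbons`, `double_bonds`, `adduct`, `isotopologue_shift`,
#'   `theoretical_mz` (of that isotopologue), `ppm_error`, `accepted`.
#' @export
match_features <- function(ft, db, tolerance_ppm = 3, max_shift = 3,
                           rt_window = NULL) {
  if (is.unsorted(db$theoretical_mz)) db <- db[order(db$theoretical_mz), ]
  peaks <- .theoretical_peaks(db, max_shift)
  peaks$polarity <- db$polarity[peaks$db_index]
  out <- list()
  for (pol in unique(ft$features$ion_mode)) {
    fi <- which(ft$features$ion_mode == pol)
    pk <- peaks[peaks$polarity == pol, ]
    if (nrow(pk) == 0 || length(fi) == 0) next
    pk <- pk[order(pk$mz), ]
    mz <- ft$features$mz[fi]
    lo <- findInterval(mz * (1 - tolerance_ppm * 1e-6), pk$mz) + 1
    hi <- findInterval(mz * (1 + tolerance_ppm * 1e-6), pk$mz)
    n <- pmax(hi - lo + 1, 0)
    if (sum(n) == 0) next
    frow <- rep(fi, n)
    prow <- unlist(mapply(function(a, b) if (b >= a) a:b else integer(0),
                          lo, hi, SIMPLIFY = FALSE))
    cand <- data.frame(
      feature_id = ft$features$feature_id[frow],
      db_index = pk$db_index[prow],
      isotopologue_shift = pk$shift[prow],
      theoretical_mz = pk$mz[prow],
      ppm_error = ppm_error(ft$features$mz[frow], pk$mz[prow]),
      stringsAsFactors = FALSE)
    out[[pol]] <- cand
  }
  if (length(out) == 0) {
    ann <- data.frame(feature_id = character(), db_index = integer(),
                      class = character(), carbons = integer(),
                      double_bonds = integer(), adduct = character(),
                      isotopologue_shift = integer(),
                      theoretical_mz = numeric(), ppm_error = numeric(),
                      accepted = logical())
    return(ann)
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann$class <- db$class[ann$db_index]
  ann$carbons <- db$carbons[ann$db_index]
  ann$double_bonds <- db$double_bonds[ann$db_index]
  ann$adduct <- db$adduct[ann$db_index]
  ann <- ann[abs(ann$ppm_error) <= tolerance_ppm, ]
  # acceptance: per feature the min |ppm|, tie-break by double bonds, class,
  # then shift for determinism
  ord <- order(ann$feature_id, abs(ann$ppm_error), ann$double_bonds,
               ann$class, ann$isotopologue_shift)
  ann <- ann[ord, ]
  ann$accepted <- !duplicated(ann$feature_id)
  rownames(ann) <- NULL
  ann[, c("feature_id", "db_index", "class", "carbons", "double_bonds",
          "adduct", "isotopologue_shift", "theoretical_mz", "ppm_error",
          "accepted")]
}

#' Assemble overlap groups of unresolved isotopologue clusters
#'
#' Species whose monoisotopic peak was annotated (accepted at shift 0) are
#' deconvolution members. Each member's theoretical isotopologue peaks
#' (shifts `0..max_shift`) are mapped to the nearest observed feature within
#' the resolution-model merge threshold at that m/z; species sharing a
#' feature belong to one group (connected components). Groups partition
#' their features; a single-species group is a valid trivial system.
#'
#' @param ft A [feature_table()].
#' @param annotations Output of [match_features()].
#' @param db The database used for annotation.
#' @param max_shift Isotopologue shifts mapped per species.
#' @param resolving_power,ref_mz,peak_width_multiple Resolution model passed
#'   to [merge_threshold()].
#' @param merge_tol Optional fixed merge threshold in Da overriding the
#'   resolution model.
#' @return List of groups; each group is a list with `species` (db row
#'   indices), `features` (feature ids) and `map` (data frame `db_index`,
#'   `shift`, `feature_id`, `fraction`).
#' @export
build_overlap_groups <- function(ft, annotations, db, max_shift = 3,
                                 resolving_power = 280000, ref_mz = 200,
                                 peak_width_multiple = 2, merge_tol = NULL) {
  acc <- annotations[annotations$accepted &
                       annotations$isotopologue_shift == 0, ]
  members <- sort(unique(acc$db_index))
  if (length(members) == 0) return(list())
  peaks <- .theoretical_peaks(db[members, , drop = FALSE], max_shift)
  peaks$db_index <- members[peaks$db_index]
  peaks$polarity <- db$polarity[peaks$db_index]
  maps <- list()
  for (pol in unique(peaks$polarity)) {
    pk <- peaks[peaks$polarity == pol, ]
    fi <- which(ft$features$ion_mode == pol)
    if (length(fi) == 0) next
    fmz <- ft$features$mz[fi]
    fo <- order(fmz)
    fmz <- fmz[fo]; fids <- ft$features$feature_id[fi][fo]
    idx <- findInterval(pk$mz, fmz)
    low <- pmax(idx, 1); high <- pmin(idx + 1, length(fmz))
    d_low <- abs(pk$mz - fmz[low]); d_high <- abs(pk$mz - fmz[high])
    nearest <- ifelse(d_low <= d_high, low, high)
    dist <- pmin(d_low, d_high)
    thr <- if (is.null(merge_tol))
      merge_threshold(pk$mz, resolving_power, ref_mz, peak_width_multiple)
    else merge_tol
    keep <- dist <= thr
    if (!any(keep)) next
    maps[[pol]] <- data.frame(
      db_index = pk$db_index[keep], shift = pk$shift[keep],
      feature_id = fids[nearest[keep]], fraction = pk$fraction[keep],
      stringsAsFactors = FALSE)
  }
  if (length(maps) == 0) return(list())
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  # require the monoisotopic peak to be mapped
  has_m0 <- unique(map$db_index[map$shift == 0])
  map <- map[map$db_index %in% has_m0, ]
  # connected components over the bipartite species-feature graph
  sp <- sort(unique(map$db_index))
  parent <- seq_along(sp)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sp_of_feat <- split(match(map$db_index, sp), map$feature_id)
  for (v in sp_of_feat) {
    v <- unique(v)
    r <- find(v[1])
    for (w in v[-1]) {
      rw <- find(w)
      if (rw != r) parent[rw] <- r
    }
  }
  comp <- vapply(seq_along(sp), find, integer(1))
  lapply(split(sp, comp), function(s) {
    gm <- map[map$db_index %in% s, ]
    list(species = s, features = sort(unique(gm$feature_id)), map = gm)
  })
}
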