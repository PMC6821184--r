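#' Default internal-standard map
#'
#' Maps each lipid class to its internal-standard species and spiked amount.
#' Ether (`[O]`) classes have no standards of their own and are normalized
#' on the standard of the corresponding diacyl class, under the usual
#' equal-response assumption.
#'
#' @return Data frame with columns `class`, `std_class`, `std_carbons`,
#'   `std_double_bonds`, `nmol`.
#' @export
default_is_map <- function() {
  std <- internal_standards()
  base <- data.frame(class = std$class, std_class = std$class,
                     std_carbons = std$carbons,
                     std_double_bonds = std$double_bonds, nmol = std$nmol,
                     stringsAsFactors = FALSE)
  ether <- paste0(c("PC", "LPC", "PE", "LPE", "PS", "DG", "TG"), "[O]")
  eth <- base[match(.base_class(ether), base$class), ]
  eth$class <- ether
  rbind(base, eth)
}

#' Internal-standard normalization and protein scaling
#'
#' For classes covered by the internal-standard map, species values become
#' `(species intensity / IS intensity) * IS nmol / protein_mg`, in nmol per
#' mg protein. Classes without a standard are scaled by protein only and
#' unit-tagged `intensity_per_mg`; their values are comparable across
#' samples but not across classes. Samples in which a class's IS intensity
#' is zero get `NA` for that class (flagged invalid).
#'
#' @param corrected A `corrected_matrix` from [correct_feature_table()].
#' @param is_map Data frame as [default_is_map()].
#' @return Object of class `abundance_matrix`: `values` (species x samples),
#'   `species` (with `unit` and `is_standard`), `samples`, `invalid` (class x
#'   sample logical matrix of zero-IS flags).
#' @export
normalize_abundance <- function(corrected, is_map = default_is_map()) {
  sp <- corrected$species
  if (any(corrected$samples$protein_mg <= 0)) {
    bad <- corrected$samples$sample_id[corrected$samples$protein_mg <= 0]
    stop("non-positive protein_mg for sample(s): ",
         paste(bad, collapse = ", "))
  }
  values <- corrected$values
  unit <- rep("intensity_per_mg", nrow(sp))
  classes <- unique(sp$class)
  invalid <- matrix(FALSE, length(classes), ncol(values),
                    dimnames = list(classes, colnames(values)))
  for (cl in classes) {
    rows <- which(sp$class == cl)
    m <- is_map[match(cl, is_map$class), ]
    std_row <- NA_integer_
    if (!is.na(m$class)) {
      std_row <- which(sp$class == m$std_class &
                         sp$carbons == m$std_carbons &
                         sp$double_bonds == m$std_double_bonds &
                         sp$is_standard)
    }
    if (!is.na(m$class) && length(std_row) == 1) {
      is_int <- values[std_row, ]
      zero <- !is.na(is_int) & is_int == 0
      invalid[cl, zero] <- TRUE
      ratio <- sweep(corrected$values[rows, , drop = FALSE], 2, is_int, `/`)
      ratio[, zero] <- NA
      values[rows, ] <- ratio * m$nmol
      unit[rows] <- "nmol_per_mg"
    }
  }
  values <- sweep(values, 2, corrected$samples$protein_mg, `/`)
  species <- sp
  species$unit <- unit
  structure(list(values = values, species = species,
                 samples = corrected$samples, invalid = invalid),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix> ", nrow(x$values), " species x ", ncol(x$values),
      " samples (", sum(x$species$unit == "nmol_per_mg"),
      " IS-normalized)\n", sep = "")
  invisible(x)
}

#' Class totals
#'
#' Arithmetic sum of species abundances per lipid class per sample, internal
#' standards excluded. The per-class unit tag is propagated; totals of
#' different classes rest on different internal standards (equal-response
#' assumption) and must not be compared with each other, only across sample
#' groups within a class.
#'
#' @param abundance An `abundance_matrix`.
#' @return List of class `class_totals`: `values` (class x sample), `unit`
#'   (named per class).
#' @export
class_totals <- function(abundance) {
  sp <- abundance$species
  keep <- !sp$is_standard
  cl <- sp$class[keep]
  vals <- abundance$values[keep, , drop = FALSE]
  units <- tapply(sp$unit[keep], cl, function(u) unique(u))
  if (any(lengths(units) > 1))
    stop("mixed unit tags within class(es): ",
         paste(names(units)[lengths(units) > 1], collapse = ", "))
  out <- rowsum(vals, group = cl)
  structure(list(values = out,
                 unit = stats::setNames(unlist(units), names(units)),
                 comparable_across_classes = FALSE),
            class = "class_totals")
}

#' Fold changes of patient versus control group means
#'
#' @param values Species- or class-by-sample matrix.
#' @param groups Character vector of group labels per sample (column).
#' @param control Label of the control group; all other samples are pooled
#'   as the comparison (patient) group unless `comparison` is given.
#' @param comparison Optional label restricting the comparison group.
#' @return Data frame: `key`, `control_mean`, `patient_mean`, `fold`,
#'   `status` (`"ratio"`, `"patients_only"` when the control mean is zero
#'   with a positive patient mean, `"undetected"` when both means are zero).
#'   `fold` is `NA` for the sentinel rows; no infinities are produced.
#' @export
fold_changes <- function(values, groups, control = "control",
                         comparison = NULL) {
  ctrl <- groups == control
  if (!any(ctrl)) stop("no samples in control group '", control, "'")
  if (is.null(comparison)) comp <- !ctrl
  else comp <- groups %in% comparison
  if (!any(comp)) stop("no samples in comparison group")
  cm <- rowMeans(values[, ctrl, drop = FALSE], na.rm = TRUE)
  pm <- rowMeans(values[, comp, drop = FALSE], na.rm = TRUE)
  status <- ifelse(cm > 0, "ratio",
                   ifelse(pm > 0, "patients_only", "undetected"))
  fold <- ifelse(cm > 0, pm / cm, NA_real_)
  data.frame(key = rownames(values), control_mean = cm, patient_mean = pm,
             fold = fold, status = status, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Flag polyunsaturated-fatty-acid-rich species
#'
#' A species is PUFA-flagged when its side chains hold 38 or more combined
#' carbon atoms and five or more double bonds, e.g. PS(40:5).
#'
#' @param species Data frame with `carbons` and `double_bonds`.
#' @return Logical vector.
#' @export
flag_pufa <- function(species) {
  species$carbons >= 38 & species$double_bonds >= 5
}

#' Classify sn-1 linkage from an acid-hydrolysis pair
#'
#' Hydrochloric-acid treatment hydrolyses the plasmenyl (vinyl-ether) but not
#' the plasmanyl (alkyl) sn-1 linkage, so the fraction of a species surviving
#' treatment separates the two: below `survival_threshold` is plasmenyl
#' (plasmalogen), at or above is plasmanyl. Species undetected before
#' treatment are indeterminate.
#'
#' @param untreated,treated Non-negative abundances of the same species in
#'   untreated and treated aliquots (vectors).
#' @param survival_threshold Fraction-remaining cutoff (default 0.5).
#' @param detection_floor Untreated abundances at or below this are
#'   indeterminate (default 0).
#' @return Character vector: `"plasmanyl"`, `"plasmenyl"` or
#'   `"indeterminate"`.
#' @export
classify_sn1_linkage <- function(untreated, treated,
                                 survival_threshold = 0.5,
                                 detection_floor = 0) {
  if (any(untreated < 0, na.rm = TRUE) || any(treated < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  frac <- treated / untreated
  out <- ifelse(frac < survival_threshold, "plasmenyl", "plasmanyl")
  out[is.na(untreated) | untreated <= detection_floor] <- "indeterminate"
  out
}

#' Pair untreated and treated runs and classify ether species
#'
#' Aligns two corrected (or abundance) matrices from an acid-hydrolysis
#' experiment by species key. The untreated run defines the species set;
#' species absent from the treated run are fully hydrolysed and enter with
#' abundance zero. Ether (`[O]`) species are then classified with
#' [classify_sn1_linkage()].
#'
#' @param untreated,treated `corrected_matrix` or `abundance_matrix` objects
#'   from the two runs.
#' @param survival_threshold,detection_floor Passed to
#'   [classify_sn1_linkage()].
#' @return Data frame: `key`, `class`, `untreated`, `treated` (per-species
#'   mean across samples), `fraction_remaining`, `linkage` (`NA` for
#'   non-ether species).
#' @export
classify_hydrolysis_experiment <- function(untreated, treated,
                                           survival_threshold = 0.5,
                                           detection_floor = 0) {
  keys <- rownames(untreated$values)
  u <- rowMeans(untreated$values, na.rm = TRUE)
  tv <- rep(0, length(keys))
  hit <- match(keys, rownames(treated$values))
  tv[!is.na(hit)] <- rowMeans(treated$values, na.rm = TRUE)[hit[!is.na(hit)]]
  out <- data.frame(key = keys, class = untreated$species$class,
                    untreated = u, treated = tv,
                    fraction_remaining = tv / u, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$linkage <- NA_character_
  eth <- .is_ether_class(out$class) & !untreated$species$is_standard
  out$linkage[eth] <- classify_sn1_linkage(
    out$untreated[eth], out$treated[eth],
    survival_threshold = survival_threshold,
    detection_floor = detection_floor)
  out
}

#' Enzyme specific activity by stable-isotope dilution
#'
#' Converts a product peak area to an amount via the internal-standard ratio
#' and the calibration curve, then to a specific activity. The measured
#' response is `y = product_area / is_area * is_pmol`; the calibration curve
#' (same response model, `y` versus known amount) is fitted by ordinary least
#' squares and inverted. With a blank record supplied, the blank amount is
#' subtracted before computing activity.
#'
#' @param record A one-row data frame (or list) with `product_area`,
#'   `is_area`, `is_pmol`, `protein_mg`, `hours`.
#' @param calibration Data frame with `amount_pmol` and `area_ratio`
#'   (product area / IS area for the known amounts); at least 2 points.
#' @param blank Optional blank record; its measured amount is subtracted.
#' @param through_origin Fit the calibration without intercept.
#' @return List: `amount_pmol`, `activity` (pmol/h/mg), `calibration_slope`,
#'   `calibration_intercept`.
#' @export
enzyme_activity <- function(record, calibration, blank = NULL,
                            through_origin = FALSE) {
  if (nrow(calibration) < 2) stop("calibration needs >= 2 points")
  if (record$is_area <= 0) stop("internal-standard area must be positive")
  y_cal <- calibration$area_ratio * record$is_pmol
  fit <- if (through_origin)
    stats::lm(y_cal ~ 0 + amount_pmol, data = calibration)
  else stats::lm(y_cal ~ amount_pmol, data = calibration)
  cf <- stats::coef(fit)
  slope <- cf[["amount_pmol"]]
  intercept <- if (through_origin) 0 else cf[[1]]
  if (abs(slope) < 1e-12 * max(1, max(abs(y_cal))))
    stop("calibration curve has zero slope; cannot invert")
  measure <- function(r) {
    y <- r$product_area / r$is_area * r$is_pmol
    (y - intercept) / slope
  }
  amount <- measure(record)
  if (!is.null(blank)) amount <- amount - measure(blank)
  list(amount_pmol = amount,
       activity = amount / (record$protein_mg * record$hours),
       calibration_slope = slope, calibration_intercept = intercept)
}
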