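#' Lipid class construction rules
#'
#' The per-class backbone formulas and increments that turn a shorthand
#' species annotation like `PC(34:1)` into an elemental formula, read from the
#' versioned rule table shipped with the package.
#'
#' @return Data frame with one row per class: `class`, `n_chains`, base atom
#'   counts `C`,`H`,`N`,`O`,`P`, `min_carbons`, `ether_allowed`, default
#'   `polarity` and `adduct`.
#' @export
class_rules <- function() {
  if (is.null(.lp_cache$classes))
    .lp_cache$classes <- .read_constants("lipid_classes.tsv")
  .lp_cache$classes
}

#' Adduct definitions
#'
#' @return Data frame with columns `label`, `polarity`, `mass_delta` (Da,
#'   electron mass included) and `charge`.
#' @export
adduct_table <- function() {
  if (is.null(.lp_cache$adducts))
    .lp_cache$adducts <- .read_constants("adducts.tsv")
  .lp_cache$adducts
}

#' Internal-standard panel
#'
#' The synthetic short-chain internal standards spiked into every extraction,
#' with spiked amounts in nmol (per extraction of 1 mg protein).
#'
#' @return Data frame with columns `class`, `carbons`, `double_bonds`, `nmol`.
#' @export
internal_standards <- function() {
  if (is.null(.lp_cache$standards))
    .lp_cache$standards <- .read_constants("internal_standards.tsv")
  .lp_cache$standards
}

.base_class <- function(class) sub("\\[O\\]$", "", class)
.is_ether_class <- function(class) grepl("\\[O\\]$", class)

#' Construct a lipid species
#'
#' A lipid species is identified by its class (with optional `[O]` ether
#' suffix), total side-chain carbon count, total side-chain double-bond count
#' and sn-1 linkage. Plasmenyl (vinyl-ether, plasmalogen) species are
#' represented as alkyl species whose vinyl-ether double bond is counted in
#' `double_bonds`, so `sn1_linkage` does not change the formula; it carries
#' the chemical identity needed by the acid-hydrolysis classification.
#'
#' @param class Class code, e.g. `"PC"`, `"PE[O]"`, `"TG"`.
#' @param carbons Total side-chain carbons.
#' @param double_bonds Total side-chain double bonds (vinyl-ether bond
#'   included for plasmenyl species).
#' @param sn1_linkage `"acyl"` (default for non-ether classes), `"alkyl"`,
#'   `"alkenyl"` or `"unknown"` (default for ether classes).
#' @return A one-row data frame with class `lipid_species`.
#' @examples
#' lipid_species("PC", 34, 1)
#' lipid_species("PE[O]", 36, 2, sn1_linkage = "alkenyl")
#' @export
lipid_species <- function(class, carbons, double_bonds,
                          sn1_linkage = NULL) {
  rules <- class_rules()
  base <- .base_class(class)
  ether <- .is_ether_class(class)
  row <- rules[rules$class == base, ]
  if (nrow(row) != 1) stop("unregistered lipid class: ", class)
  if (ether && row$ether_allowed != "yes")
    stop("ether variant not allowed for class ", base)
  if (carbons < row$min_carbons)
    stop(class, ": carbons below class minimum (", row$min_carbons, ")")
  if (double_bonds < 0) stop("double_bonds must be >= 0")
  if (is.null(sn1_linkage)) sn1_linkage <- if (ether) "unknown" else "acyl"
  if (ether && sn1_linkage == "acyl")
    stop("ether species cannot have an acyl sn-1 linkage")
  if (!ether && sn1_linkage != "acyl")
    stop("non-ether species must have an acyl sn-1 linkage")
  out <- data.frame(class = class, carbons = as.integer(carbons),
                    double_bonds = as.integer(double_bonds),
                    sn1_linkage = sn1_linkage, stringsAsFactors = FALSE)
  class(out) <- c("lipid_species", "data.frame")
  out
}

#' Elemental formula of a lipid species
#'
#' Applies the class construction rule: base formula plus one C and two H per
#' side-chain carbon, minus two H per double bond; ether (`[O]`) species are
#' the diacyl counterpart minus O plus 2 H.
#'
#' @param species A `lipid_species` (one row) or a data frame with columns
#'   `class`, `carbons`, `double_bonds`.
#' @return An `el_formula`.
#' @examples
#' format(build_formula(lipid_species("PC", 28, 0))) # di-14:0 PC
#' @export
build_formula <- function(species) {
  rules <- class_rules()
  base <- .base_class(species$class)
  ether <- .is_ether_class(species$class)
  row <- rules[rules$class == base, ]
  if (nrow(row) != 1) stop("unregistered lipid class: ", species$class)
  if (species$carbons < row$min_carbons)
    stop(species$class, ": carbons below class minimum")
  h <- row$H + 2 * species$carbons - 2 * species$double_bonds + if (ether) 2 else 0
  o <- row$O - if (ether) 1 else 0
  if (h < 0 || o < 0)
    stop("degenerate composition for ", species_key(species))
  el_formula(C = row$C + species$carbons, H = h, N = row$N, O = o, P = row$P)
}

#' Shorthand key for a species
#'
#' @param species Data frame with `class`, `carbons`, `double_bonds`.
#' @return Character vector like `"PC(34:1)"`.
#' @export
species_key <- function(species) {
  paste0(species$class, "(", species$carbons, ":", species$double_bonds, ")")
}

#' m/z of a formula under an adduct
#'
#' @param formula `el_formula` or formula string.
#' @param adduct Adduct label, e.g. `"[M+H]+"`, or a one-row data frame from
#'   [adduct_table()].
#' @return (monoisotopic mass + adduct mass delta) / charge.
#' @export
mz_of <- function(formula, adduct) {
  if (is.character(adduct)) {
    tab <- adduct_table()
    row <- tab[tab$label == adduct, ]
    if (nrow(row) != 1) stop("unknown adduct: ", adduct)
    adduct <- row
  }
  if (adduct$charge < 1) stop("adduct charge must be >= 1")
  (monoisotopic_mass(formula) + adduct$mass_delta) / adduct$charge
}

#' Default database enumeration config
#'
#' Carbon and double-bond ranges per lipid class for the default species
#' database, covering the classes of the internal-standard panel plus the
#' ether (`[O]`) variants relevant to ether-lipid biosynthesis defects
#' (including plasmanyl-PS). One primary adduct per class, in the class's
#' routine polarity.
#'
#' @param study_only If `TRUE` (default) restrict to the classes simulated in
#'   the synthetic study; if `FALSE` include every class with an internal
#'   standard.
#' @return Data frame with columns `class`, `carbons_min`, `carbons_max`,
#'   `carbons_step`, `db_min`, `db_max`, `adduct`.
#' @export
default_class_config <- function(study_only = TRUE) {
  cfg <- data.frame(
    class       = c("PC", "PC[O]", "LPC", "LPC[O]", "PE", "PE[O]",
                    "LPE", "LPE[O]", "PS", "PS[O]", "PI",
                    "DG", "DG[O]", "TG", "TG[O]"),
    carbons_min = c(30, 30, 16, 14, 32, 32, 16, 16, 34, 34, 34,
                    30, 30, 48, 48),
    carbons_max = c(40, 38, 20, 18, 40, 40, 22, 20, 40, 38, 38,
                    36, 34, 54, 52),
    carbons_step = 2L,
    db_min      = c(0, 0, 0, 0, 0, 1, 0, 1, 0, 1, 0, 0, 0, 0, 0),
    db_max      = c(5, 3, 2, 1, 6, 5, 2, 2, 6, 3, 4, 3, 2, 5, 3),
    stringsAsFactors = FALSE
  )
  rules <- class_rules()
  cfg$adduct <- rules$adduct[match(.base_class(cfg$class), rules$class)]
  if (!study_only) {
    extra <- setdiff(internal_standards()$class, .base_class(cfg$class))
    if (length(extra) > 0) {
      rows <- rules[rules$class %in% extra, ]
      cfg <- rbind(cfg, data.frame(
        class = rows$class,
        carbons_min = rows$min_carbons + 24, carbons_max = rows$min_carbons + 32,
        carbons_step = 2L, db_min = 0, db_max = 3, adduct = rows$adduct))
    }
  }
  cfg
}

#' Build a lipid species database
#'
#' Cartesian enumeration of species over the per-class carbon and double-bond
#' ranges, each paired with its class's adduct, plus the internal-standard
#' species of every enumerated class flagged `is_standard`. Entries are
#' sorted by theoretical m/z.
#'
#' @param class_config Data frame as returned by [default_class_config()].
#' @param include_standards Add the internal-standard species for each class
#'   present in the config (default `TRUE`). `[O]` classes map to the diacyl
#'   class standard, which is already a separate entry.
#' @return Data frame (`lipid_db`) with columns `class`, `carbons`,
#'   `double_bonds`, `sn1_linkage`, `formula`, `adduct`, `polarity`, `charge`,
#'   `theoretical_mz`, `is_standard`.
#' @export
build_database <- function(class_config = default_class_config(),
                           include_standards = TRUE) {
  if (is.null(class_config) || nrow(class_config) == 0) {
    out <- data.frame(class = character(), carbons = integer(),
                      double_bonds = integer(), sn1_linkage = character(),
                      formula = character(), adduct = character(),
                      polarity = character(), charge = integer(),
                      theoretical_mz = numeric(), is_standard = logical())
    class(out) <- c("lipid_db", "data.frame")
    return(out)
  }
  if (anyDuplicated(class_config$class))
    stop("duplicate class definitions in config")
  rows <- lapply(seq_len(nrow(class_config)), function(i) {
    cc <- class_config[i, ]
    grid <- expand.grid(
      carbons = seq(cc$carbons_min, cc$carbons_max, by = cc$carbons_step),
      double_bonds = seq(cc$db_min, cc$db_max))
    data.frame(class = cc$class, grid, adduct = cc$adduct,
               is_standard = FALSE, stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, rows)
  if (include_standards) {
    std <- internal_standards()
    std <- std[std$class %in% .base_class(class_config$class), ]
    if (nrow(std) > 0) {
      rules <- class_rules()
      cfgad <- class_config$adduct[match(std$class, class_config$class)]
      cfgad[is.na(cfgad)] <- rules$adduct[match(std$class[is.na(cfgad)],
                                                rules$class)]
      db <- rbind(db, data.frame(class = std$class, carbons = std$carbons,
                                 double_bonds = std$double_bonds,
                                 adduct = cfgad, is_standard = TRUE))
    }
  }
  # drop duplicates where a standard coincides with an enumerated species:
  # keep the standard-flagged row
  key <- paste(db$class, db$carbons, db$double_bonds, db$adduct)
  db <- db[order(key, !db$is_standard), ]
  db <- db[!duplicated(paste(db$class, db$carbons, db$double_bonds, db$adduct)), ]

  db$sn1_linkage <- ifelse(.is_ether_class(db$class), "unknown", "acyl")
  ad <- adduct_table()
  am <- match(db$adduct, ad$label)
  if (anyNA(am)) stop("unknown adduct in config")
  db$polarity <- ad$polarity[am]
  db$charge <- ad$charge[am]
  forms <- vapply(seq_len(nrow(db)), function(i) {
    format(build_formula(db[i, ]))
  }, character(1))
  db$formula <- forms
  mono <- vapply(forms, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)
  db$theoretical_mz <- (mono + ad$mass_delta[am]) / ad$charge[am]
  db <- db[order(db$theoretical_mz), ]
  rownames(db) <- NULL
  db <- db[, c("class", "carbons", "double_bonds", "sn1_linkage", "formula",
               "adduct", "polarity", "charge", "theoretical_mz",
               "is_standard")]
  class(db) <- c("lipid_db", "data.frame")
  db
}

#' Write / read a lipid database as TSV
#'
#' @param db A `lipid_db` data frame.
#' @param path Output file.
#' @export
write_database <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  db <- db[order(db$theoretical_mz), ]
  class(db) <- c("lipid_db", "data.frame")
  db
}
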