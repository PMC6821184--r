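# Shared fixtures, built in code at test time.

# A small class panel (about 30 species) for fast end-to-end tests.
small_class_config <- function() {
  cfg <- default_class_config()
  cfg <- cfg[cfg$class %in% c("PC", "PC[O]", "PE", "PE[O]", "TG"), ]
  cfg$carbons_max <- pmin(cfg$carbons_max, cfg$carbons_min + 4)
  cfg$db_max <- pmin(cfg$db_max, 2)
  cfg
}

# A panel without isotopologue overlap: single double-bond count per class,
# carbons two apart, so no species' M+2 can land on another's M0.
no_overlap_config <- function() {
  cfg <- small_class_config()
  cfg$db_max <- cfg$db_min
  cfg
}

# Annotate + group + correct in one call.
run_correction <- function(ft, db, ...) {
  ann <- match_features(ft, db, ...)
  groups <- build_overlap_groups(ft, ann, db)
  correct_feature_table(ft, groups, db)
}

# A synthetic overlap group for constructed deconvolution systems.
# fractions: list per species, named by isotopologue shift; feat_of: list per
# species mapping each shift to a feature id.
make_group <- function(fractions, feat_of) {
  map <- do.call(rbind, lapply(seq_along(fractions), function(s) {
    data.frame(db_index = s,
               shift = as.integer(names(fractions[[s]])),
               feature_id = feat_of[[s]],
               fraction = as.numeric(fractions[[s]]),
               stringsAsFactors = FALSE)
  }))
  list(species = seq_along(fractions),
       features = sort(unique(map$feature_id)), map = map)
}

# A strictly triangular double-bond overlap chain of k species:
# species s has its M0 on feature s and an M+2 fraction landing on feature
# s+1 (the next species' M0), the classic unresolved-isotope geometry.
make_chain_group <- function(k, f2 = 0.06) {
  fractions <- lapply(seq_len(k), function(s) {
    if (s < k) c(`0` = 1, `2` = f2) else c(`0` = 1)
  })
  feat_of <- lapply(seq_len(k), function(s) {
    if (s < k) paste0("F", c(s, s + 1)) else paste0("F", s)
  })
  make_group(fractions, feat_of)
}

# A minimal corrected_matrix for quantify-level tests.
make_corrected <- function(values, classes, carbons, double_bonds,
                           is_standard, protein_mg,
                           groups = rep("control", ncol(values))) {
  species <- data.frame(class = classes, carbons = carbons,
                        double_bonds = double_bonds,
                        sn1_linkage = ifelse(grepl("\\[O\\]$", classes),
                                             "unknown", "acyl"),
                        is_standard = is_standard, stringsAsFactors = FALSE)
  species$key <- species_key(species)
  rownames(values) <- species$key
  samples <- data.frame(
    sample_id = colnames(values), group = groups,
    replicate = seq_len(ncol(values)), protein_mg = protein_mg,
    treatment = "none", matrix = "fibroblast", stringsAsFactors = FALSE)
  structure(list(values = values, species = species, samples = samples,
                 diagnostics = NULL, unknown_features = character()),
            class = "corrected_matrix")
}
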