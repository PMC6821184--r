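#' Pipeline configuration
#'
#' Collects every tunable of the processing pipeline with its default:
#' annotation tolerance (3 ppm), isotopologue truncation (M+3), the
#' resolution model of the instrument (resolving power 280,000 referenced at
#' m/z 200), the internal-standard map, and the statistics options.
#'
#' @param tolerance_ppm Annotation tolerance in ppm.
#' @param max_shift Isotopologue shifts modeled per species.
#' @param resolving_power,ref_mz,peak_width_multiple Resolution model, see
#'   [merge_threshold()].
#' @param is_map Internal-standard map ([default_is_map()]).
#' @param control Control group label.
#' @param var_equal Pooled-variance t-test (Student's) if `TRUE`.
#' @param n_components PLS-DA components.
#' @param top_k Heat-map rows (top VIP-ranked species).
#' @param dunnett Also run Dunnett's test versus control (default `FALSE`;
#'   meaningful with >= 2 comparison groups).
#' @param n_mc Monte-Carlo draws for Dunnett's test.
#' @param seed Seed for the Monte-Carlo stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(tolerance_ppm = 3, max_shift = 3,
                            resolving_power = 280000, ref_mz = 200,
                            peak_width_multiple = 2,
                            is_map = default_is_map(),
                            control = "control", var_equal = TRUE,
                            n_components = 2, top_k = 30,
                            dunnett = FALSE, n_mc = 1e5, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

.config_string <- function(config) {
  cfg <- config
  cfg$is_map <- NULL
  paste0("lipidproc ", as.character(utils::packageVersion("lipidproc")),
         "; config: ",
         jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE))
}

#' Run the full processing pipeline
#'
#' Orchestrates annotation, overlap grouping, isotope correction,
#' internal-standard normalization, class summation, fold changes,
#' differential statistics and PLS-DA/VIP ranking on one feature table.
#' Input is validated per stage; failures raise errors naming the stage and
#' the offending sample or field. Given the same inputs and config the run
#' is deterministic.
#'
#' @param ft A [feature_table()].
#' @param db Annotation database (default [build_database()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, every output table is
#'   written as TSV with a header line carrying the package version and the
#'   effective config.
#' @return List: `annotations`, `groups`, `corrected`, `abundance`,
#'   `class_totals`, `species_stats`, `class_fold`, `plsda`, `vip`,
#'   `heatmap`, `dunnett` (optional), `log` (per-stage counts).
#' @export
run_pipeline <- function(ft, db = build_database(),
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(ft, "feature_table"), inherits(config, "pipeline_config"))
  if (any(ft$samples$protein_mg <= 0))
    stop("quantify stage: non-positive protein_mg for sample(s): ",
         paste(ft$samples$sample_id[ft$samples$protein_mg <= 0],
               collapse = ", "))
  log <- list(features_in = nrow(ft$features), samples = nrow(ft$samples))

  ann <- match_features(ft, db, tolerance_ppm = config$tolerance_ppm,
                        max_shift = config$max_shift)
  log$features_annotated <- length(unique(ann$feature_id[ann$accepted]))
  if (log$features_annotated < 0.5 * log$features_in)
    warning("annotate stage: more than half of the features are unannotated")

  groups <- build_overlap_groups(
    ft, ann, db, max_shift = config$max_shift,
    resolving_power = config$resolving_power, ref_mz = config$ref_mz,
    peak_width_multiple = config$peak_width_multiple)
  log$overlap_groups <- length(groups)

  corrected <- correct_feature_table(ft, groups, db)
  log$species_out <- nrow(corrected$values)

  abundance <- normalize_abundance(corrected, is_map = config$is_map)
  totals <- class_totals(abundance)

  grp <- ft$samples$group
  endo <- !abundance$species$is_standard
  sp_values <- abundance$values[endo, , drop = FALSE]
  stats_tab <- differential_stats(sp_values, grp, control = config$control,
                                  var_equal = config$var_equal)
  log$tests_run <- sum(!is.na(stats_tab$p_t))
  class_fold <- fold_changes(totals$values, grp, control = config$control)

  # the VIP ranking targets the patient-versus-control discrimination;
  # subject-level subgroups are collapsed for the PLS-DA response
  grp_bin <- ifelse(grp == config$control, config$control, "case")
  model <- plsda_fit(t(sp_values), grp_bin,
                     n_components = config$n_components)
  vip <- vip_scores(model)
  hm <- heatmap_matrix(sp_values, vip, k = min(config$top_k,
                                               nrow(sp_values)))
  dn <- NULL
  if (isTRUE(config$dunnett) && length(unique(grp)) > 2)
    dn <- dunnett_vs_control(sp_values, grp, control = config$control,
                             n_mc = config$n_mc, seed = config$seed)

  res <- list(annotations = ann, groups = groups, corrected = corrected,
              abundance = abundance, class_totals = totals,
              species_stats = stats_tab, class_fold = class_fold,
              plsda = model, vip = vip, heatmap = hm, dunnett = dn,
              log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir, config)
  res
}

#' Write every pipeline output table as TSV
#'
#' @param res Result list from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param config The config used; embedded in each file header.
#' @return The output directory, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .config_string(config)
  wt <- function(x, file) {
    p <- file.path(out_dir, file)
    writeLines(paste0("# ", hdr), p)
    suppressWarnings(utils::write.table(x, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  wt(res$annotations, "annotations.tsv")
  write_matrix_tsv(res$corrected, file.path(out_dir, "corrected.tsv"),
                   header = hdr)
  write_matrix_tsv(res$abundance, file.path(out_dir, "abundance.tsv"),
                   header = hdr)
  tot <- data.frame(class = rownames(res$class_totals$values),
                    unit = res$class_totals$unit[rownames(res$class_totals$values)],
                    res$class_totals$values, check.names = FALSE)
  wt(tot, "class_totals.tsv")
  wt(res$species_stats, "species_stats.tsv")
  wt(data.frame(key = names(res$vip), vip = res$vip,
                rank = rank(-res$vip, ties.method = "first")), "vip.tsv")
  wt(data.frame(key = rownames(res$heatmap), res$heatmap,
                check.names = FALSE), "heatmap_matrix.tsv")
  if (!is.null(res$dunnett)) wt(res$dunnett, "dunnett.tsv")
  invisible(out_dir)
}
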