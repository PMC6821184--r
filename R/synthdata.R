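#' Configuration for a synthetic lipidomics study
#'
#' Defaults emulate the study design the pipeline targets: three control and
#' two patient fibroblast lines, each extracted and measured in quadruplicate,
#' a species panel of roughly 270 lipids over the phospholipid, lysolipid,
#' neutral-lipid and ether-lipid classes, internal standards spiked at the
#' panel amounts (e.g. 2.0 nmol PC(14:0)2, 0.5 nmol PE(14:0)2 per extraction),
#' multiplicative log-normal intensity noise (CV 15 percent), Gaussian mass
#' error (SD 1 ppm), and class-level patient effects: ether-PC, neutral and
#' neutral-ether classes accumulate, diacyl PC/PE and their lyso and ether
#' analogues are reduced, and plasmanyl-PS appears in patients only.
#'
#' @param classes Class enumeration config ([default_class_config()]).
#' @param n_controls,n_patients Number of control / patient subjects.
#' @param n_replicates Technical replicates per subject (quadruplicate).
#' @param multipliers Named vector of patient-vs-control class fold
#'   multipliers (> 0); classes absent from the vector are unperturbed.
#' @param multiplier_sdlog Log-SD of the fixed per-species effect
#'   heterogeneity around the class multiplier: each perturbed species
#'   carries its own fold change, drawn once per study (it belongs to the
#'   biology, not to the measurement noise).
#' @param noise_seed Seed of the measurement-noise stream (intensity noise,
#'   mass error). Defaults to `seed + 5000`; regenerating with the same
#'   `seed` but a different `noise_seed` yields a fresh noise realization of
#'   the same underlying biology.
#' @param pso_patient_meanlog Log-mean of the patients-only plasmanyl-PS
#'   baseline (nmol/mg); controls carry a true zero.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-species baseline abundance (nmol/mg protein).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise.
#' @param ppm_sd SD (ppm) of the Gaussian mass error on feature m/z.
#' @param protein_sdlog Log-SD of per-sample protein content around 1 mg.
#' @param response Named per-class instrument response factors
#'   (intensity units per nmol); classes absent default to 1.
#' @param resolving_power,ref_mz,peak_width_multiple Resolution model: peaks
#'   closer than `peak_width_multiple` x FWHM merge into one observed
#'   feature, with FWHM = mz^1.5 / (resolving_power * sqrt(ref_mz)).
#' @param max_shift Isotopologues emitted per species (0..max_shift).
#' @param matrix `"fibroblast"` or `"plasma"` (plasma replaces protein
#'   scaling by volume scaling; the generator is otherwise identical).
#' @param linkage Named vector assigning the true sn-1 linkage per ether
#'   class; the default encodes plasmanyl PC/LPC/PS/DG/TG ethers and
#'   plasmenyl (plasmalogen) PE/LPE ethers.
#' @param seed Integer seed; fully determines the generated study.
#' @return A list of class `study_config`.
#' @export
study_config <- function(classes = default_class_config(),
                         n_controls = 3, n_patients = 2, n_replicates = 4,
                         multipliers = c("PC[O]" = 4, "LPC[O]" = 3,
                                         "DG" = 2, "TG" = 2,
                                         "DG[O]" = 3, "TG[O]" = 4,
                                         "PC" = 0.5, "LPC" = 0.5,
                                         "PE" = 0.5, "LPE" = 0.5,
                                         "PE[O]" = 0.5, "LPE[O]" = 0.5),
                         multiplier_sdlog = 0.25,
                         pso_patient_meanlog = log(0.05),
                         baseline_meanlog = log(0.5), baseline_sdlog = 0.7,
                         noise_cv = 0.15, ppm_sd = 1,
                         protein_sdlog = 0.1,
                         response = c(),
                         resolving_power = 280000, ref_mz = 200,
                         peak_width_multiple = 2,
                         max_shift = 3,
                         matrix = "fibroblast",
                         linkage = c("PC[O]" = "alkyl", "LPC[O]" = "alkyl",
                                     "PS[O]" = "alkyl", "DG[O]" = "alkyl",
                                     "TG[O]" = "alkyl",
                                     "PE[O]" = "alkenyl",
                                     "LPE[O]" = "alkenyl"),
                         seed = 1, noise_seed = seed + 5000) {
  if (any(multipliers <= 0)) stop("class multipliers must be > 0")
  structure(as.list(environment()), class = "study_config")
}

# FWHM of the resolution model at a given m/z.
.fwhm <- function(mz, resolving_power, ref_mz) {
  mz^1.5 / (resolving_power * sqrt(ref_mz))
}

#' Peak-merge threshold of the resolution model
#'
#' Two theoretical peaks closer than this in m/z are unresolvable and appear
#' as one observed feature.
#'
#' @param mz m/z at which to evaluate the threshold.
#' @param resolving_power Resolving power referenced at `ref_mz`.
#' @param ref_mz Reference m/z of the resolving power.
#' @param peak_width_multiple Merge radius in units of FWHM.
#' @return Threshold in Da.
#' @export
merge_threshold <- function(mz, resolving_power = 280000, ref_mz = 200,
                            peak_width_multiple = 2) {
  peak_width_multiple * .fwhm(mz, resolving_power, ref_mz)
}

# Log-normal multiplicative noise with mean 1 and coefficient of variation cv.
.lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# All theoretical isotopologue peaks of a database, with per-peak m/z and
# pattern fraction. Distributions are cached per formula string.
.theoretical_peaks <- function(db, max_shift) {
  dists <- lapply(unique(db$formula), function(f)
    isotope_distribution(parse_formula(f), max_shift))
  names(dists) <- unique(db$formula)
  rows <- lapply(seq_len(nrow(db)), function(i) {
    d <- dists[[db$formula[i]]]
    data.frame(db_index = i, shift = d$shift,
               mz = db$theoretical_mz[i] + d$mass_shift / db$charge[i],
               fraction = d$abundance)
  })
  do.call(rbind, rows)
}

# Render species-level intensities into an observed feature table: emit
# isotopologue peaks, merge unresolvable peaks, centroid each merged cluster
# at its strongest member peak, apply ppm error.
.render_feature_table <- function(db, spec_int, samples, cfg) {
  peaks <- .theoretical_peaks(db, cfg$max_shift)
  peaks$polarity <- db$polarity[peaks$db_index]
  feats <- list(); ints <- list(); m0 <- list(); fid <- 0
  for (pol in unique(peaks$polarity)) {
    pk <- peaks[peaks$polarity == pol, ]
    pk <- pk[order(pk$mz), ]
    thr <- merge_threshold(pk$mz, cfg$resolving_power, cfg$ref_mz,
                           cfg$peak_width_multiple)
    gap_ok <- diff(pk$mz) < (thr[-nrow(pk)] + thr[-1]) / 2
    cluster <- cumsum(c(TRUE, !gap_ok))
    pk_int <- spec_int[pk$db_index, , drop = FALSE] * pk$fraction
    for (cl in split(seq_len(nrow(pk)), cluster)) {
      m <- pk_int[cl, , drop = FALSE]
      tot <- colSums(m)
      if (all(tot == 0)) next
      fid <- fid + 1
      apex <- cl[which.max(rowSums(m))]
      mz_obs <- pk$mz[apex] *
        (1 + stats::rnorm(1, 0, cfg$ppm_sd) * 1e-6)
      lead <- db[pk$db_index[apex], ]
      feats[[fid]] <- data.frame(
        feature_id = NA_character_, mz = mz_obs,
        rt_min = 1 + 0.4 * match(lead$class, unique(db$class)) +
          0.005 * lead$carbons,
        ion_mode = pol, stringsAsFactors = FALSE)
      ints[[fid]] <- tot
      # truth record: which feature holds each member species' monoisotopic
      # peak, and whether that peak is the cluster apex (detectable M0)
      is0 <- which(pk$shift[cl] == 0)
      if (length(is0) > 0)
        m0[[length(m0) + 1]] <- data.frame(
          db_index = pk$db_index[cl[is0]], feature = fid,
          apex = cl[is0] == apex)
    }
  }
  features <- do.call(rbind, feats)
  features$feature_id <- sprintf("F%05d", seq_len(nrow(features)))
  intensities <- do.call(rbind, ints)
  ft <- feature_table(features, intensities, samples)
  m0 <- do.call(rbind, m0)
  m0$feature_id <- features$feature_id[m0$feature]
  m0$feature <- NULL
  attr(ft, "m0_map") <- m0[order(m0$db_index), ]
  ft
}

# Draw per-species truth amounts (nmol/mg) for every sample. The biology
# (baselines, per-species fold changes, patients-only species) is drawn on
# the current RNG stream seeded by cfg$seed; the per-sample measurement
# noise is drawn on a stream seeded by cfg$noise_seed, so the same biology
# can be re-measured under a fresh noise realization.
.draw_amounts <- function(db, samples, cfg) {
  n_s <- nrow(db); n_j <- nrow(samples)
  baseline <- stats::rlnorm(n_s, cfg$baseline_meanlog, cfg$baseline_sdlog)
  pso <- db$class == "PS[O]" & !db$is_standard
  baseline[pso] <- 0
  pso_patient <- stats::rlnorm(sum(pso), cfg$pso_patient_meanlog, 0.5)
  mult <- rep(1, n_s)
  keep <- db$class %in% names(cfg$multipliers) & !db$is_standard
  mult[keep] <- cfg$multipliers[db$class[keep]] *
    stats::rlnorm(sum(keep), 0, cfg$multiplier_sdlog)
  is_patient <- grepl("^patient", samples$group)
  amounts <- matrix(0, n_s, n_j,
                    dimnames = list(species_key(db), samples$sample_id))
  set.seed(cfg$noise_seed)
  for (j in seq_len(n_j)) {
    mean_j <- if (is_patient[j]) baseline * mult else baseline
    if (is_patient[j]) mean_j[pso] <- pso_patient
    amounts[, j] <- mean_j * .lnorm_noise(n_s, cfg$noise_cv)
  }
  # internal standards: fixed spiked nmol per extraction, not per mg
  std <- internal_standards()
  si <- which(db$is_standard)
  amounts[si, ] <- std$nmol[match(db$class[si], std$class)]
  attr(amounts, "species_multipliers") <- mult
  amounts
}

# Species intensity in the extract: endogenous nmol/mg x protein, standards
# fixed nmol; times the class response factor.
.species_intensities <- function(db, amounts, samples, cfg) {
  resp <- rep(1, nrow(db))
  hit <- db$class %in% names(cfg$response)
  resp[hit] <- cfg$response[db$class[hit]]
  extract <- amounts
  endo <- !db$is_standard
  extract[endo, ] <- sweep(amounts[endo, , drop = FALSE], 2,
                           samples$protein_mg, `*`)
  extract * resp
}

#' Simulate a ground-truthed lipidomics study
#'
#' Generates an observed feature table (merged isotopologue peaks, ppm mass
#' error, log-normal intensity noise, spiked internal standards) together
#' with the ground truth needed for parameter-recovery testing.
#'
#' @param config A [study_config()].
#' @param render Render the observed feature table (default). With
#'   `render = FALSE` only the ground truth is generated (`table` is `NULL`),
#'   which is much faster and sufficient for tests that work on true
#'   abundances.
#' @return List with elements `table` (a [feature_table()]), `truth` (list:
#'   `amounts` species x samples nmol/mg, `db` the species table with true
#'   sn-1 linkages, `multipliers`, `m0_map` — per species the feature
#'   carrying its monoisotopic peak and whether that peak is the cluster
#'   apex, i.e. detectable at the instrument resolution —, `noise`, `seed`)
#'   and `db` (the annotation database, linkage `"unknown"` as for real
#'   data).
#' @examples
#' st <- simulate_study(study_config(seed = 7))
#' st$table
#' @export
simulate_study <- function(config = study_config(), render = TRUE) {
  cfg <- config
  db <- build_database(cfg$classes)
  if (nrow(db) == 0) stop("species panel is empty")
  # truth linkage labels
  truth_db <- db
  eth <- .is_ether_class(db$class)
  truth_db$sn1_linkage[eth] <- cfg$linkage[db$class[eth]]
  set.seed(cfg$seed)
  subjects <- c(paste0("C", seq_len(cfg$n_controls)),
                paste0("P", seq_len(cfg$n_patients)))
  groups <- c(rep("control", cfg$n_controls),
              paste0("patient_", seq_len(cfg$n_patients)))
  samples <- data.frame(
    sample_id = paste0(rep(subjects, each = cfg$n_replicates), "_r",
                       seq_len(cfg$n_replicates)),
    group = rep(groups, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), length(subjects)),
    protein_mg = stats::rlnorm(length(subjects) * cfg$n_replicates,
                               0, cfg$protein_sdlog),
    treatment = "none", matrix = cfg$matrix, stringsAsFactors = FALSE)
  amounts <- .draw_amounts(db, samples, cfg)
  ft <- NULL
  if (render) {
    spec_int <- .species_intensities(db, amounts, samples, cfg)
    ft <- .render_feature_table(db, spec_int, samples, cfg)
  }
  truth <- list(amounts = amounts, db = truth_db, samples = samples,
                multipliers = cfg$multipliers,
                species_multipliers = stats::setNames(
                  attr(amounts, "species_multipliers"), species_key(db)),
                m0_map = attr(ft, "m0_map"),
                noise = list(cv = cfg$noise_cv, ppm_sd = cfg$ppm_sd),
                seed = cfg$seed)
  list(table = ft, truth = truth, db = db)
}

#' Simulate paired acid-hydrolysis experiments
#'
#' Emulates the hydrochloric-acid treatment that hydrolyses plasmenyl
#' (vinyl-ether, plasmalogen) but not plasmanyl (alkyl) sn-1 linkages: the
#' same extracts are rendered untreated and treated, with treated species
#' amounts scaled by `1 - efficiency` for plasmenyl species and unchanged for
#' all others (up to fresh measurement noise).
#'
#' @param config A [study_config()].
#' @param efficiency Hydrolysis efficiency in `[0, 1]` (default 1).
#' @return List with `untreated` and `treated` feature tables, plus `truth`
#'   and `db` as in [simulate_study()].
#' @export
simulate_hydrolysis_pairs <- function(config = study_config(),
                                      efficiency = 1) {
  if (efficiency < 0 || efficiency > 1)
    stop("hydrolysis efficiency must be in [0, 1]")
  cfg <- config
  db <- build_database(cfg$classes)
  truth_db <- db
  eth <- .is_ether_class(db$class)
  truth_db$sn1_linkage[eth] <- cfg$linkage[db$class[eth]]
  set.seed(cfg$seed)
  subjects <- c(paste0("C", seq_len(cfg$n_controls)),
                paste0("P", seq_len(cfg$n_patients)))
  groups <- c(rep("control", cfg$n_controls),
              paste0("patient_", seq_len(cfg$n_patients)))
  samples <- data.frame(
    sample_id = paste0(subjects, "_r1"), group = groups, replicate = 1L,
    protein_mg = stats::rlnorm(length(subjects), 0, cfg$protein_sdlog),
    treatment = "none", matrix = cfg$matrix, stringsAsFactors = FALSE)
  amounts <- .draw_amounts(db, samples, cfg)
  survival <- ifelse(truth_db$sn1_linkage == "alkenyl", 1 - efficiency, 1)
  survival[db$is_standard] <- 1
  treated_amounts <- amounts * survival *
    matrix(.lnorm_noise(length(amounts), cfg$noise_cv),
           nrow(amounts), ncol(amounts))
  samples_hcl <- samples
  samples_hcl$treatment <- "HCl"
  spec_u <- .species_intensities(db, amounts, samples, cfg)
  spec_t <- .species_intensities(db, treated_amounts, samples_hcl, cfg)
  list(untreated = .render_feature_table(db, spec_u, samples, cfg),
       treated = .render_feature_table(db, spec_t, samples_hcl, cfg),
       truth = list(amounts = amounts, treated_amounts = treated_amounts,
                    db = truth_db, efficiency = efficiency,
                    seed = cfg$seed),
       db = db)
}

#' Simulate a null abundance matrix
#'
#' Species-by-sample abundances under the null configuration (all class
#' multipliers 1): every species has the same expected abundance in both
#' groups, with the generator's multiplicative log-normal noise. Used for
#' statistical-calibration checks, where the lipid class structure is
#' irrelevant and only the noise model matters.
#'
#' @param n_species Number of simulated species.
#' @param n_control,n_patient Samples per group.
#' @param cv Log-normal noise CV.
#' @param baseline_meanlog,baseline_sdlog Baseline abundance distribution.
#' @param seed Integer seed.
#' @return List with `values` (species x samples) and `groups`.
#' @export
simulate_null_matrix <- function(n_species = 2000, n_control = 12,
                                 n_patient = 8, cv = 0.15,
                                 baseline_meanlog = log(0.5),
                                 baseline_sdlog = 0.7, seed = 1) {
  set.seed(seed)
  n <- n_control + n_patient
  baseline <- stats::rlnorm(n_species, baseline_meanlog, baseline_sdlog)
  values <- baseline * matrix(.lnorm_noise(n_species * n, cv), n_species, n)
  dimnames(values) <- list(paste0("S", seq_len(n_species)),
                           paste0("s", seq_len(n)))
  list(values = values,
       groups = rep(c("control", "patient"), c(n_control, n_patient)))
}

#' Simulate stable-isotope-dilution enzyme assays
#'
#' Emulates the CTP:phosphoethanolamine cytidylyltransferase (ET) activity
#' assay: product (CDP-ethanolamine) formed over the incubation is measured
#' against an 87 pmol isotope-labelled internal standard and an external
#' calibration curve generated under the same instrument response model.
#'
#' @param activities True specific activities (pmol/h/mg), one record each;
#'   zero gives a blank.
#' @param protein_mg Protein per assay (default 0.04 mg = 40 ug).
#' @param hours Incubation time (default 1 h).
#' @param is_pmol Internal-standard amount (default 87 pmol).
#' @param area_cv CV of the multiplicative noise on the measured peak areas
#'   (0 = noise-free).
#' @param response_product,response_is Instrument response factors (area per
#'   pmol).
#' @param calibration_amounts Standard-curve amounts in pmol.
#' @param seed Integer seed.
#' @return List with `records` (data frame: `activity_true`, `product_area`,
#'   `is_area`, `is_pmol`, `protein_mg`, `hours`) and `calibration`
#'   (data frame: `amount_pmol`, `area_ratio`).
#' @export
simulate_enzyme_assay <- function(activities, protein_mg = 0.04, hours = 1,
                                  is_pmol = 87, area_cv = 0,
                                  response_product = 120,
                                  response_is = 85,
                                  calibration_amounts = c(0, 25, 50, 100,
                                                          150, 200),
                                  seed = 1) {
  if (any(activities < 0)) stop("activities must be >= 0")
  set.seed(seed)
  n <- length(activities)
  product_pmol <- activities * protein_mg * hours
  records <- data.frame(
    activity_true = activities,
    product_area = product_pmol * response_product * .lnorm_noise(n, area_cv),
    is_area = is_pmol * response_is * .lnorm_noise(n, area_cv),
    is_pmol = is_pmol, protein_mg = protein_mg, hours = hours)
  calibration <- data.frame(
    amount_pmol = calibration_amounts,
    area_ratio = calibration_amounts * response_product /
      (is_pmol * response_is))
  list(records = records, calibration = calibration)
}
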