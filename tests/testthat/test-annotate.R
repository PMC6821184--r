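make_ft <- function(mz, ion_mode = "positive", n_samples = 2,
                    intensity = 1000) {
  n <- length(mz)
  feature_table(
    data.frame(feature_id = sprintf("F%03d", seq_len(n)), mz = mz,
               rt_min = 1, ion_mode = ion_mode, stringsAsFactors = FALSE),
    matrix(intensity, n, n_samples),
    data.frame(sample_id = paste0("s", seq_len(n_samples)),
               group = "control", replicate = seq_len(n_samples),
               protein_mg = 1, treatment = "none", matrix = "fibroblast",
               stringsAsFactors = FALSE))
}

test_that("ppm error arithmetic is exact", {
  expect_equal(ppm_error(678.5068, 678.5068), 0)
  expect_equal(ppm_error(678.5088, 678.5068), 2.9476, tolerance = 1e-4)
  # 3 ppm window width at m/z 678.5068
  expect_equal(3e-6 * 678.5068, 0.0020355, tolerance = 1e-4)
  expect_error(ppm_error(1, 0), "positive")
})

test_that("features in and out of the tolerance window behave as specified", {
  db <- build_database(data.frame(class = "PC", carbons_min = 32,
                                  carbons_max = 36, carbons_step = 2,
                                  db_min = 0, db_max = 2,
                                  adduct = "[M+H]+"),
                       include_standards = FALSE)
  target <- db$theoretical_mz[5]
  ft <- make_ft(c(target,                      # exact
                  target * (1 + 3.5e-6),       # 3.5 ppm off: rejected
                  target * (1 + 2.5e-6)))      # 2.5 ppm off: accepted
  ann <- match_features(ft, db, tolerance_ppm = 3)
  a1 <- ann[ann$feature_id == "F001" & ann$accepted, ]
  expect_equal(a1$ppm_error, 0, tolerance = 1e-9)
  expect_false("F002" %in% ann$feature_id)
  a3 <- ann[ann$feature_id == "F003" & ann$accepted, ]
  expect_equal(a3$ppm_error, 2.5, tolerance = 1e-3)
  expect_true(all(abs(ann$ppm_error) <= 3))
})

test_that("matching equals the all-pairs oracle and is monotone in tolerance", {
  db <- build_database(small_class_config())
  set.seed(31)
  # random features around database entries plus decoys
  base <- sample(db$theoretical_mz, 30)
  mz <- c(base * (1 + rnorm(30, 0, 2e-6)), runif(20, 400, 900))
  pol <- sample(c("positive", "negative"), 50, replace = TRUE)
  ft <- make_ft(mz)
  ft$features$ion_mode <- pol
  peaks <- lipidproc:::.theoretical_peaks(db, 3)
  peaks$polarity <- db$polarity[peaks$db_index]
  prev <- NULL
  for (tol in c(1, 2, 3, 5)) {
    ann <- match_features(ft, db, tolerance_ppm = tol)
    want <- oracle_match(ft$features$mz, ft$features$ion_mode,
                         peaks$mz, peaks$polarity, tol)
    got_keys <- sort(paste(ann$feature_id, ann$db_index,
                           ann$isotopologue_shift))
    want_keys <- sort(paste(ft$features$feature_id[want$feature],
                            peaks$db_index[want$peak],
                            peaks$shift[want$peak]))
    expect_equal(got_keys, want_keys, info = paste("tol", tol))
    if (!is.null(prev)) expect_true(all(prev %in% got_keys))
    prev <- got_keys
  }
})

test_that("annotation is invariant under database row order", {
  db <- build_database(small_class_config())
  ft <- make_ft(db$theoretical_mz[c(3, 10, 20)] * (1 + 1e-6))
  ann1 <- match_features(ft, db)
  set.seed(5)
  shuf <- db[sample(nrow(db)), ]
  ann2 <- match_features(ft, shuf)
  k1 <- sort(paste(ann1$feature_id, ann1$class, ann1$carbons,
                   ann1$double_bonds, ann1$isotopologue_shift,
                   ann1$accepted))
  k2 <- sort(paste(ann2$feature_id, ann2$class, ann2$carbons,
                   ann2$double_bonds, ann2$isotopologue_shift,
                   ann2$accepted))
  expect_equal(k1, k2)
})

test_that("overlap groups follow the resolution geometry", {
  # two TG species one double bond apart: the M+2 of the more unsaturated
  # sits ~9 mDa below the other's M0
  cfg <- data.frame(class = "TG", carbons_min = 52, carbons_max = 52,
                    carbons_step = 2, db_min = 1, db_max = 2,
                    adduct = "[M+NH4]+")
  db <- build_database(cfg, include_standards = FALSE)
  # db is mz-sorted: entry 1 = TG(52:2) (lighter), entry 2 = TG(52:1)
  sep <- abs((db$theoretical_mz[1] + 2.00671) - db$theoretical_mz[2])
  expect_lt(sep, 0.010)
  expect_gt(sep, 0.008)
  ft <- make_ft(db$theoretical_mz)
  ann <- match_features(ft, db)
  # generous 20 mDa merge threshold: one group holding both species
  g20 <- build_overlap_groups(ft, ann, db, merge_tol = 0.020)
  expect_equal(length(g20), 1)
  expect_setequal(g20[[1]]$species, c(1, 2))
  # resolved case: species 28 Da apart (two carbons) stay singleton groups
  cfg2 <- data.frame(class = "PC", carbons_min = 34, carbons_max = 36,
                     carbons_step = 2, db_min = 0, db_max = 0,
                     adduct = "[M+H]+")
  db2 <- build_database(cfg2, include_standards = FALSE)
  ft2 <- make_ft(db2$theoretical_mz)
  g2 <- build_overlap_groups(ft2, match_features(ft2, db2), db2,
                             merge_tol = 0.012)
  expect_equal(length(g2), 2)
  expect_true(all(lengths(lapply(g2, `[[`, "species")) == 1))
})

test_that("groups partition their features", {
  st <- simulate_study(study_config(classes = small_class_config(),
                                    seed = 3))
  ann <- match_features(st$table, st$db)
  groups <- build_overlap_groups(st$table, ann, st$db)
  feats <- unlist(lapply(groups, `[[`, "features"))
  expect_equal(anyDuplicated(feats), 0)
  # every member species' monoisotopic peak is mapped within its group
  for (g in groups) {
    m0 <- g$map[g$map$shift == 0, ]
    expect_setequal(m0$db_index, g$species)
  }
})
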