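test_that("the generator is deterministic under a fixed seed", {
  cfg <- study_config(classes = small_class_config(), seed = 9)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_study(study_config(classes = small_class_config(),
                                    seed = 10))
  expect_false(identical(s1$table$intensities, s3$table$intensities))
})

test_that("ground truth respects the configured study structure", {
  cfg <- study_config(seed = 4)
  st <- simulate_study(cfg, render = FALSE)
  tr <- st$truth
  expect_equal(ncol(tr$amounts), (cfg$n_controls + cfg$n_patients) *
                 cfg$n_replicates)
  # conservation: class sums of the truth equal summed species truths
  cls <- tr$db$class
  sums <- rowsum(tr$amounts, cls)
  one <- tapply(tr$amounts[, 1], cls, sum)
  expect_equal(sums[names(one), 1], as.numeric(one), tolerance = 1e-12,
               ignore_attr = TRUE)
  # plasmanyl-PS: zero in all control samples, positive in patients
  ctrl <- tr$samples$group == "control"
  pso <- cls == "PS[O]" & !tr$db$is_standard
  expect_true(all(tr$amounts[pso, ctrl] == 0))
  expect_true(all(tr$amounts[pso, !ctrl] > 0))
  # standards have identical nominal amounts in every sample
  std <- which(tr$db$is_standard)
  expect_true(all(tr$amounts[std, ] == tr$amounts[std, 1]))
})

test_that("class effect directions match the configured multipliers", {
  ok <- 0; tot <- 0
  for (s in 1:10) {
    st <- simulate_study(study_config(seed = s), render = FALSE)
    tr <- st$truth
    keep <- !tr$db$is_standard & tr$db$class != "PS[O]"
    sums <- rowsum(tr$amounts[keep, ], tr$db$class[keep])
    ctrl <- tr$samples$group == "control"
    fold <- rowMeans(sums[, !ctrl]) / rowMeans(sums[, ctrl])
    for (cl in names(tr$multipliers)) {
      tot <- tot + 1
      if (sign(log(fold[[cl]])) == sign(log(tr$multipliers[[cl]])))
        ok <- ok + 1
    }
  }
  expect_gte(ok / tot, 0.95)
})

test_that("null configurations are exchangeable between groups", {
  cfg0 <- small_class_config()
  pvals <- c()
  for (s in 1:100) {
    st <- simulate_study(study_config(classes = cfg0, multipliers = c(),
                                      seed = s), render = FALSE)
    tr <- st$truth
    keep <- !tr$db$is_standard
    sums <- rowsum(tr$amounts[keep, ], tr$db$class[keep])
    ctrl <- tr$samples$group == "control"
    pvals <- c(pvals, apply(sums, 1, function(v)
      stats::t.test(v[!ctrl], v[ctrl])$p.value))
  }
  expect_gte(mean(pvals > 0.05), 0.94)
})

test_that("hydrolysis pairs encode the linkage chemistry", {
  cfg <- study_config(classes = small_class_config(), noise_cv = 0,
                      ppm_sd = 0, seed = 12)
  # efficiency 0: treated equals untreated
  hp0 <- simulate_hydrolysis_pairs(cfg, efficiency = 0)
  expect_equal(hp0$truth$treated_amounts, hp0$truth$amounts)
  # efficiency 1: plasmenyl amounts vanish, plasmanyl survive
  hp1 <- simulate_hydrolysis_pairs(cfg, efficiency = 1)
  alkenyl <- hp1$truth$db$sn1_linkage == "alkenyl"
  expect_true(all(hp1$truth$treated_amounts[alkenyl, ] == 0))
  alkyl <- hp1$truth$db$sn1_linkage == "alkyl"
  expect_equal(hp1$truth$treated_amounts[alkyl, ],
               hp1$truth$amounts[alkyl, ])
  # efficiency 0.9 with noise: plasmanyl survival ~1, plasmenyl ~0.1
  cfgn <- study_config(classes = small_class_config(), noise_cv = 0.02,
                       ppm_sd = 0, seed = 13)
  hp9 <- simulate_hydrolysis_pairs(cfgn, efficiency = 0.9)
  surv <- hp9$truth$treated_amounts / hp9$truth$amounts
  expect_equal(mean(surv[alkyl & !hp9$truth$db$is_standard, ]), 1,
               tolerance = 0.05)
  expect_equal(mean(surv[alkenyl, ]), 0.1, tolerance = 0.05)
  expect_error(simulate_hydrolysis_pairs(cfg, efficiency = 1.2), "0, 1")
})

test_that("simulated feature tables are structurally valid", {
  st <- simulate_study(study_config(classes = small_class_config(),
                                    seed = 14))
  ft <- st$table
  expect_s3_class(ft, "feature_table")
  expect_equal(anyDuplicated(ft$features$feature_id), 0)
  expect_true(all(ft$intensities >= 0))
  expect_true(all(ft$features$mz > 0))
  m0 <- st$truth$m0_map
  expect_true(all(m0$feature_id %in% ft$features$feature_id))
  # most species have a detectable (apex) monoisotopic feature
  expect_gte(mean(m0$apex), 0.9)
})

test_that("enzyme assay records follow the response model", {
  sim <- simulate_enzyme_assay(c(0, 1000), area_cv = 0, seed = 2)
  expect_equal(sim$records$product_area[1], 0)  # blank
  expect_gt(sim$records$product_area[2], 0)
  sim2 <- simulate_enzyme_assay(c(0, 1000), area_cv = 0, seed = 2)
  expect_identical(sim, sim2)
  expect_error(simulate_enzyme_assay(-5), ">= 0")
})
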