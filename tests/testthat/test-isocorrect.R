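test_that("a singleton group is corrected by its pattern fractions", {
  # only the monoisotopic feature observed: total = observed / M0 fraction
  g <- make_group(list(c(`0` = 0.8)), list("F1"))
  sol <- deconvolute_group(g, c(F1 = 400))
  expect_equal(unname(sol$intensity), 500)
  # full pattern observed on separate features: exact recovery
  g2 <- make_group(list(c(`0` = 0.7, `1` = 0.2, `2` = 0.1)),
                   list(c("F1", "F2", "F3")))
  sol2 <- deconvolute_group(g2, c(F1 = 700, F2 = 200, F3 = 100))
  expect_equal(unname(sol2$intensity), 1000)
  expect_equal(sol2$residual, 0, tolerance = 1e-9)
})

test_that("the two-species triangular system solves by hand", {
  # species A: M0 on F1, M+2 fraction 0.06 relative landing on F2;
  # species B: M0 on F2. Observed F1 = 1000, F2 = 560 -> B = 500.
  g <- make_group(list(c(`0` = 1, `2` = 0.06), c(`0` = 1)),
                  list(c("F1", "F2"), "F2"))
  sol <- deconvolute_group(g, c(F1 = 1000, F2 = 560))
  expect_equal(unname(sol$intensity), c(1000, 500))
  # observed below predicted contamination: NNLS clamps B at zero
  sol2 <- deconvolute_group(g, c(F1 = 1000, F2 = 50))
  expect_equal(unname(sol2$intensity[2]), 0)
  expect_gt(sol2$residual, 0)
})

test_that("rank-deficient systems are flagged unresolved, not zeroed", {
  # two species mapped to the same single feature
  g <- make_group(list(c(`0` = 1), c(`0` = 1)), list("F1", "F1"))
  sol <- deconvolute_group(g, c(F1 = 100))
  expect_true(all(is.na(sol$intensity)))
  expect_false(any(sol$resolved))
})

test_that("triangular chains match sequential peel-off within 1e-9", {
  set.seed(41)
  for (k in 2:6) {
    g <- make_chain_group(k, f2 = 0.06)
    A <- lipidproc:::.group_design(g)
    truth <- runif(k, 100, 2000)
    y <- as.numeric(A %*% truth)
    names(y) <- rownames(A)
    sol <- deconvolute_group(g, y)
    peel <- oracle_peel_off(A, y)
    expect_equal(unname(sol$intensity), peel, tolerance = 1e-9)
    expect_equal(unname(sol$intensity), truth, tolerance = 1e-9)
  }
})

test_that("NNLS agrees with grid-refinement search on random systems", {
  set.seed(42)
  for (i in 1:20) {
    p <- sample(2:5, 1)
    n <- p + sample(0:2, 1)
    A <- matrix(runif(n * p, 0, 0.2), n, p)
    diag(A) <- runif(p, 0.6, 1)
    truth <- runif(p, 0, 1000) * rbinom(p, 1, 0.8)
    y <- as.numeric(A %*% truth) + rnorm(n, 0, 5)
    y <- pmax(y, 0)
    x_pkg <- pracma::lsqnonneg(A, y)$x
    g <- make_group(
      lapply(seq_len(p), function(j) {
        fr <- A[, j][A[, j] > 0]
        names(fr) <- seq_along(fr) - 1
        fr
      }),
      lapply(seq_len(p), function(j) paste0("F", which(A[, j] > 0))))
    names(y) <- paste0("F", seq_len(n))
    sol <- deconvolute_group(g, y)
    x_grid <- oracle_nnls_grid(A, y)
    scale <- max(abs(x_pkg), 1)
    expect_equal(unname(sol$intensity) / scale, x_grid / scale,
                 tolerance = 1e-3)
  }
})

test_that("zero-noise overlap-free studies are recovered exactly", {
  cfg <- study_config(classes = no_overlap_config(), noise_cv = 0,
                      ppm_sd = 0, protein_sdlog = 0, seed = 5)
  st <- simulate_study(cfg)
  corr <- run_correction(st$table, st$db)
  keys <- intersect(rownames(corr$values), rownames(st$truth$amounts))
  truth <- st$truth$amounts[keys, ]
  # corrected intensity = amount-in-extract x response (response 1, protein 1)
  endo <- !st$truth$db$is_standard[match(keys, species_key(st$truth$db))]
  rel <- abs(corr$values[keys, ][endo, ] / truth[endo, ] - 1)
  expect_lt(max(rel, na.rm = TRUE), 1e-6)
})

test_that("correction is per-sample and passes trivial columns through", {
  st <- simulate_study(study_config(classes = small_class_config(),
                                    seed = 6))
  ft <- st$table
  ann <- match_features(ft, st$db)
  groups <- build_overlap_groups(ft, ann, st$db)
  # an all-zero sample column stays all-zero
  ft0 <- ft
  ft0$intensities[, 3] <- 0
  c0 <- correct_feature_table(ft0, groups, st$db)
  expect_true(all(c0$values[, 3] == 0, na.rm = TRUE))
  # permuting samples permutes the output columns identically
  perm <- rev(seq_len(ncol(ft$intensities)))
  ftp <- feature_table(ft$features, ft$intensities[, perm],
                       ft$samples[perm, ])
  cp <- correct_feature_table(ftp, groups, st$db)
  cr <- correct_feature_table(ft, groups, st$db)
  expect_equal(cp$values, cr$values[, perm])
})

test_that("mass conservation holds per group and sample", {
  st <- simulate_study(study_config(classes = small_class_config(),
                                    seed = 7))
  ann <- match_features(st$table, st$db)
  groups <- build_overlap_groups(st$table, ann, st$db)
  for (g in groups[seq_len(min(10, length(groups)))]) {
    A <- lipidproc:::.group_design(g)
    y <- st$table$intensities[g$features, 1]
    sol <- deconvolute_group(g, y)
    if (!all(sol$resolved)) next
    expect_lte(sum(A %*% sol$intensity), sum(y) + 1e-6 * sum(y) + 1e-9)
  }
})
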