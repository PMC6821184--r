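test_that("t-test, ANOVA and Bonferroni columns behave as specified", {
  vals <- rbind(a = c(1, 2, 3, 4, 5, 6),
                b = c(5, 5, 5, 5, 5, 5),
                c = c(1, 1, 1, 2, 2, 2))
  groups <- rep(c("control", "patient_1"), each = 3)
  ds <- differential_stats(vals, groups, family = 30)
  # closed-form pooled t for [1,2,3] vs [4,5,6]: t = 3.674, df = 4
  expect_equal(ds$p_t[ds$key == "a"], 0.02131, tolerance = 1e-3)
  # identical groups: fold 1, degenerate p = 1
  expect_equal(ds$fold[ds$key == "b"], 1)
  expect_equal(ds$p_t[ds$key == "b"], 1)
  expect_true(ds$degenerate[ds$key == "b"])
  # zero variance, unequal means: p = 0 convention
  expect_equal(ds$p_t[ds$key == "c"], 0)
  # Bonferroni arithmetic with family 30
  expect_equal(ds$p_t_bonf[ds$key == "a"],
               min(ds$p_t[ds$key == "a"] * 30, 1))
  expect_true(all(ds$p_t_bonf >= ds$p_t, na.rm = TRUE))
  expect_true(all(ds$p_anova_bonf <= 1, na.rm = TRUE))
  # two-group ANOVA agrees with the pooled t-test
  expect_equal(ds$p_anova[ds$key == "a"], ds$p_t[ds$key == "a"],
               tolerance = 1e-9)
})

test_that("Dunnett reduces to the t-test with one comparison group", {
  set.seed(51)
  x <- rnorm(12)
  g <- rep(c("control", "patient_1"), each = 6)
  d <- dunnett_vs_control(x, g, n_mc = 1e5, seed = 5)
  p_t <- stats::t.test(x[g == "patient_1"], x[g == "control"],
                       var.equal = TRUE)$p.value
  expect_equal(d$p_adjusted, p_t, tolerance = 0.005)
  expect_gte(d$p_adjusted + 0.005, d$p_raw)
})

test_that("Dunnett matches multcomp and sits between raw and Bonferroni", {
  set.seed(52)
  y <- rnorm(18) + rep(c(0, 0.8, 0.3), each = 6)
  g <- rep(c("control", "patient_1", "patient_2"), each = 6)
  d <- dunnett_vs_control(y, g, n_mc = 2e5, seed = 6)
  fit <- stats::aov(y ~ factor(g))
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(
    `factor(g)` = "Dunnett")))
  expect_equal(d$p_adjusted, as.numeric(mc$test$pvalues), tolerance = 0.01)
  expect_true(all(d$p_adjusted >= d$p_raw - 0.005))
  expect_true(all(d$p_adjusted <= pmin(2 * d$p_raw, 1) + 0.005))
  expect_error(dunnett_vs_control(y, g, control = "none"), "absent")
})

test_that("PLS-DA finds the informative variable and is well-formed", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(20 * 50), 20, 50)
    X[11:20, 17] <- X[11:20, 17] + 3   # one group-shifted column
    colnames(X) <- paste0("V", 1:50)
    g <- rep(c("a", "b"), each = 10)
    m <- plsda_fit(X, g, n_components = 2)
    v <- vip_scores(m)
    if (which.max(abs(m$weights[, 1])) == 17 && which.max(v) == 17)
      hits <- hits + 1
    # algebraic identities on every fitted model
    expect_equal(sum(v^2), 50, tolerance = 1e-6)
    expect_equal(sum(colSums(m$weights^2)), 2, tolerance = 1e-8)
    expect_lt(abs(crossprod(m$scores[, 1], m$scores[, 2])), 1e-8)
  }
  expect_gte(hits, 9)
})

test_that("PLS-DA is invariant to sample duplication", {
  set.seed(53)
  X <- matrix(rnorm(12 * 8), 12, 8)
  g <- rep(c("a", "b"), each = 6)
  m1 <- plsda_fit(X, g, n_components = 2)
  m2 <- plsda_fit(rbind(X, X), c(g, g), n_components = 2)
  expect_equal(abs(m1$weights), abs(m2$weights), tolerance = 1e-8)
})

test_that("VIP agrees with the mixOmics reference implementation", {
  set.seed(54)
  X <- matrix(rnorm(16 * 30), 16, 30)
  X[9:16, 1:4] <- X[9:16, 1:4] + 1.5
  colnames(X) <- paste0("V", 1:30)
  g <- rep(c("a", "b"), each = 8)
  v <- vip_scores(plsda_fit(X, g, n_components = 2))
  mo <- mixOmics::plsda(X, factor(g), ncomp = 2, scale = TRUE)
  vm <- mixOmics::vip(mo)[, 2]
  expect_equal(unname(v), unname(vm), tolerance = 1e-6)
})

test_that("single-variable models are forced to VIP = 1", {
  set.seed(55)
  X <- matrix(rnorm(12) + rep(c(0, 2), each = 6), 12, 1,
              dimnames = list(NULL, "only"))
  m <- plsda_fit(X, rep(c("a", "b"), each = 6), n_components = 1)
  expect_equal(unname(vip_scores(m)), 1, tolerance = 1e-9)
})

test_that("heat-map matrices are row-centered and VIP-ordered", {
  set.seed(56)
  vals <- matrix(rlnorm(40 * 6), 40, 6,
                 dimnames = list(paste0("S", 1:40), paste0("s", 1:6)))
  vals[3, 2] <- 0  # zero handled by pseudo-count
  ranking <- stats::setNames(runif(40), rownames(vals))
  hm <- heatmap_matrix(vals, ranking, k = 30)
  expect_equal(dim(hm), c(30, 6))
  expect_lt(max(abs(rowMeans(hm))), 1e-12)
  full <- heatmap_matrix(vals, ranking, k = 40)
  expect_equal(rownames(full),
               names(sort(ranking, decreasing = TRUE)))
  expect_error(heatmap_matrix(vals, ranking, k = 0), "positive")
  expect_error(heatmap_matrix(vals, ranking, k = 41), "exceeds")
  expect_error(heatmap_matrix(vals, ranking[-1], k = 5), "cover")
})
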