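#' Differential statistics per species
#'
#' Two-sided two-sample t-test (pooled-variance Student's test by default,
#' Welch optional) of all non-control versus control samples, one-way ANOVA
#' F-test across all group levels, and Bonferroni adjustment with the family
#' size equal to the number of species tested (configurable). Species with
#' zero variance in both groups and equal means get p = 1 by convention and
#' are flagged.
#'
#' @param values Species-by-sample matrix.
#' @param groups Group label per column.
#' @param control Control group label.
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @param family Bonferroni family size; default `nrow(values)`.
#' @return Data frame: `key`, `control_mean`, `patient_mean`, `fold`,
#'   `status`, `p_t`, `p_t_bonf`, `p_anova`, `p_anova_bonf`, `degenerate`.
#' @export
differential_stats <- function(values, groups, control = "control",
                               var_equal = TRUE, family = nrow(values)) {
  ctrl <- groups == control
  if (sum(ctrl) < 2 || sum(!ctrl) < 2)
    stop("need >= 2 samples per group for variance estimates")
  fc <- fold_changes(values, groups, control)
  gf <- factor(groups)
  n_sp <- nrow(values)
  p_t <- p_a <- rep(NA_real_, n_sp)
  degen <- rep(FALSE, n_sp)
  for (i in seq_len(n_sp)) {
    x <- values[i, ctrl]; y <- values[i, !ctrl]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) next
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      degen[i] <- TRUE
      p_t[i] <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p_t[i] <- stats::t.test(y, x, var.equal = var_equal)$p.value
    }
    v <- values[i, ]
    wg_var <- tapply(v, gf, stats::var)
    if (all(wg_var == 0, na.rm = TRUE)) {
      # perfect within-group fit: p by the degenerate-means convention
      p_a[i] <- if (stats::var(tapply(v, gf, mean)) == 0) 1 else 0
    } else {
      p_a[i] <- stats::anova(stats::lm(v ~ gf))[["Pr(>F)"]][1]
    }
  }
  fc$p_t <- p_t
  fc$p_t_bonf <- pmin(p_t * family, 1)
  fc$p_anova <- p_a
  fc$p_anova_bonf <- pmin(p_a * family, 1)
  fc$degenerate <- degen
  fc
}

# Monte-Carlo sample of the null max-|t| statistic for Dunnett's test:
# group means ~ N(0, 1/n_g), pooled variance ~ chi-square(df)/df shared
# across comparisons, t_i = (mbar_i - mbar_0)/(s * sqrt(1/n_i + 1/n_0)).
.dunnett_null <- function(n_control, n_comp, df, n_mc) {
  k <- length(n_comp)
  z0 <- stats::rnorm(n_mc, 0, sqrt(1 / n_control))
  s <- sqrt(stats::rchisq(n_mc, df) / df)
  maxt <- rep(0, n_mc)
  for (i in seq_len(k)) {
    zi <- stats::rnorm(n_mc, 0, sqrt(1 / n_comp[i]))
    ti <- (zi - z0) / (s * sqrt(1 / n_comp[i] + 1 / n_control))
    maxt <- pmax(maxt, abs(ti))
  }
  maxt
}

#' Dunnett's multiple comparisons versus control
#'
#' Each non-control group is compared with the control group using the
#' pooled ANOVA error; the family-wise adjusted p-value is
#' `P(max_i |T_i| >= |t_obs|)` under the joint null, estimated by Monte
#' Carlo from the multivariate t distribution with the Dunnett correlation
#' structure (simulated via group means and a shared pooled variance).
#' With a single comparison group this reduces to the two-sided two-sample
#' t-test up to Monte-Carlo error.
#'
#' @param values Species-by-sample matrix (or a vector for one response).
#' @param groups Group label per column.
#' @param control Control group label.
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed Seed for the Monte-Carlo draws.
#' @return Data frame: `key`, `comparison`, `estimate` (mean difference),
#'   `t`, `p_adjusted`, and `p_raw` (unadjusted two-sided t from the pooled
#'   ANOVA error).
#' @export
dunnett_vs_control <- function(values, groups, control = "control",
                               n_mc = 1e5, seed = 1) {
  if (is.vector(values)) values <- matrix(values, 1,
                                          dimnames = list("response", NULL))
  if (!control %in% groups) stop("control group '", control, "' absent")
  gl <- unique(groups)
  comps <- setdiff(gl, control)
  n_g <- table(factor(groups, levels = c(control, comps)))
  df <- length(groups) - length(gl)
  if (df < 1) stop("no residual degrees of freedom")
  set.seed(seed)
  maxt <- .dunnett_null(n_g[[control]], as.numeric(n_g[comps]), df, n_mc)
  out <- list()
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    mse <- sum(tapply(v, groups, function(x) sum((x - mean(x))^2))) / df
    m <- tapply(v, groups, mean)
    for (cp in comps) {
      est <- m[[cp]] - m[[control]]
      se <- sqrt(mse * (1 / n_g[[cp]] + 1 / n_g[[control]]))
      t_obs <- est / se
      out[[length(out) + 1]] <- data.frame(
        key = rownames(values)[i], comparison = cp, estimate = est,
        t = t_obs,
        p_adjusted = mean(maxt >= abs(t_obs)),
        p_raw = 2 * stats::pt(-abs(t_obs), df),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fit a PLS-DA model
#'
#' Partial least squares regression discriminant analysis: sequential NIPALS
#' extraction against the one-hot class-indicator matrix, with deflation of
#' the predictor block after each component. Predictors are autoscaled
#' (centered, unit variance) by default. The fit is deterministic.
#'
#' @param X Samples-by-variables matrix.
#' @param groups Class label per sample (row).
#' @param n_components Number of latent components (default 2).
#' @param preprocessing `"autoscale"` (default), `"center"` or `"pareto"`.
#' @param tol,max_iter NIPALS convergence controls.
#' @return Object of class `plsda_model`: `weights` (variables x components,
#'   unit norm), `scores` (samples x components, mutually orthogonal),
#'   `x_loadings`, `y_loadings`, `ss_y` (explained response sum of squares
#'   per component), `groups`, `preprocessing`, `center`, `scale`.
#' @export
plsda_fit <- function(X, groups, n_components = 2,
                      preprocessing = c("autoscale", "center", "pareto"),
                      tol = 1e-10, max_iter = 500) {
  preprocessing <- match.arg(preprocessing)
  X <- as.matrix(X)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  Y <- stats::model.matrix(~ 0 + factor(groups))
  colnames(Y) <- levels(factor(groups))
  ctr <- colMeans(X)
  scl <- switch(preprocessing,
                autoscale = apply(X, 2, stats::sd),
                pareto = sqrt(apply(X, 2, stats::sd)),
                center = rep(1, ncol(X)))
  scl[scl == 0] <- 1 # constant columns carry no information
  Xc <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (n_components > qr(Xc)$rank)
    stop("n_components exceeds the rank of the predictor matrix")
  p <- ncol(Xc)
  W <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(Xc), n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(Y), n_components)
  ssy <- numeric(n_components)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q / sum(q^2)
      if (sum((w - w_old)^2) < tol^2) break
      w_old <- w
    }
    pp <- crossprod(Xd, tt) / sum(tt^2)
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pp; Q[, a] <- q
    ssy[a] <- sum((tt %*% t(q))^2)
    Xd <- Xd - tt %*% t(pp)
    Yd <- Yd - tt %*% t(q)
  }
  dimnames(W) <- list(colnames(X), paste0("comp", seq_len(n_components)))
  structure(list(weights = W, scores = Tm, x_loadings = P, y_loadings = Q,
                 ss_y = ssy, groups = groups, preprocessing = preprocessing,
                 center = ctr, scale = scl), class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("<plsda_model> ", ncol(x$weights), " components, ",
      nrow(x$weights), " variables, groups: ",
      paste(unique(x$groups), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a )` with unit-norm
#' component weights `w_a` and `SS_a` the explained response sum of squares
#' of component `a`. The squared VIPs sum to the number of variables, so the
#' mean squared VIP is 1 and `VIP = 1` is forced when there is a single
#' variable.
#'
#' @param model A `plsda_model`.
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model) {
  ssy <- model$ss_y
  if (sum(ssy) <= 0) stop("model explains no response variance")
  W2 <- model$weights^2 # columns already unit norm
  p <- nrow(W2)
  sqrt(p * as.numeric(W2 %*% ssy) / sum(ssy)) |>
    stats::setNames(rownames(model$weights))
}

#' Heat-map matrix of the top-k ranked species
#'
#' Selects the `k` species with the highest ranking score (VIP), takes the
#' logarithm of their abundances and centers each row on its mean, so color
#' reflects the log relative abundance versus the per-species mean. Zeros
#' are handled with a pseudo-count of half the smallest nonzero value of the
#' matrix.
#'
#' @param values Species-by-sample abundance matrix.
#' @param ranking Named score vector covering the rows of `values`.
#' @param k Number of rows to keep (default 30).
#' @param base Logarithm base (default 2).
#' @return The k-by-samples centered log matrix, rows in ranking order, with
#'   attribute `ranking` (the scores of the selected rows).
#' @export
heatmap_matrix <- function(values, ranking, k = 30, base = 2) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(values)) stop("k exceeds the number of species")
  if (!all(rownames(values) %in% names(ranking)))
    stop("ranking does not cover all species")
  sel <- names(sort(ranking[rownames(values)], decreasing = TRUE))[seq_len(k)]
  m <- values[sel, , drop = FALSE]
  pseudo <- min(m[m > 0], na.rm = TRUE) / 2
  lm_ <- log(m + pseudo, base = base)
  out <- lm_ - rowMeans(lm_, na.rm = TRUE)
  attr(out, "ranking") <- ranking[sel]
  out
}

#' Render a heat map of the top-ranked species
#'
#' Thin wrapper around [pheatmap::pheatmap()] for the matrix produced by
#' [heatmap_matrix()]; red above, blue below the per-species mean.
#'
#' @param hm Matrix from [heatmap_matrix()].
#' @param filename Optional output file passed to pheatmap.
#' @param ... Further pheatmap arguments.
#' @export
plot_heatmap <- function(hm, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_heatmap needs the pheatmap package")
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  pheatmap::pheatmap(hm, color = pal, cluster_rows = FALSE,
                     cluster_cols = FALSE, filename = filename, ...)
}
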