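# Independent oracles used to check the package's computations. These are
# deliberately implemented by different routes than the package code:
# enumeration instead of convolution, all-pairs scans instead of indexed
# lookup, grid search instead of active-set NNLS, forward substitution
# instead of least squares.

# Brute-force isotopologue distribution: enumerate every combination of
# heavy-isotope counts whose total nucleon shift fits max_shift, with
# multinomial probabilities per element.
oracle_isotope_dist <- function(formula, max_shift) {
  tab <- isotope_table()
  cnt <- unclass(formula)
  cnt <- cnt[cnt > 0]
  per_el <- lapply(names(cnt), function(el) {
    iso <- tab[tab$element == el, ]
    heavy <- iso[-1, , drop = FALSE]
    if (nrow(heavy) == 0)
      return(data.frame(shift = 0, mass = 0, prob = 1))
    sh <- heavy$nucleons - iso$nucleons[1]
    caps <- pmin(floor(max_shift / sh), cnt[[el]])
    grid <- as.matrix(expand.grid(lapply(caps, function(k) 0:k)))
    keep <- (grid %*% sh <= max_shift) & (rowSums(grid) <= cnt[[el]])
    grid <- grid[keep, , drop = FALSE]
    prob <- apply(grid, 1, function(ks)
      stats::dmultinom(c(cnt[[el]] - sum(ks), ks),
                       prob = iso$abundance / sum(iso$abundance)))
    data.frame(shift = as.vector(grid %*% sh),
               mass = as.vector(grid %*% (heavy$mass - iso$mass[1])),
               prob = prob)
  })
  comb <- Reduce(function(a, b) {
    out <- merge(a, b, by = NULL)
    out <- data.frame(shift = out$shift.x + out$shift.y,
                      mass = out$mass.x + out$mass.y,
                      prob = out$prob.x * out$prob.y)
    out[out$shift <= max_shift, ]
  }, per_el)
  ab <- tapply(comb$prob, comb$shift, sum)
  ms <- tapply(comb$prob * comb$mass, comb$shift, sum) / ab
  data.frame(shift = as.integer(names(ab)), mass_shift = as.numeric(ms),
             abundance = as.numeric(ab))
}

# Random lipid-scale formula (CHNOPS) for property tests.
random_formula <- function(max_c = 60) {
  el_formula(C = sample(1:max_c, 1), H = sample(0:(2 * max_c), 1),
             N = sample(0:3, 1), O = sample(0:15, 1),
             P = sample(0:2, 1), S = sample(0:2, 1))
}

# All-pairs exhaustive annotation scan.
oracle_match <- function(fmz, fpol, pmz, ppol, tol) {
  hits <- list()
  for (i in seq_along(fmz)) {
    for (j in seq_along(pmz)) {
      if (fpol[i] != ppol[j]) next
      ppm <- (fmz[i] - pmz[j]) / pmz[j] * 1e6
      if (abs(ppm) <= tol)
        hits[[length(hits) + 1]] <- data.frame(feature = i, peak = j,
                                               ppm = ppm)
    }
  }
  if (length(hits) == 0)
    return(data.frame(feature = integer(), peak = integer(),
                      ppm = numeric()))
  do.call(rbind, hits)
}

# Coordinate-wise grid-refinement minimizer of ||y - A x|| over x >= 0.
oracle_nnls_grid <- function(A, y, n_outer = 120, n_grid = 25) {
  p <- ncol(A)
  x <- rep(0, p)
  r <- rep(2 * max(y) / max(A), p)
  obj <- function(x) sum((y - A %*% x)^2)
  for (it in seq_len(n_outer)) {
    for (j in seq_len(p)) {
      grid <- seq(max(0, x[j] - r[j]), x[j] + r[j], length.out = n_grid)
      vals <- vapply(grid, function(g) {
        xt <- x; xt[j] <- g; obj(xt)
      }, numeric(1))
      x[j] <- grid[which.min(vals)]
    }
    r <- r * 0.75
  }
  x
}

# Classic sequential peel-off subtraction for a strictly triangular
# double-bond chain (most-unsaturated species first).
oracle_peel_off <- function(A, y) {
  p <- ncol(A)
  x <- numeric(p)
  yy <- y
  for (s in seq_len(p)) {
    x[s] <- yy[s] / A[s, s]
    yy <- yy - x[s] * A[, s]
  }
  x
}
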