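# Order in which elements are stored and printed (Hill-ish, fixed).
.ELEMENTS <- c("C", "H", "N", "O", "P", "S", "Na", "K")

# Package-level cache for bundled constants tables.
.lp_cache <- new.env(parent = emptyenv())

.read_constants <- function(file) {
  path <- system.file("extdata", file, package = "lipidproc")
  if (!nzchar(path)) {
    # during development (load_all) inst/ may still be on the source path
    path <- file.path("inst", "extdata", file)
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Bundled element isotope table
#'
#' Monoisotopic masses and natural isotopic abundances of the elements that
#' occur in the supported lipid classes and adducts (C, H, N, O, P, S, Na, K),
#' read from a versioned table shipped with the package.
#'
#' @return A data frame with columns `element`, `nucleons`, `mass` (Da) and
#'   `abundance` (fraction). Abundances sum to 1 within each element.
#' @export
isotope_table <- function() {
  if (is.null(.lp_cache$isotopes)) {
    tab <- .read_constants("isotopes.tsv")
    tab <- tab[order(match(tab$element, .ELEMENTS), tab$nucleons), ]
    .lp_cache$isotopes <- tab
  }
  .lp_cache$isotopes
}

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of atom counts over the
#' supported elements. Counts must be non-negative.
#'
#' @param ... Named atom counts, e.g. `el_formula(C = 36, H = 72, N = 1, O = 8,
#'   P = 1)`.
#' @return An object of class `el_formula`.
#' @examples
#' el_formula(C = 36, H = 72, N = 1, O = 8, P = 1)
#' @export
el_formula <- function(...) {
  counts <- c(...)
  if (is.null(counts)) counts <- integer(0)
  if (is.null(names(counts)) && length(counts) > 0)
    stop("atom counts must be named by element")
  bad <- setdiff(names(counts), .ELEMENTS)
  if (length(bad) > 0)
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("atom counts must be non-negative")
  if (any(counts != round(counts))) stop("atom counts must be integers")
  full <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  full[names(counts)] <- as.integer(counts)
  structure(full, class = "el_formula")
}

#' Parse a molecular formula string
#'
#' @param x Formula string such as `"C36H72NO8P"`. An element symbol without a
#'   following number counts as one atom.
#' @return An `el_formula`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  parts <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  parts <- parts[nzchar(parts)]
  if (paste(parts, collapse = "") != x)
    stop("cannot parse formula string: ", x)
  els <- sub("[0-9]*$", "", parts)
  ns <- sub("^[A-Z][a-z]?", "", parts)
  ns <- ifelse(nzchar(ns), as.integer(ns), 1L)
  counts <- tapply(ns, els, sum)
  do.call(el_formula, as.list(counts))
}

#' @export
format.el_formula <- function(x, ...) {
  nz <- x[x > 0]
  if (length(nz) == 0) return("")
  paste0(names(nz), ifelse(nz == 1, "", nz), collapse = "")
}

#' @export
print.el_formula <- function(x, ...) {
  cat("<el_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Add or subtract elemental formulas
#'
#' Element-wise arithmetic on atom counts. Subtraction that would produce a
#' negative count is an error.
#'
#' @param f1,f2 `el_formula` objects.
#' @return An `el_formula`.
#' @export
formula_add <- function(f1, f2) {
  structure(unclass(f1) + unclass(f2), class = "el_formula")
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f1, f2) {
  out <- unclass(f1) - unclass(f2)
  if (any(out < 0))
    stop("formula subtraction would give negative atom count for: ",
         paste(names(out)[out < 0], collapse = ", "))
  structure(out, class = "el_formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum of atom counts times the lightest-isotope masses from
#' [isotope_table()].
#'
#' @param formula An `el_formula` (or formula string).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  tab <- isotope_table()
  mono <- tab[!duplicated(tab$element), ] # lightest first per element
  m <- stats::setNames(mono$mass, mono$element)
  sum(unclass(formula) * m[names(formula)])
}

# Per-element isotope pattern as a "shift distribution": list(ab, mass) where
# ab[k+1] is the abundance at nominal shift k and mass[k+1] the exact mass
# shift (Da) relative to the lightest isotope.
.element_pattern <- function(element) {
  tab <- isotope_table()
  rows <- tab[tab$element == element, ]
  shifts <- rows$nucleons - rows$nucleons[1]
  ab <- numeric(max(shifts) + 1)
  ms <- numeric(max(shifts) + 1)
  ab[shifts + 1] <- rows$abundance
  ms[shifts + 1] <- rows$mass - rows$mass[1]
  list(ab = ab, mass = ms)
}

# Convolve two shift distributions; exact mass shift per nominal bin is the
# abundance-weighted mean over the contributing combinations.
.conv_dist <- function(a, b) {
  la <- length(a$ab); lb <- length(b$ab)
  n <- la + lb - 1
  ab <- numeric(n); macc <- numeric(n)
  for (i in seq_len(la)) {
    if (a$ab[i] == 0) next
    j <- seq_len(lb)
    k <- i + j - 1
    w <- a$ab[i] * b$ab
    ab[k] <- ab[k] + w
    macc[k] <- macc[k] + w * (a$mass[i] + b$mass)
  }
  mass <- ifelse(ab > 0, macc / ab, 0)
  list(ab = ab, mass = mass)
}

# n-fold self-convolution by binary exponentiation.
.pow_dist <- function(d, n) {
  out <- list(ab = 1, mass = 0)
  while (n > 0) {
    if (n %% 2 == 1) out <- .conv_dist(out, d)
    n <- n %/% 2
    if (n > 0) d <- .conv_dist(d, d)
  }
  out
}

#' Theoretical isotopologue distribution of a formula
#'
#' Computes the natural-abundance isotopologue pattern of a molecule by
#' element-wise convolution of the per-element isotope patterns. Entry 0 is
#' the monoisotopic peak; nominal shifts count additional nucleons (so 18-O
#' contributes at shift 2). The exact mass shift reported for each nominal
#' shift is the abundance-weighted mean over the isotopic combinations that
#' fall in that bin (e.g. 2x 13-C vs 1x 18-O at shift 2).
#'
#' @param formula An `el_formula` or formula string.
#' @param max_shift Largest nominal shift retained (default 3; the M+3
#'   abundance is below 1 percent of the pattern for all supported lipid
#'   species).
#' @return A data frame with columns `shift`, `mass_shift` (Da) and
#'   `abundance` (fraction of the full pattern), with attribute
#'   `retained_fraction` = sum of the retained abundances.
#' @examples
#' isotope_distribution(el_formula(C = 1))
#' @export
isotope_distribution <- function(formula, max_shift = 3) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(max_shift >= 0)
  full <- list(ab = 1, mass = 0)
  cnt <- unclass(formula)
  for (el in names(cnt)) {
    if (cnt[[el]] == 0) next
    full <- .conv_dist(full, .pow_dist(.element_pattern(el), cnt[[el]]))
  }
  k <- min(max_shift + 1, length(full$ab))
  out <- data.frame(
    shift = 0:(k - 1),
    mass_shift = full$mass[seq_len(k)],
    abundance = full$ab[seq_len(k)]
  )
  attr(out, "retained_fraction") <- sum(out$abundance)
  attr(out, "total_abundance") <- sum(full$ab)
  out
}
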