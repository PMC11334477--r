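# Natural-abundance correction of carbon-isotopologue distributions (CIDs)
# measured on amino-acid fragments by full-scan Orbitrap MS. Low-resolution
# mode: isotopes are collapsed onto nominal mass shifts and the measured
# spectrum is the convolution of the true CID with the natural-abundance
# mass-shift distributions of all atoms; the correction solves the resulting
# linear system by non-negative least squares.

#' Parse an elemental formula
#'
#' @param formula string like `"C3H7NO2"` (element symbols followed by
#'   optional counts).
#' @return named integer vector of atom counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) return(formula)
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts) || paste(parts, collapse = "") != formula)
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Z][a-z]?", "", parts)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  out <- tapply(n, el, sum)
  counts <- as.integer(out); names(counts) <- names(out)
  if (any(counts < 0)) stop("negative atom count")
  counts
}

#' Natural isotope abundance table
#'
#' Mass-shift probabilities per atom: for each element, the probability of a
#' +1, +2, ... nominal mass shift relative to the lightest isotope. Defaults
#' are the standard terrestrial abundances (13C 0.0107; 2H 0.000115;
#' 15N 0.00364; 17O 0.00038, 18O 0.00205; 33S 0.0075, 34S 0.0425).
#'
#' @param overrides named list of numeric vectors replacing the default
#'   mass-shift probabilities of individual elements, e.g.
#'   `list(C = c(`1` = 0))` for a 13C-free world.
#' @return named list: element -> numeric vector of P(shift = k), k >= 1.
#' @export
natural_abundances <- function(overrides = list()) {
  tab <- list(
    C = c(0.0107),
    H = c(0.000115),
    N = c(0.00364),
    O = c(0.00038, 0.00205),
    S = c(0.0075, 0.0425))
  for (nm in names(overrides)) tab[[nm]] <- as.numeric(overrides[[nm]])
  tab
}

# Mass-shift distribution of one atom: P(0) = 1 - sum(shifts), P(k) = shifts.
atom_shift_dist <- function(shifts) {
  p0 <- 1 - sum(shifts)
  if (p0 < 0) stop("isotope abundances exceed 1")
  c(p0, shifts)
}

# Discrete convolution of two mass-shift distributions.
conv <- function(a, b) {
  if (is.null(a)) return(b)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  out
}

# n-fold self-convolution (atoms of one element).
conv_pow <- function(dist, n) {
  out <- NULL
  for (i in seq_len(n)) out <- conv(out, dist)
  out %||% 1
}

#' Build a natural-abundance correction matrix
#'
#' Column `j` (0-based) is the mass-shift distribution expected from a
#' molecule whose true state is Mj: the convolution of (a) the
#' natural-abundance shift distribution of all non-tracer atoms, (b) natural
#' 13C on the `n - j` unlabeled carbons, and (c) the tracer-purity binomial
#' over the `j` labeled carbons. The matrix is truncated at Mn; columns are
#' column-stochastic up to that truncation.
#'
#' @param formula elemental formula (string or named counts vector).
#' @param tracer list with `element` (must be `"C"`) and `purity` in (0, 1].
#' @param abundances see [natural_abundances()].
#' @return (n+1) x (n+1) matrix, n = carbon count.
#' @export
build_correction_matrix <- function(formula,
                                    tracer = list(element = "C", purity = 1),
                                    abundances = natural_abundances()) {
  counts <- parse_formula(formula)
  if (!"C" %in% names(counts) || counts[["C"]] < 1)
    stop("CID correction requires at least one carbon")
  if (!identical(tracer$element, "C")) stop("only a carbon tracer is supported")
  purity <- tracer$purity
  if (purity <= 0 || purity > 1) stop("tracer purity must be in (0, 1]")
  n <- counts[["C"]]
  miss <- setdiff(names(counts), names(abundances))
  if (length(miss)) stop("no abundance data for element(s): ",
                         paste(miss, collapse = ", "))
  # non-tracer elements
  other <- NULL
  for (el in setdiff(names(counts), "C"))
    if (counts[[el]] > 0)
      other <- conv(other, conv_pow(atom_shift_dist(abundances[[el]]), counts[[el]]))
  c_nat <- atom_shift_dist(abundances[["C"]])
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    col <- other %||% 1
    col <- conv(col, conv_pow(c_nat, n - j))          # unlabeled carbons
    if (j > 0) {                                      # tracer purity binomial
      pur <- stats::dbinom(0:j, j, purity)            # k of j actually 13C
      col <- conv(col, pur)                           # shift = k
    }
    M[, j + 1L] <- col[seq_len(n + 1L)]               # truncate at Mn
  }
  M
}

#' Correct a measured CID for natural isotope abundance
#'
#' Solves `measured = matrix %*% corrected` by non-negative least squares,
#' renormalizes the corrected vector to sum one, and reports the mean 13C
#' enrichment `sum(j * Mj) / n`.
#'
#' @param measured numeric vector M0..Mn of measured fractions.
#' @param matrix a [build_correction_matrix()] of matching dimension.
#' @return list with `corrected` (numeric, sums to 1, non-negative),
#'   `enrichment` (mean fractional 13C labeling), and `residual` (norm of the
#'   NNLS residual).
#' @export
correct_cid <- function(measured, matrix) {
  if (all(measured == 0)) stop("all-zero measured CID")
  if (length(measured) != ncol(matrix)) stop("dimension mismatch")
  fit <- pracma::lsqnonneg(matrix, as.numeric(measured))
  x <- fit$x
  if (sum(x) <= 0) stop("correction produced an empty distribution")
  corrected <- x / sum(x)
  n <- length(measured) - 1L
  list(corrected = corrected,
       enrichment = sum(seq(0, n) * corrected) / n,
       residual = sqrt(fit$resid.norm %||% sum((matrix %*% x - measured)^2)))
}

#' Labeled fraction of a split metabolite pool
#'
#' Bookkeeping helper: percentage of a pool carrying the tracer label, from
#' the concentrations of its labeled and unlabeled forms.
#'
#' @param labeled,unlabeled concentrations (same units).
#' @return percentage in \[0, 100\].
#' @export
labeled_fraction <- function(labeled, unlabeled) {
  if (labeled < 0 || unlabeled < 0) stop("concentrations must be >= 0")
  tot <- labeled + unlabeled
  if (tot == 0) stop("empty pool has no labeled fraction")
  100 * labeled / tot
}
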