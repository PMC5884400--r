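# Effect-coded age-period-cohort design matrix and its null space.
#
# The exact dependency cohort = period - age makes the APC design matrix
# rank-deficient by exactly one: its kernel is spanned by a single vector B0
# whose entries, within each effect block, are linear in category index. All
# identification strategies differ only in how they resolve this one free
# direction.

effect_code_row <- function(idx, L) {
  # sum-to-zero coding, last category omitted: category L maps to -1 on all
  # L-1 columns, category i < L to the i-th unit vector
  v <- numeric(L - 1L)
  if (idx < L) v[idx] <- 1 else v[] <- -1
  v
}

#' Build the effect-coded APC design matrix
#'
#' One row per cell of the A x P Lexis grid in age-major order (age 1,
#' periods 1..P; then age 2, ...). Columns: intercept, then A-1 age, P-1
#' period and C-1 cohort effect-coded contrasts (C = A + P - 1), each block
#' omitting its last category. The cohort of row (i, j) is
#' `cohort_index(i, j, A)`. The matrix has rank m - 1: its kernel is the
#' one-dimensional span of the returned unit null vector.
#'
#' @param A number of age groups (>= 2).
#' @param P number of periods (>= 2).
#' @return object of class `apc_design`: list with `matrix` (n x m),
#'   `blocks` (named list of column index ranges), `null_vector` (unit
#'   length-m kernel basis), `A`, `P`, `C`, and per-row `age`, `period`,
#'   `cohort` indices.
#' @export
apc_design <- function(A, P) {
  stopifnot(A >= 2, P >= 2)
  A <- as.integer(A); P <- as.integer(P)
  C <- A + P - 1L
  m <- 1L + (A - 1L) + (P - 1L) + (C - 1L)
  n <- A * P

  age_i <- rep(seq_len(A), each = P)
  per_j <- rep(seq_len(P), times = A)
  coh_k <- cohort_index(age_i, per_j, A)

  X <- matrix(0, nrow = n, ncol = m)
  X[, 1] <- 1
  blocks <- list(intercept = 1L,
                 age = 1L + seq_len(A - 1L),
                 period = 1L + (A - 1L) + seq_len(P - 1L),
                 cohort = 1L + (A - 1L) + (P - 1L) + seq_len(C - 1L))
  for (r in seq_len(n)) {
    X[r, blocks$age] <- effect_code_row(age_i[r], A)
    X[r, blocks$period] <- effect_code_row(per_j[r], P)
    X[r, blocks$cohort] <- effect_code_row(coh_k[r], C)
  }

  # spectral decomposition of X'X: eigenvalues are squared singular values
  # and the full set of m right singular vectors is available even when the
  # grid has fewer cells than columns
  ev <- eigen(crossprod(X), symmetric = TRUE)
  d <- sqrt(pmax(ev$values, 0))
  # kernel detection on the eigenvalue scale (numerical noise of a zero
  # eigenvalue is relative to the largest eigenvalue, not its square root)
  tol <- max(dim(X)) * max(ev$values) * .Machine$double.eps * 100
  kern_dim <- sum(ev$values < tol)
  if (kern_dim != 1L) {
    stop("APC design kernel dimension is ", kern_dim,
         " (expected exactly 1); the design is malformed")
  }
  b0 <- ev$vectors[, m]
  # sign convention: first age-block entry positive
  if (b0[blocks$age[1]] < 0) b0 <- -b0

  structure(
    list(matrix = X, blocks = blocks, null_vector = b0,
         A = A, P = P, C = C,
         age = age_i, period = per_j, cohort = coh_k,
         right_vectors = ev$vectors, singular_values = d),
    class = "apc_design")
}

#' @export
print.apc_design <- function(x, ...) {
  cat(sprintf("apc_design: A=%d P=%d C=%d; %d x %d, rank %d (kernel dim 1)\n",
              x$A, x$P, x$C, nrow(x$matrix), ncol(x$matrix), ncol(x$matrix) - 1L))
  invisible(x)
}

#' Null vector of an APC design
#'
#' Unit-norm basis of the kernel, computed from the design's singular value
#' decomposition (the right singular vector of the smallest singular value),
#' with sign fixed so the first age-block entry is positive. Within each
#' effect block its entries are linear in category index — the signature of
#' the age/period/cohort linear dependency.
#'
#' @param design an [apc_design()].
#' @return numeric vector of length `ncol(design$matrix)`.
#' @export
apc_null_vector <- function(design) {
  stopifnot(inherits(design, "apc_design"))
  design$null_vector
}

# orthonormal basis of the complement of the null vector: the m-1 right
# singular vectors with nonzero singular value
nonnull_basis <- function(design) {
  m <- ncol(design$matrix)
  design$right_vectors[, seq_len(m - 1L), drop = FALSE]
}
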