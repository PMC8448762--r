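# Arithmetic for atomic displacement parameters (ADPs).
#
# An anisotropic ADP (a-ADP) is a symmetric 3x3 tensor U in A^2; throughout
# the package it is stored as a length-6 numeric vector in the order
# (u11, u22, u33, u12, u13, u23), or as an n x 6 matrix for a set of atoms.
# Isotropic B-factors are derived views: B = 8 * pi^2 * Tr(U) / 3.

#' Conversion constant between U (A^2) and B-factors (A^2)
#'
#' \code{B = 8 * pi^2 * u_iso} where \code{u_iso} is the mean-square
#' displacement. The exact value \code{8 * pi^2 = 78.9568...} is used
#' everywhere; it is never rounded.
#' @export
B_FROM_U <- 8 * pi^2

#' Construct an anisotropic displacement tensor
#'
#' @param u11,u22,u33 diagonal elements (A^2)
#' @param u12,u13,u23 off-diagonal elements (A^2)
#' @return length-6 numeric vector (class-free; the 6-vector convention is
#'   used package-wide)
#' @export
anisou <- function(u11 = 0, u22 = 0, u33 = 0, u12 = 0, u13 = 0, u23 = 0) {
  as.numeric(c(u11, u22, u33, u12, u13, u23))
}

#' Convert a 6-vector U to a symmetric 3x3 matrix
#' @param u length-6 vector (u11, u22, u33, u12, u13, u23)
#' @export
u_as_mat <- function(u) {
  matrix(c(u[1], u[4], u[5],
           u[4], u[2], u[6],
           u[5], u[6], u[3]), 3, 3)
}

#' Convert a symmetric 3x3 matrix to the 6-vector convention
#' @param m symmetric 3x3 matrix
#' @export
u_from_mat <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# Coerce scalar-or-matrix U input to an n x 6 matrix.
u_as_rows <- function(u) {
  if (is.matrix(u)) u else matrix(u, nrow = 1)
}

#' Trace of U tensor(s)
#' @param u length-6 vector or n x 6 matrix
#' @return numeric vector of traces (A^2)
#' @export
u_trace <- function(u) {
  u <- u_as_rows(u)
  u[, 1] + u[, 2] + u[, 3]
}

#' Squared Frobenius norm of U tensor(s)
#'
#' Off-diagonal elements are counted twice, i.e. this is the norm of the full
#' symmetric 3x3 matrix. This is the contraction used in the least-squares
#' target of the fit.
#' @param u length-6 vector or n x 6 matrix
#' @export
u_norm2 <- function(u) {
  u <- u_as_rows(u)
  rowSums(u[, 1:3, drop = FALSE]^2) + 2 * rowSums(u[, 4:6, drop = FALSE]^2)
}

#' Frobenius inner product of U tensors (off-diagonals double-counted)
#' @param x,y length-6 vectors or n x 6 matrices (recycled row-wise)
#' @export
u_dot <- function(x, y) {
  x <- u_as_rows(x); y <- u_as_rows(y)
  rowSums(x[, 1:3, drop = FALSE] * y[, 1:3, drop = FALSE]) +
    2 * rowSums(x[, 4:6, drop = FALSE] * y[, 4:6, drop = FALSE])
}

#' Equivalent isotropic B-factor of anisotropic tensor(s)
#'
#' \code{B_eq = 8 * pi^2 * Tr(U) / 3}.
#' @param u length-6 vector or n x 6 matrix
#' @return numeric vector of B-factors (A^2)
#' @export
u_to_b <- function(u) {
  B_FROM_U * u_trace(u) / 3
}

#' Isotropic embedding of B-factor(s)
#'
#' Returns the isotropic tensor \code{diag(b / 8pi^2)} such that
#' \code{u_to_b(b_to_u(b)) == b}.
#' @param b numeric vector of B-factors (A^2); must be non-negative
#' @return n x 6 matrix (or 6-vector for scalar input)
#' @export
b_to_u <- function(b) {
  if (any(b < 0)) {
    stop("unphysical input: negative B-factor(s) cannot be embedded as ",
         "displacement tensors", call. = FALSE)
  }
  uiso <- b / B_FROM_U
  out <- cbind(uiso, uiso, uiso, 0, 0, 0)
  dimnames(out) <- NULL
  if (length(b) == 1L) out[1, ] else out
}

#' Eigenvalues of U tensor(s)
#' @param u length-6 vector or n x 6 matrix
#' @return n x 3 matrix of eigenvalues, decreasing
#' @export
u_eigenvalues <- function(u) {
  u <- u_as_rows(u)
  t(apply(u, 1, function(row) eigen(u_as_mat(row), symmetric = TRUE,
                                    only.values = TRUE)$values))
}

#' Test positive semi-definiteness of U tensor(s)
#'
#' A displacement tensor is physical when it is positive semi-definite. The
#' test applies a tolerance directly to the smallest eigenvalue of the
#' symmetric eigendecomposition: PSD iff \code{min(eigenvalues) >= -eps}.
#' @param u length-6 vector or n x 6 matrix
#' @param eps non-negative tolerance (A^2)
#' @return logical vector
#' @export
is_psd_u <- function(u, eps = 1e-6) {
  stopifnot(eps >= 0)
  ev <- u_eigenvalues(u)
  ev[, 3] >= -eps
}

#' Project U tensor(s) onto the positive semi-definite cone
#'
#' Eigenvalue clipping, which is the minimizer of the (double-counted
#' off-diagonal) squared Frobenius distance over PSD tensors.
#' @param u length-6 vector or n x 6 matrix
#' @return projected tensors, same shape convention as input
#' @export
psd_project_u <- function(u) {
  um <- u_as_rows(u)
  out <- t(apply(um, 1, function(row) {
    e <- eigen(u_as_mat(row), symmetric = TRUE)
    if (e$values[3] >= 0) return(row)
    lam <- pmax(e$values, 0)
    u_from_mat(e$vectors %*% diag(lam) %*% t(e$vectors))
  }))
  if (!is.matrix(u)) out[1, ] else out
}
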