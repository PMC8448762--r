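# Translation-Libration-Screw (TLS) model: matrix container, the closed-form
# per-atom ADP contribution, a physical-validity screen, and the amplitude
# normalization used by the hierarchical fit.

#' Construct a TLS matrix set
#'
#' T and L are symmetric and stored as 6-vectors ((11,22,33,12,13,23)); S is
#' stored as 8 free elements (s11, s12, s13, s21, s22, s23, s31, s32) with the
#' trace constraint s33 = -(s11 + s22), since the S trace is not determined by
#' the ADPs. L is radian-native (rad^2); S is in A*rad; T in A^2.
#'
#' @param T length-6 vector, A^2
#' @param L length-6 vector, rad^2
#' @param S length-8 vector, A*rad
#' @param origin length-3 vector, A
#' @return object of class \code{tls_matrices}
#' @export
tls_matrices <- function(T = c(0, 0, 0, 0, 0, 0),
                         L = c(0, 0, 0, 0, 0, 0),
                         S = rep(0, 8),
                         origin = c(0, 0, 0)) {
  stopifnot(length(T) == 6, length(L) == 6, length(S) == 8, length(origin) == 3)
  structure(list(T = as.numeric(T), L = as.numeric(L), S = as.numeric(S),
                 origin = as.numeric(origin)),
            class = "tls_matrices")
}

# Full 3x3 S matrix with the zero-trace convention; S[k, j] = <theta_k t_j>.
s_as_mat <- function(S) {
  matrix(c(S[1], S[2], S[3],
           S[4], S[5], S[6],
           S[7], S[8], -(S[1] + S[5])), 3, 3, byrow = TRUE)
}

s_from_mat <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 1], m[2, 2], m[2, 3], m[3, 1], m[3, 2])
}

#' @export
print.tls_matrices <- function(x, ...) {
  cat("TLS matrices (origin:", paste(sprintf("%.3f", x$origin), collapse = " "),
      "A)\n")
  cat("  T (A^2):   ", paste(sprintf("% .5f", x$T), collapse = " "), "\n")
  cat("  L (rad^2): ", paste(sprintf("% .5f", x$L), collapse = " "), "\n")
  cat("  S (A rad): ", paste(sprintf("% .5f", x$S), collapse = " "), "\n")
  invisible(x)
}

#' Per-atom anisotropic ADP contributions of a TLS model
#'
#' The rigid-body displacement of an atom at position r is
#' \code{u = t + theta x (r - origin)} in the small-angle regime, with
#' \code{t ~ N(0, T)}, \code{theta ~ N(0, L)} and cross-covariance
#' \code{S = Cov(theta, t)}. The resulting positional covariance is the
#' standard closed form \code{U = T + A L A' + A S + S' A'}, where A is the
#' antisymmetric matrix of (r - origin). At the origin the lever arm is zero
#' and U = T exactly.
#'
#' @param m \code{tls_matrices}
#' @param positions n x 3 matrix (or length-3 vector) of positions, A
#' @return n x 6 matrix of U tensors (6-vector for a single position)
#' @export
tls_uij <- function(m, positions) {
  single <- !is.matrix(positions)
  pos <- if (single) matrix(positions, nrow = 1) else positions
  d <- sweep(pos, 2, m$origin)
  d1 <- d[, 1]; d2 <- d[, 2]; d3 <- d[, 3]
  Tm <- u_as_mat(m$T); Lm <- u_as_mat(m$L); Sm <- s_as_mat(m$S)

  # Rows of the antisymmetric lever-arm matrix A (so that A %*% theta =
  # theta x d): A1 = (0, d3, -d2); A2 = (-d3, 0, d1); A3 = (d2, -d1, 0).
  AL1 <- outer(d3, Lm[2, ]) - outer(d2, Lm[3, ])
  AL2 <- outer(d1, Lm[3, ]) - outer(d3, Lm[1, ])
  AL3 <- outer(d2, Lm[1, ]) - outer(d1, Lm[2, ])

  alat11 <- AL1[, 2] * d3 - AL1[, 3] * d2
  alat12 <- AL1[, 3] * d1 - AL1[, 1] * d3
  alat13 <- AL1[, 1] * d2 - AL1[, 2] * d1
  alat22 <- AL2[, 3] * d1 - AL2[, 1] * d3
  alat23 <- AL2[, 1] * d2 - AL2[, 2] * d1
  alat33 <- AL3[, 1] * d2 - AL3[, 2] * d1

  AS11 <- d3 * Sm[2, 1] - d2 * Sm[3, 1]
  AS12 <- d3 * Sm[2, 2] - d2 * Sm[3, 2]
  AS13 <- d3 * Sm[2, 3] - d2 * Sm[3, 3]
  AS21 <- d1 * Sm[3, 1] - d3 * Sm[1, 1]
  AS22 <- d1 * Sm[3, 2] - d3 * Sm[1, 2]
  AS23 <- d1 * Sm[3, 3] - d3 * Sm[1, 3]
  AS31 <- d2 * Sm[1, 1] - d1 * Sm[2, 1]
  AS32 <- d2 * Sm[1, 2] - d1 * Sm[2, 2]
  AS33 <- d2 * Sm[1, 3] - d1 * Sm[2, 3]

  out <- cbind(Tm[1, 1] + alat11 + 2 * AS11,
               Tm[2, 2] + alat22 + 2 * AS22,
               Tm[3, 3] + alat33 + 2 * AS33,
               Tm[1, 2] + alat12 + AS12 + AS21,
               Tm[1, 3] + alat13 + AS13 + AS31,
               Tm[2, 3] + alat23 + AS23 + AS32)
  dimnames(out) <- NULL
  if (single) out[1, ] else out
}

# Pseudo-inverse of a symmetric PSD 3x3 matrix via eigendecomposition.
sym_pinv <- function(m, tol = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  scale <- max(abs(e$values), 1e-300)
  keep <- e$values > tol * scale
  if (!any(keep)) return(matrix(0, 3, 3))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / e$values[keep])
}

#' Screen a TLS parameter set for physical validity
#'
#' Simplified decomposability check: the joint Gaussian over (theta, t) with
#' covariance blocks L, T and cross term S must exist. Requires (within eps):
#' T positive semi-definite; L positive semi-definite; the columns of S lying
#' in the range of L (no screw coupling along a non-librating axis); and the
#' conditional translation covariance \code{T - S' pinv(L) S} positive
#' semi-definite. All-zero matrices are valid. This is a documented
#' simplification of the full published TLS-decomposition protocol.
#'
#' @param m \code{tls_matrices}
#' @param eps tolerance applied to eigenvalues (and to the S range check)
#' @return logical
#' @export
validate_tls <- function(m, eps = 1e-6) {
  Tm <- u_as_mat(m$T); Lm <- u_as_mat(m$L); Sm <- s_as_mat(m$S)
  if (!is_psd_u(m$T, eps)) return(FALSE)
  if (!is_psd_u(m$L, eps)) return(FALSE)
  Lp <- sym_pinv(Lm)
  resid_s <- (diag(3) - Lm %*% Lp) %*% Sm
  if (max(abs(resid_s)) > max(eps, sqrt(eps * max(abs(Sm), 1e-12)))) {
    return(FALSE)
  }
  Tc <- Tm - t(Sm) %*% Lp %*% Sm
  is_psd_u(u_from_mat((Tc + t(Tc)) / 2), eps)
}

# Graded violation measure used to steer the simplex away from invalid sets;
# 0 for valid parameters.
tls_violation <- function(m, eps = 1e-6) {
  Tm <- u_as_mat(m$T); Lm <- u_as_mat(m$L); Sm <- s_as_mat(m$S)
  v <- 0
  v <- v + max(0, -min(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values) - eps)
  v <- v + max(0, -min(eigen(Lm, symmetric = TRUE, only.values = TRUE)$values) - eps)
  Lp <- sym_pinv(Lm)
  resid_s <- (diag(3) - Lm %*% Lp) %*% Sm
  v <- v + max(0, max(abs(resid_s)) - max(eps, sqrt(eps * max(abs(Sm), 1e-12))))
  Tc <- Tm - t(Sm) %*% Lp %*% Sm
  Tc <- (Tc + t(Tc)) / 2
  v + max(0, -min(eigen(Tc, symmetric = TRUE, only.values = TRUE)$values) - eps)
}

#' Construct a TLS group
#'
#' A TLS group is an atom selection plus normalized TLS matrices and a scalar
#' amplitude (A^2). In normalized form the mean over the group's atoms of
#' Tr(U)/3 from the matrices alone is 1, so the amplitude equals the group's
#' mean U-level contribution (mean B / 8pi^2).
#'
#' @param selection integer vector of atom indices (non-empty)
#' @param matrices \code{tls_matrices}
#' @param amplitude non-negative scalar, A^2
#' @param name optional group label
#' @return object of class \code{tls_group}
#' @export
tls_group <- function(selection, matrices = tls_matrices(), amplitude = 0,
                      name = NULL) {
  selection <- as.integer(selection)
  if (length(selection) == 0L) stop("TLS group selection must be non-empty")
  if (amplitude < 0) stop("TLS group amplitude must be non-negative")
  structure(list(selection = selection, matrices = matrices,
                 amplitude = as.numeric(amplitude), name = name),
            class = "tls_group")
}

#' Renormalize a TLS group
#'
#' Rescales the matrices so the mean over the group's atoms of Tr(U)/3 equals
#' 1, and scales the amplitude inversely, leaving the product (the physical
#' contribution) unchanged per atom. A group whose matrices produce zero mean
#' trace cannot be normalized: its amplitude is set to 0 and matrices are left
#' as they are.
#'
#' @param g \code{tls_group}
#' @param positions n_total x 3 matrix of atom positions indexed by
#'   \code{g$selection}
#' @return renormalized \code{tls_group}
#' @export
normalize_group <- function(g, positions) {
  u <- tls_uij(g$matrices, positions[g$selection, , drop = FALSE])
  s <- mean(u_trace(u) / 3)
  if (abs(s) < 1e-14) {
    g$amplitude <- 0
    return(g)
  }
  g$matrices$T <- g$matrices$T / s
  g$matrices$L <- g$matrices$L / s
  g$matrices$S <- g$matrices$S / s
  g$amplitude <- g$amplitude * s
  g
}

#' Per-atom ADP contributions of a TLS group
#'
#' Returns \code{amplitude * tls_uij(matrices, pos)} for each atom in the
#' selection; a zero amplitude yields all-zero tensors.
#'
#' @param g \code{tls_group}
#' @param positions n_total x 3 matrix indexed by \code{g$selection}
#' @return length(selection) x 6 matrix of tensors
#' @export
group_uijs <- function(g, positions) {
  if (any(g$selection > nrow(positions)) || anyNA(positions[g$selection, ])) {
    stop("TLS group selection refers to atoms without coordinates")
  }
  g$amplitude * tls_uij(g$matrices, positions[g$selection, , drop = FALSE])
}

# --- serialization (JSON sidecar) -------------------------------------------

#' Serialize TLS groups to a JSON string
#' @param groups list of \code{tls_group}
#' @return JSON string (origin, T, L, S, amplitude, selection)
#' @export
tls_to_json <- function(groups) {
  payload <- lapply(groups, function(g) {
    list(name = if (is.null(g$name)) "" else g$name,
         selection = g$selection,
         amplitude = g$amplitude,
         origin = g$matrices$origin,
         T = g$matrices$T, L = g$matrices$L, S = g$matrices$S)
  })
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
}

#' Deserialize TLS groups from a JSON string or file
#' @param txt JSON string or path to a JSON file
#' @return list of \code{tls_group}
#' @export
tls_from_json <- function(txt) {
  payload <- jsonlite::fromJSON(txt, simplifyDataFrame = FALSE)
  lapply(payload, function(p) {
    tls_group(selection = as.integer(p$selection),
              matrices = tls_matrices(T = p$T, L = p$L, S = p$S,
                                      origin = p$origin),
              amplitude = p$amplitude,
              name = if (nzchar(p$name %||% "")) p$name else NULL)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
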