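# Core fitting operations: atom weights, level targets, the weighted
# least-squares residual, elastic-net penalties, a Nelder-Mead simplex with
# validity rejection for TLS matrices, the PSD-constrained atomic update, and
# joint non-negative amplitude optimization.

#' Optimizer configuration
#'
#' @param gamma elastic-net mixing in [0, 1]: 1 = pure lasso, 0 = pure ridge
#' @param delta per-macrocycle penalty decay factor in (0, 1)
#' @param omega0 initial total elastic-net weight (lasso + ridge); "auto"
#'   scales it to \code{kappa * (weighted mean input B) / (8 pi^2)} so the
#'   first macrocycle admits only the largest-scale level
#' @param kappa auto-scaling multiplier for \code{omega0 = "auto"}; the
#'   default 5 puts the initial lasso weight below the full-structure group's
#'   activation threshold (~6x the weighted mean amplitude) but far above
#'   that of any smaller group
#' @param db_cutoff amplitude-stability threshold, in B-factor units (A^2)
#' @param stable_fraction fraction of macrocycles so far over which amplitudes
#'   must stay stable before convergence is declared (minimum 2 cycles)
#' @param rmsd_cutoff optional early stop on RMSD(U_input, U_model) (A^2)
#' @param max_macrocycles hard cap on macrocycles
#' @param max_microcycles hard cap on microcycles per macrocycle
#' @param eps_psd tolerance for positive semi-definiteness (A^2)
#' @param simplex_step initial simplex increment per normalized matrix element
#' @param simplex_maxit evaluation cap per simplex search
#' @param seed integer seed (the fit is deterministic; kept for provenance
#'   and for seeding any downstream simulation)
#' @return object of class \code{echt_config}
#' @export
echt_config <- function(gamma = 0.9, delta = 0.8, omega0 = "auto",
                        kappa = 5, db_cutoff = 0.1, stable_fraction = 0.25,
                        rmsd_cutoff = NULL, max_macrocycles = 60,
                        max_microcycles = 5, eps_psd = 1e-6,
                        simplex_step = 0.01, simplex_maxit = 400, seed = 1) {
  stopifnot(gamma >= 0, gamma <= 1, delta > 0, delta < 1,
            db_cutoff >= 0, stable_fraction > 0, stable_fraction <= 1,
            eps_psd >= 0, simplex_step > 0,
            is.null(rmsd_cutoff) || rmsd_cutoff >= 0)
  structure(list(gamma = gamma, delta = delta, omega0 = omega0, kappa = kappa,
                 db_cutoff = db_cutoff, stable_fraction = stable_fraction,
                 rmsd_cutoff = rmsd_cutoff, max_macrocycles = max_macrocycles,
                 max_microcycles = max_microcycles, eps_psd = eps_psd,
                 simplex_step = simplex_step, simplex_maxit = simplex_maxit,
                 seed = as.integer(seed)),
            class = "echt_config")
}

#' Per-atom fitting weights
#'
#' \code{w_a} is proportional to the inverse mean-square displacement
#' \code{1 / (Tr(U_a)/3)} and normalized to sum to one, reducing the pull of
#' large-B atoms on the large-scale levels during the early cycles.
#'
#' @param input_u n x 6 matrix of input ADPs
#' @return numeric vector of weights summing to 1
#' @export
compute_weights <- function(input_u) {
  tr3 <- u_trace(input_u) / 3
  if (any(tr3 <= 0)) {
    stop("atom(s) with non-positive ADP trace (indices ",
         paste(utils::head(which(tr3 <= 0), 10), collapse = ", "),
         "): weights are undefined")
  }
  w <- 1 / tr3
  w / sum(w)
}

#' Fitting target for one level
#'
#' The input ADPs minus the contributions of every other level; may be
#' non-PSD (it is a fitting target, not a physical ADP).
#'
#' @param input_u n x 6 input ADPs
#' @param level_contribs list of n x 6 per-level contribution matrices
#' @param k index of the level being optimized
#' @return n x 6 target matrix
#' @export
level_target <- function(input_u, level_contribs, k) {
  out <- input_u
  for (l in seq_along(level_contribs)) {
    if (l != k) out <- out - level_contribs[[l]]
  }
  out
}

#' Weighted least-squares ADP residual
#'
#' For anisotropic atoms the per-atom discrepancy is the squared Frobenius
#' norm of the tensor difference (off-diagonals double-counted); for
#' isotropic atoms it is the squared difference of the isotropic equivalents,
#' \code{(Tr(dU)/3)^2}.
#'
#' @param target,candidate n x 6 matrices
#' @param weights per-atom weights
#' @param iso logical vector: TRUE for atoms compared isotropically
#' @return non-negative scalar; 0 iff equal (up to the isotropic projection)
#' @export
adp_residual <- function(target, candidate, weights, iso = NULL) {
  target <- u_as_rows(target); candidate <- u_as_rows(candidate)
  d <- target - candidate
  m <- u_norm2(d)
  if (!is.null(iso) && any(iso)) {
    m[iso] <- (u_trace(d[iso, , drop = FALSE]) / 3)^2
  }
  sum(weights * m)
}

#' Elastic-net penalty on component amplitudes
#'
#' \code{omega_alpha * sum(A) + omega_beta * sum(A^2)}; with total weight
#' \code{omega0} and mixing \code{gamma}, \code{omega_alpha = gamma * omega0}
#' (lasso) and \code{omega_beta = (1 - gamma) * omega0} (ridge).
#'
#' @param amplitudes non-negative amplitudes
#' @param omega_alpha lasso weight
#' @param omega_beta ridge weight
#' @export
elastic_net_penalty <- function(amplitudes, omega_alpha, omega_beta) {
  omega_alpha * sum(amplitudes) + omega_beta * sum(amplitudes^2)
}

#' Decay an elastic-net weight
#' @param omega current weight
#' @param delta decay factor in (0, 1)
#' @param n_cycles number of decay steps
#' @export
decay_weights <- function(omega, delta, n_cycles) {
  stopifnot(delta > 0, delta < 1, n_cycles >= 0)
  omega * delta^n_cycles
}

# --- Nelder-Mead with explicit initial simplex ------------------------------

# Plain Nelder-Mead; the initial simplex is x0 plus `step` along each
# coordinate, which for TLS matrices corresponds to incrementing each
# normalized matrix element independently. Returns the best vertex; the
# value never exceeds fn(x0).
nelder_mead <- function(fn, x0, step, maxit = 400, reltol = 1e-8) {
  np <- length(x0)
  verts <- matrix(rep(x0, np + 1), ncol = np, byrow = TRUE)
  for (i in seq_len(np)) verts[i + 1, i] <- verts[i + 1, i] + step
  vals <- apply(verts, 1, fn)
  evals <- np + 1
  alpha <- 1; gamma_e <- 2; rho <- 0.5; sigma <- 0.5
  while (evals < maxit) {
    ord <- order(vals)
    verts <- verts[ord, , drop = FALSE]; vals <- vals[ord]
    if (abs(vals[np + 1] - vals[1]) <=
        reltol * (abs(vals[1]) + reltol)) break
    centroid <- colMeans(verts[1:np, , drop = FALSE])
    xr <- centroid + alpha * (centroid - verts[np + 1, ])
    fr <- fn(xr); evals <- evals + 1
    if (fr < vals[1]) {
      xe <- centroid + gamma_e * (xr - centroid)
      fe <- fn(xe); evals <- evals + 1
      if (fe < fr) { verts[np + 1, ] <- xe; vals[np + 1] <- fe }
      else { verts[np + 1, ] <- xr; vals[np + 1] <- fr }
    } else if (fr < vals[np]) {
      verts[np + 1, ] <- xr; vals[np + 1] <- fr
    } else {
      xc <- centroid + rho * (verts[np + 1, ] - centroid)
      fc <- fn(xc); evals <- evals + 1
      if (fc < vals[np + 1]) {
        verts[np + 1, ] <- xc; vals[np + 1] <- fc
      } else {
        for (i in 2:(np + 1)) {
          verts[i, ] <- verts[1, ] + sigma * (verts[i, ] - verts[1, ])
          vals[i] <- fn(verts[i, ])
        }
        evals <- evals + np
      }
    }
  }
  best <- which.min(vals)
  list(par = verts[best, ], value = vals[best], evals = evals,
       converged = evals < maxit)
}

# Rotation that diagonalizes L (columns = eigenvectors); identity when L = 0.
l_eigenframe <- function(L) {
  if (max(abs(L)) < 1e-12) return(diag(3))
  eigen(u_as_mat(L), symmetric = TRUE)$vectors
}

tls_to_par <- function(m, R) {
  Tp <- t(R) %*% u_as_mat(m$T) %*% R
  Lp <- t(R) %*% u_as_mat(m$L) %*% R
  Sp <- t(R) %*% s_as_mat(m$S) %*% R
  c(u_from_mat(Tp), u_from_mat(Lp), s_from_mat(Sp))
}

par_to_tls <- function(x, R, origin) {
  Tm <- R %*% u_as_mat(x[1:6]) %*% t(R)
  Lm <- R %*% u_as_mat(x[7:12]) %*% t(R)
  Sm <- R %*% s_as_mat(x[13:20]) %*% t(R)
  # the rotated S need not be traceless numerically; remove the trace (it
  # does not affect the ADPs)
  Sm <- Sm - diag(3) * sum(diag(Sm)) / 3
  tls_matrices(T = u_from_mat(Tm), L = u_from_mat(Lm), S = s_from_mat(Sm),
               origin = origin)
}

#' Simplex optimization of one group's TLS matrices
#'
#' Optimizes the 20 free normalized matrix elements (6 T, 6 L, 8 S) of a
#' group at fixed amplitude against a level target, in the coordinate basis
#' of the current L matrix (lab frame when L = 0). Candidate parameter sets
#' failing \code{\link{validate_tls}} are rejected through a graded penalty.
#' The objective includes the elastic-net cost of the renormalized amplitude
#' so that the subsequent renormalization per the unit-mean-trace convention
#' cannot increase the penalized objective. Groups with zero amplitude are
#' returned unchanged (the objective is flat in their matrices).
#'
#' @param group \code{tls_group}
#' @param target n_total x 6 target ADPs (indexed by the group selection)
#' @param weights per-atom weights (full length)
#' @param positions n_total x 3 coordinates
#' @param config \code{echt_config}
#' @param omega_alpha,omega_beta current elastic-net weights
#' @param iso full-length logical vector of isotropic-comparison flags
#' @return updated, renormalized \code{tls_group}; attribute
#'   "simplex_converged" flags whether the search hit its evaluation cap
#' @export
optimize_tls_matrices <- function(group, target, weights, positions, config,
                                  omega_alpha = 0, omega_beta = 0,
                                  iso = NULL) {
  if (group$amplitude == 0) return(group)
  sel <- group$selection
  pos_sel <- positions[sel, , drop = FALSE]
  tgt <- target[sel, , drop = FALSE]
  w <- weights[sel]
  iso_sel <- if (is.null(iso)) NULL else iso[sel]
  A <- group$amplitude
  origin <- group$matrices$origin
  R <- l_eigenframe(group$matrices$L)
  x0 <- tls_to_par(group$matrices, R)

  fn <- function(x) {
    m <- par_to_tls(x, R, origin)
    v <- tls_violation(m, config$eps_psd)
    if (v > 0) return(1e6 * (1 + v))
    u <- tls_uij(m, pos_sel)
    s <- mean(u_trace(u) / 3)
    adp_residual(tgt, A * u, w, iso_sel) +
      omega_alpha * A * s + omega_beta * (A * s)^2
  }

  res <- nelder_mead(fn, x0, step = config$simplex_step,
                     maxit = config$simplex_maxit)
  group$matrices <- par_to_tls(res$par, R, origin)
  group <- normalize_group(group, positions)
  attr(group, "simplex_converged") <- res$converged
  group
}

#' PSD-constrained atomic-level update
#'
#' Minimizes the per-atom weighted least-squares discrepancy against the
#' atomic-level target subject to the result being positive semi-definite:
#' for anisotropic atoms this is the eigenvalue-clipping projection of the
#' target (the per-atom weight is a scalar and does not move the minimizer);
#' for isotropic atoms it is \code{max(0, Tr(target)/3) * I}. Results are
#' returned in normalized form: amplitude \code{A_a = Tr(U_a)/3} and a
#' unit-mean-trace shape tensor (identity when the amplitude is zero).
#'
#' @param target n x 6 atomic-level target
#' @param weights per-atom weights (unused by the minimizer; kept for the
#'   operation's contract)
#' @param config \code{echt_config}
#' @param iso logical vector: isotropic atoms
#' @return list with \code{uhat} (n x 6 normalized shapes) and
#'   \code{amplitudes} (length n)
#' @export
optimize_atomic_adps <- function(target, weights = NULL, config = echt_config(),
                                 iso = NULL) {
  target <- u_as_rows(target)
  n <- nrow(target)
  if (is.null(iso)) iso <- rep(FALSE, n)
  proj <- target
  if (any(!iso)) proj[!iso, ] <- u_as_rows(psd_project_u(target[!iso, , drop = FALSE]))
  if (any(iso)) {
    c_iso <- pmax(0, u_trace(target[iso, , drop = FALSE]) / 3)
    proj[iso, ] <- cbind(c_iso, c_iso, c_iso, 0, 0, 0)
  }
  amps <- u_trace(proj) / 3
  amps[amps < 0] <- 0
  uhat <- matrix(rep(c(1, 1, 1, 0, 0, 0), each = n), n, 6)
  nz <- amps > 0
  uhat[nz, ] <- proj[nz, , drop = FALSE] / amps[nz]
  list(uhat = uhat, amplitudes = amps)
}

#' Joint non-negative amplitude optimization with elastic-net penalties
#'
#' Minimizes the weighted least-squares residual against the input ADPs plus
#' the elastic-net penalty over all component amplitudes jointly (TLS groups
#' and atomic shapes), subject to A >= 0, using L-BFGS-B with analytic
#' gradients, initialized at the current amplitudes.
#'
#' @param bases list of components; each a list with \code{idx} (atom
#'   indices) and \code{phi} (length(idx) x 6 fixed per-atom tensors of the
#'   normalized component)
#' @param input_u n x 6 input ADPs
#' @param weights per-atom weights
#' @param omega_alpha,omega_beta elastic-net weights
#' @param start starting amplitudes (defaults to zeros)
#' @param iso logical vector of isotropic-comparison flags
#' @return list with \code{amplitudes} and the attained \code{objective}
#' @export
optimize_amplitudes <- function(bases, input_u, weights, omega_alpha = 0,
                                omega_beta = 0, start = NULL, iso = NULL) {
  input_u <- u_as_rows(input_u)
  n <- nrow(input_u)
  if (is.null(iso)) iso <- rep(FALSE, n)
  nc <- length(bases)
  if (is.null(start)) start <- numeric(nc)

  model_of <- function(A) {
    m <- matrix(0, n, 6)
    for (j in seq_len(nc)) {
      if (A[j] != 0) {
        m[bases[[j]]$idx, ] <- m[bases[[j]]$idx, ] + A[j] * bases[[j]]$phi
      }
    }
    m
  }
  fn <- function(A) {
    adp_residual(input_u, model_of(A), weights, iso) +
      elastic_net_penalty(A, omega_alpha, omega_beta)
  }
  gr <- function(A) {
    resid <- input_u - model_of(A)
    tr3 <- u_trace(resid) / 3
    g <- numeric(nc)
    for (j in seq_len(nc)) {
      idx <- bases[[j]]$idx
      phi <- bases[[j]]$phi
      dots <- u_dot(resid[idx, , drop = FALSE], phi)
      ii <- iso[idx]
      if (any(ii)) {
        # isotropic metric: d/dA of (trR/3 - A trPhi/3)^2 terms
        dots[ii] <- tr3[idx][ii] * (u_trace(phi[ii, , drop = FALSE]) / 3)
      }
      g[j] <- -2 * sum(weights[idx] * dots) + omega_alpha + 2 * omega_beta * A[j]
    }
    g
  }

  res <- stats::optim(start, fn, gr, method = "L-BFGS-B", lower = 0,
                      control = list(factr = 1e4, maxit = 500))
  # keep the better of start and result (the objective must not increase)
  f_start <- fn(start)
  if (res$value <= f_start) {
    list(amplitudes = res$par, objective = res$value)
  } else {
    list(amplitudes = start, objective = f_start)
  }
}
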