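# The hierarchical fit: alternating per-level TLS simplex optimization and
# joint elastic-net amplitude optimization, under a decaying penalty
# schedule. Macrocycles decay the penalties; microcycles alternate matrix and
# amplitude updates until the amplitudes stop changing.

# Per-level contribution matrices (n x 6 each), atomic level last.
compute_level_contribs <- function(levels, atomic, pos, n) {
  out <- lapply(levels, function(lv) {
    m <- matrix(0, n, 6)
    if (lv$kind == "tls") {
      for (g in lv$groups) {
        if (g$amplitude > 0) {
          m[g$selection, ] <- m[g$selection, ] + group_uijs(g, pos)
        }
      }
    } else {
      m <- atomic$amp * atomic$uhat
    }
    m
  })
  out
}

collect_amplitudes <- function(levels, atomic) {
  amps <- numeric(0)
  for (lv in levels) {
    if (lv$kind == "tls") {
      amps <- c(amps, vapply(lv$groups, `[[`, 0, "amplitude"))
    }
  }
  c(amps, atomic$amp)
}

# RMSD between two ADP sets in the fit metric: sqrt(mean ||dU||_F^2 / 3),
# with isotropic atoms compared through their isotropic equivalents.
adp_rmsd <- function(u1, u2, iso = NULL) {
  d <- u_as_rows(u1) - u_as_rows(u2)
  m <- u_norm2(d) / 3
  if (!is.null(iso) && any(iso)) {
    m[iso] <- (u_trace(d[iso, , drop = FALSE]) / 3)^2
  }
  sqrt(mean(m))
}

#' Fit the hierarchical TLS disorder decomposition
#'
#' Re-factors the input ADPs into the level scheme's TLS contributions plus a
#' per-atom residual level. Each macrocycle runs microcycles that (i)
#' simplex-optimize every active group's normalized TLS matrices against the
#' level target (input minus all other levels), (ii) update the atomic shapes
#' under the PSD constraint, and (iii) jointly optimize all component
#' amplitudes under non-negativity with elastic-net penalties; the penalties
#' then decay by \code{delta}. Optimization stops when all component
#' amplitudes have been stable (below \code{db_cutoff} in B-factor units)
#' over a fraction of the cycles run so far, when the optional RMSD cutoff is
#' reached, or at \code{max_macrocycles}.
#'
#' @param atoms atom table carrying ADPs (anisotropic tensors used where
#'   present, isotropic B elsewhere)
#' @param scheme \code{level_scheme}; default \code{build_default_scheme}
#' @param config \code{echt_config}
#' @param isotropic if TRUE, fit all atoms against their isotropic
#'   equivalent B only (the anisotropy of the TLS components is then
#'   unconstrained by the data); if NULL, inferred per atom from the input
#' @return object of class \code{echt_fit}: the fitted scheme and atomic
#'   level, the optimization trace (one row per macrocycle and level), and
#'   convergence diagnostics
#' @export
fit_echt <- function(atoms, scheme = NULL, config = echt_config(),
                     isotropic = NULL) {
  n <- nrow(atoms)
  if (n == 0) stop("empty structure")
  pos <- atom_positions(atoms)
  u_input <- atom_uijs(atoms)
  iso <- if (isTRUE(isotropic)) rep(TRUE, n) else !atom_is_aniso(atoms)
  weights <- compute_weights(u_input)
  if (is.null(scheme)) scheme <- build_default_scheme(atoms)
  levels <- scheme$levels
  n_levels <- length(levels)
  atomic_i <- n_levels
  tls_idx <- which(vapply(levels, `[[`, "", "kind") == "tls")

  # initialization: isotropic T, zero L/S, centroid origin, zero amplitudes
  for (li in tls_idx) {
    levels[[li]]$groups <- lapply(levels[[li]]$groups, function(g) {
      g$matrices <- tls_matrices(T = c(1, 1, 1, 0, 0, 0),
                                 origin = colMeans(pos[g$selection, ,
                                                       drop = FALSE]))
      g$amplitude <- 0
      g
    })
  }
  atomic <- list(uhat = matrix(rep(c(1, 1, 1, 0, 0, 0), each = n), n, 6),
                 amp = numeric(n))

  # Auto penalty scaling: the activation gradient of a full-coverage group
  # with matching shape is ~ 2 * f * (weighted mean amplitude), where the
  # metric factor f is 3 for anisotropic atoms (Frobenius) and 1 for
  # isotropic atoms (trace metric). kappa = 5 with gamma = 0.9 puts the
  # initial lasso weight below that threshold (admitting the first level in
  # macrocycle 1) but well above the gradient of any smaller group.
  omega0 <- if (identical(config$omega0, "auto")) {
    metric_f <- ifelse(iso, 1, 3)
    config$kappa * sum(weights * metric_f * u_trace(u_input) / 3) / 3
  } else {
    as.numeric(config$omega0)
  }

  build_bases <- function() {
    bases <- list()
    for (li in tls_idx) {
      for (g in levels[[li]]$groups) {
        bases[[length(bases) + 1L]] <-
          list(idx = g$selection,
               phi = tls_uij(g$matrices, pos[g$selection, , drop = FALSE]))
      }
    }
    for (a in seq_len(n)) {
      bases[[length(bases) + 1L]] <- list(idx = a,
                                          phi = matrix(atomic$uhat[a, ], 1))
    }
    bases
  }
  assign_amps <- function(A) {
    k <- 0
    for (li in tls_idx) {
      for (gi in seq_along(levels[[li]]$groups)) {
        k <- k + 1
        levels[[li]]$groups[[gi]]$amplitude <<- A[k]
      }
    }
    atomic$amp <<- A[(k + 1):(k + n)]
  }

  trace_rows <- list()
  micro_obj_log <- list()
  amps_prev_macro <- collect_amplitudes(levels, atomic)
  stable_streak <- 0
  converged <- FALSE
  macro <- 0
  db_amp <- config$db_cutoff / B_FROM_U

  while (macro < config$max_macrocycles) {
    macro <- macro + 1
    omega <- decay_weights(omega0, config$delta, macro - 1)
    oa <- config$gamma * omega
    ob <- (1 - config$gamma) * omega
    micro_objs <- numeric(0)

    for (micro in seq_len(config$max_microcycles)) {
      amps_prev <- collect_amplitudes(levels, atomic)

      # (i) TLS matrix optimization, largest scale first
      for (li in tls_idx) {
        contribs <- compute_level_contribs(levels, atomic, pos, n)
        tgt <- level_target(u_input, contribs, li)
        for (gi in seq_along(levels[[li]]$groups)) {
          g <- levels[[li]]$groups[[gi]]
          if (g$amplitude == 0) next
          levels[[li]]$groups[[gi]] <- optimize_tls_matrices(
            g, tgt, weights, pos, config, oa, ob, iso)
        }
      }

      # (ii) atomic shape update at fixed amplitude (accepted per atom only
      # when not worse, so the objective cannot increase)
      contribs <- compute_level_contribs(levels, atomic, pos, n)
      tgt <- level_target(u_input, contribs, atomic_i)
      upd <- optimize_atomic_adps(tgt, weights, config, iso)
      res_old <- per_atom_resid(tgt, atomic$amp * atomic$uhat, iso)
      res_new <- per_atom_resid(tgt, atomic$amp * upd$uhat, iso)
      take <- res_new <= res_old + 1e-15
      atomic$uhat[take, ] <- upd$uhat[take, , drop = FALSE]

      # (iii) joint amplitude optimization
      bases <- build_bases()
      out <- optimize_amplitudes(bases, u_input, weights, oa, ob,
                                 start = collect_amplitudes(levels, atomic),
                                 iso = iso)
      assign_amps(out$amplitudes)
      micro_objs <- c(micro_objs, out$objective)

      d_amp <- max(abs(collect_amplitudes(levels, atomic) - amps_prev))
      if (d_amp < db_amp) break
    }

    micro_obj_log[[macro]] <- micro_objs
    contribs <- compute_level_contribs(levels, atomic, pos, n)
    total <- Reduce(`+`, contribs)
    resid_val <- adp_residual(u_input, total, weights, iso)
    rmsd <- adp_rmsd(u_input, total, iso)
    for (li in seq_len(n_levels)) {
      lv_amps <- if (levels[[li]]$kind == "tls") {
        vapply(levels[[li]]$groups, `[[`, 0, "amplitude")
      } else {
        atomic$amp
      }
      trace_rows[[length(trace_rows) + 1L]] <- data.frame(
        macrocycle = macro, level = levels[[li]]$name,
        mean_b = mean(u_to_b(contribs[[li]])),
        sum_amp = sum(lv_amps), sum_amp_sq = sum(lv_amps^2),
        omega_alpha = oa, omega_beta = ob,
        objective = micro_objs[length(micro_objs)],
        residual = resid_val, rmsd = rmsd, n_micro = length(micro_objs),
        stringsAsFactors = FALSE)
    }

    amps_now <- collect_amplitudes(levels, atomic)
    if (max(abs(amps_now - amps_prev_macro)) < db_amp) {
      stable_streak <- stable_streak + 1
    } else {
      stable_streak <- 0
    }
    amps_prev_macro <- amps_now
    need <- max(2, ceiling(config$stable_fraction * macro))
    if (stable_streak >= need) {
      converged <- TRUE
      break
    }
    if (!is.null(config$rmsd_cutoff) && rmsd <= config$rmsd_cutoff) {
      converged <- TRUE
      break
    }
  }

  trace <- do.call(rbind, trace_rows)
  attr(trace, "micro_objectives") <- micro_obj_log

  scheme$levels <- levels
  structure(list(atoms = atoms, scheme = scheme, atomic = atomic,
                 trace = trace, config = config, converged = converged,
                 n_macrocycles = macro, rmsd = rmsd, u_input = u_input,
                 weights = weights, iso = iso),
            class = "echt_fit")
}

per_atom_resid <- function(target, candidate, iso) {
  d <- target - candidate
  m <- u_norm2(d)
  if (any(iso)) m[iso] <- (u_trace(d[iso, , drop = FALSE]) / 3)^2
  m
}

#' Fit against isotropic equivalent B-factors only
#'
#' For structures refined with i-ADPs (or to force isotropic treatment of a
#' mixed structure): only the magnitudes of the anisotropic TLS components
#' are fitted against the input equivalent B-factors, so the per-atom
#' residual compares \code{Tr(U)/3} values, and the atomic level is
#' isotropic. Note the fitted TLS anisotropy is then not constrained by the
#' data: TLS parameter sets with equal per-atom traces fit equally well.
#'
#' @inheritParams fit_echt
#' @return \code{echt_fit}
#' @export
fit_isotropic_mode <- function(atoms, scheme = NULL, config = echt_config()) {
  fit_echt(atoms, scheme, config, isotropic = TRUE)
}

#' Per-level and total model ADPs of a fitted decomposition
#'
#' @param fit \code{echt_fit}
#' @return list with \code{levels} (list of n x 6 matrices, one per level)
#'   and \code{total} (their sum; exact additivity by construction)
#' @export
model_uijs <- function(fit) {
  pos <- atom_positions(fit$atoms)
  contribs <- compute_level_contribs(fit$scheme$levels, fit$atomic, pos,
                                     nrow(fit$atoms))
  names(contribs) <- vapply(fit$scheme$levels, `[[`, "", "name")
  list(levels = contribs, total = Reduce(`+`, contribs))
}

#' Model complexity of a fitted decomposition
#'
#' The sum of all component amplitudes (TLS groups plus atomic components),
#' and the same number normalized per atom.
#'
#' @param fit \code{echt_fit}
#' @return list with \code{sum_amplitudes} (A^2) and \code{per_atom}
#' @export
model_complexity <- function(fit) {
  s <- sum(collect_amplitudes(fit$scheme$levels, fit$atomic))
  list(sum_amplitudes = s, per_atom = s / nrow(fit$atoms))
}

#' Per-level mean-B summary table
#'
#' @param fit \code{echt_fit}
#' @return data.frame with level, mean B (A^2) and percentage of the total
#' @export
level_summary <- function(fit) {
  mu <- model_uijs(fit)
  mean_b <- vapply(mu$levels, function(m) mean(u_to_b(m)), 0)
  total <- sum(mean_b)
  data.frame(level = names(mu$levels), mean_b = as.numeric(mean_b),
             percent = if (total > 0) 100 * as.numeric(mean_b) / total
                       else rep(0, length(mean_b)),
             stringsAsFactors = FALSE)
}

#' @export
print.echt_fit <- function(x, ...) {
  cat("Hierarchical TLS decomposition (", nrow(x$atoms), " atoms, ",
      x$n_macrocycles, " macrocycles, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  s <- level_summary(x)
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s %8.3f A^2  (%5.1f%%)\n",
                s$level[i], s$mean_b[i], s$percent[i]))
  }
  cx <- model_complexity(x)
  cat(sprintf("  complexity: sum(A) = %.4f A^2 (%.5f per atom); RMSD %.4f A^2\n",
              cx$sum_amplitudes, cx$per_atom, x$rmsd))
  invisible(x)
}
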