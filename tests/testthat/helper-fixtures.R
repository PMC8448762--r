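# Shared fixture builders. All fixtures are generated in code; no data files.

NO_GAP_SEQ <- c("SER", "LEU", "VAL", "THR", "ASP", "ASN")

peptide_no_gap <- function(n = 6) {
  make_peptide(n, sequence = rep_len(NO_GAP_SEQ, n))
}

# Criterion-2 style fixture: one chain-level isotropic group, mean B 10.
chain_fixture <- function(mean_b = 10, n = 6) {
  pep <- peptide_no_gap(n)
  sch <- build_default_scheme(pep, levels = c("chain", "residue"))
  gt <- make_ground_truth(pep, sch,
                          spec = list(list(level = "chain", group = 1,
                                           mean_b = mean_b)))
  list(atoms = gt$atoms, scheme = sch, truth = gt$truth)
}

# Criterion-3 style fixture: chain 8 A^2 plus one hot residue +20 A^2.
hotspot_fixture <- function(chain_b = 8, hot_b = 20, hot_res = 4, n = 8,
                            isotropic = FALSE) {
  pep <- peptide_no_gap(n)
  sch <- build_default_scheme(pep, levels = c("chain", "residue"))
  gt <- make_ground_truth(pep, sch,
                          spec = list(
                            list(level = "chain", group = 1, mean_b = chain_b),
                            list(level = "residue", group = hot_res,
                                 mean_b = hot_b)),
                          isotropic_output = isotropic)
  list(atoms = gt$atoms, scheme = sch, truth = gt$truth, hot_res = hot_res)
}

# Short-schedule config for invariant tests that do not need convergence.
fast_config <- function(...) {
  echt_config(max_macrocycles = 8, ...)
}

# Random valid small-angle TLS matrices (seeded). T is made diagonally
# dominant so the set passes the validity screen with slack.
random_valid_tls <- function(seed, l_scale = 0.003, t_scale = 0.05,
                             s_scale = 5e-4) {
  set.seed(seed)
  Tm <- crossprod(matrix(rnorm(9, 0, sqrt(t_scale)), 3)) + diag(3) * t_scale
  Lm <- crossprod(matrix(rnorm(9, 0, sqrt(l_scale)), 3)) + diag(3) * l_scale
  Sm <- matrix(rnorm(9, 0, s_scale), 3)
  Sm <- Sm - diag(3) * sum(diag(Sm)) / 3
  m <- tls_matrices(T = u_from_mat(Tm), L = u_from_mat(Lm),
                    S = c(Sm[1, 1], Sm[1, 2], Sm[1, 3], Sm[2, 1], Sm[2, 2],
                          Sm[2, 3], Sm[3, 1], Sm[3, 2]),
                    origin = rnorm(3))
  stopifnot(validate_tls(m))
  m
}

# Fit-model invariant checks shared by unit and acceptance tests.
check_fit_invariants <- function(fit) {
  # amplitudes non-negative
  for (lv in fit$scheme$levels) {
    if (lv$kind == "tls") {
      for (g in lv$groups) expect_gte(g$amplitude, 0)
    }
  }
  expect_true(all(fit$atomic$amp >= 0))

  # additivity: total equals the sum of per-level contributions recomputed
  # from the fitted parameters
  mu <- model_uijs(fit)
  pos <- atom_positions(fit$atoms)
  manual <- matrix(0, nrow(fit$atoms), 6)
  for (lv in fit$scheme$levels) {
    if (lv$kind == "tls") {
      for (g in lv$groups) {
        if (g$amplitude > 0) {
          manual[g$selection, ] <- manual[g$selection, ] + group_uijs(g, pos)
        }
      }
    }
  }
  manual <- manual + fit$atomic$amp * fit$atomic$uhat
  expect_equal(mu$total, manual, tolerance = 1e-12)

  # group normalization (unit mean trace) for active groups
  for (lv in fit$scheme$levels) {
    if (lv$kind != "tls") next
    for (g in lv$groups) {
      if (g$amplitude > 0) {
        u <- tls_uij(g$matrices, pos[g$selection, , drop = FALSE])
        expect_equal(mean(u_trace(u) / 3), 1, tolerance = 1e-6)
      }
    }
  }

  # atomic shapes PSD within eps
  nz <- fit$atomic$amp > 0
  if (any(nz)) {
    expect_true(all(is_psd_u(fit$atomic$uhat[nz, , drop = FALSE],
                             fit$config$eps_psd)))
  }

  # penalized objective non-increasing across microcycles in each macrocycle
  for (objs in attr(fit$trace, "micro_objectives")) {
    if (length(objs) > 1) {
      expect_true(all(diff(objs) <= 1e-9 * pmax(1, abs(objs[-length(objs)]))))
    }
  }
  invisible(fit)
}

level_mean_b <- function(fit, level_name) {
  mu <- model_uijs(fit)
  mean(u_to_b(mu$levels[[level_name]]))
}
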