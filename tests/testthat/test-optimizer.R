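# Optimizer building blocks and fit-level invariants.

test_that("weights are inverse mean-square displacement, normalized", {
  u <- rbind(b_to_u(0.5 * 8 * pi^2), b_to_u(1.0 * 8 * pi^2))
  expect_equal(compute_weights(u), c(2 / 3, 1 / 3))
  u4 <- do.call(rbind, rep(list(anisou(0.2, 0.2, 0.2)), 4))
  expect_equal(compute_weights(u4), rep(0.25, 4))
  expect_equal(compute_weights(matrix(anisou(1, 1, 1), 1)), 1)
  expect_error(compute_weights(matrix(anisou(0, 0, 0), 1)), "undefined")
})

test_that("level target subtracts every other level", {
  u_in <- matrix(anisou(2, 2, 2), 1)
  zero <- matrix(0, 1, 6)
  other <- matrix(anisou(0.5, 0.5, 0.5), 1)
  expect_equal(level_target(u_in, list(zero, zero), 1), u_in)
  # other levels sum exactly to the input -> target is zero
  expect_equal(level_target(u_in, list(other, u_in), 1), zero)
  expect_equal(level_target(u_in, list(zero, other), 1),
               matrix(anisou(1.5, 1.5, 1.5), 1))
})

test_that("residual double-counts off-diagonals and vanishes iff equal", {
  u <- matrix(anisou(0.1, 0.2, 0.3, 0.01, 0.02, 0.03), 1)
  expect_equal(adp_residual(u, u, 1), 0)
  expect_equal(adp_residual(matrix(anisou(1, 1, 1), 1),
                            matrix(0, 1, 6), 1), 3)
  expect_equal(adp_residual(matrix(anisou(0, 0, 0, 1), 1),
                            matrix(0, 1, 6), 1), 2)
  # isotropic metric compares traces
  expect_equal(adp_residual(matrix(anisou(1, 2, 3), 1), matrix(0, 1, 6),
                            1, iso = TRUE), 4)
})

test_that("elastic-net penalty and decay follow the stated forms", {
  expect_equal(elastic_net_penalty(c(1, 2), 0.1, 0.2), 0.1 * 3 + 0.2 * 5)
  expect_equal(elastic_net_penalty(c(1, 2), 0.3, 0), 0.9)  # pure lasso
  expect_equal(elastic_net_penalty(c(1, 2), 0, 0), 0)
  expect_equal(decay_weights(1, 0.8, 3), 0.512)
  expect_equal(decay_weights(2.5, 0.8, 0), 2.5)
  # gamma splits omega0 into lasso/ridge parts
  g <- 0.9; o0 <- 2
  expect_equal(g * o0 + (1 - g) * o0, o0)
})

test_that("atomic update copies PSD targets and projects non-PSD ones", {
  tgt <- rbind(anisou(0.1, 0.2, 0.15, 0.02, 0, 0.01),  # PSD
               anisou(1, 1, -0.5),                      # needs projection
               anisou(0, 0, 0))
  res <- optimize_atomic_adps(tgt, weights = rep(1 / 3, 3))
  expect_equal(res$amplitudes[1] * res$uhat[1, ], tgt[1, ])
  expect_equal(res$amplitudes[2] * res$uhat[2, ], anisou(1, 1, 0))
  expect_equal(res$amplitudes[3], 0)
  expect_equal(res$uhat[3, ], anisou(1, 1, 1))  # unit-trace placeholder
  # isotropic atoms become isotropic with clipped non-negative amplitude
  res_iso <- optimize_atomic_adps(rbind(anisou(1, 2, 3, 0.5, 0, 0),
                                        anisou(-1, -1, -1)),
                                  iso = c(TRUE, TRUE))
  expect_equal(res_iso$amplitudes, c(2, 0))
  expect_equal(res_iso$uhat[1, ], anisou(1, 1, 1))
})

test_that("1-D lasso amplitude has the closed-form solution", {
  # single amplitude, one atom, weight 1, unit-mean-trace shape:
  # minimize (1 - A)^2 * c + oa * A with c = |Uhat|^2 -> A* = 1 - oa / (2c)
  uhat <- anisou(1.2, 0.9, 0.9, 0.1, 0, -0.05)
  expect_equal(u_trace(uhat) / 3, 1)
  cc <- u_norm2(uhat)
  bases <- list(list(idx = 1L, phi = matrix(uhat, 1)))
  for (oa in c(0.5, 2, 10 * cc)) {
    out <- optimize_amplitudes(bases, matrix(uhat, 1), weights = 1,
                               omega_alpha = oa, start = 0.5)
    expect_equal(out$amplitudes, max(0, 1 - oa / (2 * cc)), tolerance = 1e-6)
  }
})

test_that("amplitudes reproduce a spanned target exactly without penalties", {
  set.seed(3)
  phi1 <- matrix(rep(anisou(1, 1, 1), each = 4), 4, 6)
  m2 <- random_valid_tls(21)
  pos <- matrix(rnorm(12, 0, 3), 4)
  g <- normalize_group(tls_group(1:4, m2, amplitude = 1), pos)
  phi2 <- tls_uij(g$matrices, pos)
  a_true <- c(0.07, 0.12)
  target <- a_true[1] * phi1 + a_true[2] * phi2
  out <- optimize_amplitudes(list(list(idx = 1:4, phi = phi1),
                                  list(idx = 1:4, phi = phi2)),
                             target, weights = rep(0.25, 4))
  expect_equal(out$amplitudes, a_true, tolerance = 1e-5)
  expect_lt(out$objective, 1e-10)
  # a dominating lasso weight drives everything to zero
  out0 <- optimize_amplitudes(list(list(idx = 1:4, phi = phi1),
                                   list(idx = 1:4, phi = phi2)),
                              target, weights = rep(0.25, 4),
                              omega_alpha = 100)
  expect_equal(out0$amplitudes, c(0, 0))
})

test_that("simplex matrix optimization recovers a known TLS field", {
  m_true <- random_valid_tls(31, l_scale = 0.002, t_scale = 0.04, s_scale = 0)
  pos <- matrix(rnorm(24, 0, 4), 8)
  g_true <- normalize_group(tls_group(1:8, m_true, amplitude = 1), pos)
  g_true$amplitude <- 0.1
  target <- matrix(0, 8, 6)
  target[1:8, ] <- group_uijs(g_true, pos)
  g_true$matrices$origin <- colMeans(pos)  # not used; fit uses its own origin
  g <- tls_group(1:8, tls_matrices(T = c(1, 1, 1, 0, 0, 0),
                                   origin = colMeans(pos)), amplitude = 0.1)
  cfg <- echt_config(simplex_maxit = 4000)
  w <- rep(1 / 8, 8)
  for (i in 1:6) {
    g <- optimize_tls_matrices(g, target, w, pos, cfg)
  }
  rmsd <- sqrt(mean(u_norm2(group_uijs(g, pos) - target) / 3))
  expect_lt(rmsd, 1e-3)
})

test_that("zero-amplitude groups and single-atom isotropic targets", {
  pos <- matrix(c(0, 0, 0), 1)
  g0 <- tls_group(1, tls_matrices(T = c(1, 1, 1, 0, 0, 0)), amplitude = 0)
  out <- optimize_tls_matrices(g0, matrix(0, 1, 6), 1, pos, echt_config())
  expect_identical(out$matrices$T, g0$matrices$T)  # flat objective: unchanged

  # one atom: zero lever arm, so a T-only solution attains the optimum
  tgt <- matrix(anisou(0.2, 0.2, 0.2), 1)
  g1 <- tls_group(1, tls_matrices(T = c(1, 1, 1, 0, 0, 0)), amplitude = 0.2)
  g1 <- optimize_tls_matrices(g1, tgt, 1, pos, echt_config())
  resid <- adp_residual(tgt, group_uijs(g1, pos), 1)
  expect_lt(resid, 1e-8)
})

test_that("fits are deterministic and respect invariants on a short run", {
  fx <- chain_fixture()
  f1 <- fit_echt(fx$atoms, fx$scheme, fast_config())
  f2 <- fit_echt(fx$atoms, fx$scheme, fast_config())
  expect_identical(f1$trace, f2$trace)
  check_fit_invariants(f1)
  expect_false(f1$converged)  # 8 macrocycles is below the stable window
})

test_that("atomic level absorbs any PSD residual under an RMSD cutoff", {
  pep <- peptide_no_gap(3)
  sch <- build_default_scheme(pep, levels = "chain")
  gt <- make_ground_truth(pep, sch,
                          spec = list(list(level = "chain", group = 1,
                                           mean_b = 6)),
                          noise_b = 2, seed = 9)
  # strict stability cutoff so the RMSD criterion is what terminates
  cfg <- echt_config(rmsd_cutoff = 5e-3, db_cutoff = 0.01,
                     max_macrocycles = 45)
  fit <- fit_echt(gt$atoms, sch, cfg)
  expect_true(fit$converged)
  expect_lte(fit$rmsd, 5e-3)
})

test_that("model complexity sums amplitudes over groups and atoms", {
  fx <- chain_fixture()
  fit <- fit_echt(fx$atoms, fx$scheme, fast_config())
  amps <- c(vapply(fit$scheme$levels[[1]]$groups, `[[`, 0, "amplitude"),
            vapply(fit$scheme$levels[[2]]$groups, `[[`, 0, "amplitude"),
            fit$atomic$amp)
  cx <- model_complexity(fit)
  expect_equal(cx$sum_amplitudes, sum(amps))
  expect_equal(cx$per_atom, sum(amps) / nrow(fx$atoms))
})

test_that("isotropic-mode residual ignores anisotropy of the model", {
  # two TLS candidates with equal per-atom traces fit i-ADPs equally well
  u_in <- matrix(b_to_u(20), 1)
  cand1 <- matrix(anisou(0.1, 0.1, 0.1), 1)
  cand2 <- matrix(anisou(0.3, 0, 0), 1)
  expect_equal(adp_residual(u_in, cand1, 1, iso = TRUE),
               adp_residual(u_in, cand2, 1, iso = TRUE))
})
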