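# TLS closed form, validity screen, and group normalization.

test_that("tls_uij reduces to T without libration or lever arm", {
  Tv <- anisou(0.02, 0.03, 0.01, 0.004, 0, -0.002)
  m <- tls_matrices(T = Tv, origin = c(1, 2, 3))
  expect_equal(tls_uij(m, c(10, -5, 2)), Tv)
  m2 <- tls_matrices(T = Tv, L = anisou(0.01, 0.02, 0.005),
                     S = c(1e-3, 0, 0, 0, -1e-3, 0, 0, 0),
                     origin = c(1, 2, 3))
  # at the origin the lever arm is zero
  expect_equal(tls_uij(m2, c(1, 2, 3)), Tv)
})

test_that("pure libration gives u22 = l * d^2 for an atom offset along z", {
  l <- 0.004; d <- 5
  m <- tls_matrices(L = anisou(l, 0, 0))
  u <- tls_uij(m, c(0, 0, d))
  expect_equal(u, anisou(0, l * d^2, 0))
})

test_that("T-only models are origin-invariant", {
  Tv <- anisou(0.02, 0.03, 0.01, 0.004, 0, -0.002)
  pos <- matrix(rnorm(15, 0, 5), 5)
  u1 <- tls_uij(tls_matrices(T = Tv, origin = c(0, 0, 0)), pos)
  u2 <- tls_uij(tls_matrices(T = Tv, origin = c(7, -3, 1)), pos)
  expect_equal(u1, u2)
})

test_that("Monte-Carlo ensemble covariance matches the closed form", {
  # scaled-down version of the acceptance oracle: 3 random sets, 3e4 samples
  for (seed in 1:3) {
    m <- random_valid_tls(seed)
    pos <- matrix(rnorm(9, 0, 3), 3)
    exact <- tls_uij(m, pos)
    emp <- sample_rigid_ensemble(m, pos, 3e4, seed = seed + 100)
    scale <- pmax(abs(exact), u_trace(exact) / 3 / 2)
    expect_lt(max(abs(emp - exact) / scale), 0.10)
  }
})

test_that("validate_tls accepts physical and rejects unphysical sets", {
  expect_true(validate_tls(tls_matrices()))  # all-zero
  expect_false(validate_tls(tls_matrices(T = anisou(-1, 0, 0))))
  expect_true(validate_tls(tls_matrices(T = anisou(1, 1, 1),
                                        L = anisou(0.01, 0.01, 0.01))))
  # screw coupling along a non-librating axis is rejected
  expect_false(validate_tls(tls_matrices(T = anisou(1, 1, 1),
                                         L = anisou(0, 0, 0),
                                         S = c(0.1, 0, 0, 0, -0.1, 0, 0, 0))))
  # conditional translation covariance must stay PSD
  expect_false(validate_tls(tls_matrices(T = anisou(1e-6, 1e-6, 1e-6),
                                         L = anisou(0.01, 0.01, 0.01),
                                         S = c(0.1, 0, 0, 0, 0.1, 0, 0, 0))))
})

test_that("normalize_group scales matrices and amplitude inversely", {
  pos <- matrix(c(0, 0, 0), 1)
  g <- tls_group(1, tls_matrices(T = anisou(2, 2, 2)), amplitude = 1)
  gn <- normalize_group(g, pos)
  expect_equal(gn$matrices$T, anisou(1, 1, 1))
  expect_equal(gn$amplitude, 2)
  # idempotence
  gn2 <- normalize_group(gn, pos)
  expect_equal(gn2$matrices$T, gn$matrices$T)
  expect_equal(gn2$amplitude, gn$amplitude)
  # per-atom products unchanged by normalization
  m <- random_valid_tls(5)
  pos5 <- matrix(rnorm(15, 0, 4), 5)
  g3 <- tls_group(1:5, m, amplitude = 0.7)
  before <- group_uijs(g3, pos5)
  g3n <- normalize_group(g3, pos5)
  expect_equal(group_uijs(g3n, pos5), before, tolerance = 1e-12)
  u <- tls_uij(g3n$matrices, pos5)
  expect_equal(mean(u_trace(u) / 3), 1, tolerance = 1e-9)
})

test_that("group with two atoms whose mean trace is already 1 is unchanged", {
  # atom 1 at the origin sees only T (trace/3 = 0.5); atom 2 is placed so the
  # libration adds exactly 1.0 to its trace/3 (trace of the libration term
  # for an offset d along z under L = l*I is 2*l*d^2), giving a mean of 1
  l <- 0.004
  pos <- rbind(c(0, 0, 0), c(0, 0, sqrt(3 / (2 * l))))
  m <- tls_matrices(T = anisou(0.5, 0.5, 0.5), L = anisou(l, l, l))
  u <- tls_uij(m, pos)
  expect_equal(mean(u_trace(u) / 3), 1, tolerance = 1e-12)
  g <- tls_group(1:2, m, amplitude = 1)
  gn <- normalize_group(g, pos)
  expect_equal(gn$amplitude, 1, tolerance = 1e-12)
  expect_equal(gn$matrices$T, m$T, tolerance = 1e-12)
  expect_equal(gn$matrices$L, m$L, tolerance = 1e-12)
})

test_that("group_uijs is linear in the amplitude and errors without coords", {
  m <- random_valid_tls(9)
  pos <- matrix(rnorm(12, 0, 3), 4)
  g1 <- tls_group(1:4, m, amplitude = 1)
  g2 <- tls_group(1:4, m, amplitude = 2)
  expect_equal(group_uijs(g2, pos), 2 * group_uijs(g1, pos))
  g0 <- tls_group(1:4, m, amplitude = 0)
  expect_true(all(group_uijs(g0, pos) == 0))
  g_bad <- tls_group(1:5, m, amplitude = 1)
  expect_error(group_uijs(g_bad, pos), "without coordinates")
})

test_that("normalized single-atom unit-amplitude group has mean B = 8 pi^2", {
  pos <- matrix(c(1, 1, 1), 1)
  g <- tls_group(1, tls_matrices(T = anisou(0.3, 0.2, 0.4), origin = c(1, 1, 1)),
                 amplitude = 1)
  gn <- normalize_group(g, pos)
  expect_equal(mean(u_to_b(group_uijs(gn, pos))), 8 * pi^2 * gn$amplitude)
})

test_that("TLS groups round-trip through the JSON sidecar", {
  g <- tls_group(3:7, random_valid_tls(11), amplitude = 0.25, name = "dom1")
  back <- tls_from_json(tls_to_json(list(g)))[[1]]
  expect_equal(back$selection, g$selection)
  expect_equal(back$amplitude, g$amplitude)
  expect_equal(back$matrices$T, g$matrices$T)
  expect_equal(back$matrices$L, g$matrices$L)
  expect_equal(back$matrices$S, g$matrices$S)
  expect_equal(back$matrices$origin, g$matrices$origin)
  expect_equal(back$name, "dom1")
})
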