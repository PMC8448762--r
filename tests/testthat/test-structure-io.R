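# PDB/mmCIF reading and writing, level-structure output, summary report.

make_adp_atoms <- function(n = 5, aniso = TRUE) {
  pep <- peptide_no_gap(4)
  sch <- build_default_scheme(pep, levels = "chain")
  gt <- make_ground_truth(pep, sch,
                          spec = list(list(level = "chain", group = 1,
                                           mean_b = 12,
                                           L = anisou(0.002, 0.001, 0.003))),
                          isotropic_output = !aniso)
  gt$atoms
}

test_that("ANISOU scaling: integer 10000 is 1 A^2", {
  a <- atom_table(1)
  a$serial <- 1L; a$chain <- "A"; a$resseq <- 1L; a$resname <- "SER"
  a$atom <- "CA"; a$element <- "C"
  a[hiertls:::U_COLS] <- anisou(1, 1, 1)
  a$b <- u_to_b(anisou(1, 1, 1))
  f <- tempfile(fileext = ".pdb")
  write_pdb(a, f)
  line <- grep("^ANISOU", readLines(f), value = TRUE)
  expect_match(line, "10000\\s+10000\\s+10000")
  back <- read_structure(f)
  expect_equal(as.numeric(back[1, hiertls:::U_COLS]), anisou(1, 1, 1))
})

test_that("isotropic atom with B = 8 pi^2 reads back as u_iso = 1", {
  a <- atom_table(1)
  a$serial <- 1L; a$chain <- "A"; a$resseq <- 1L; a$resname <- "SER"
  a$atom <- "CA"; a$element <- "C"
  a$b <- 78.96  # B column has 2 decimals; ~ 8 pi^2
  f <- tempfile(fileext = ".pdb")
  write_pdb(a, f)
  back <- read_structure(f)
  expect_false(atom_is_aniso(back))
  expect_equal(atom_uijs(back)[1, 1], 1, tolerance = 1e-3)
})

test_that("PDB and mmCIF round-trip within format quantization", {
  atoms <- make_adp_atoms()
  fp <- tempfile(fileext = ".pdb")
  write_pdb(atoms, fp)
  back <- read_structure(fp)
  expect_equal(nrow(back), nrow(atoms))
  expect_lt(max(abs(as.matrix(back[hiertls:::U_COLS]) -
                    as.matrix(atoms[hiertls:::U_COLS]))), 5e-5 + 1e-12)
  expect_equal(back$resseq, atoms$resseq)
  expect_equal(back$atom, atoms$atom)
  # write-read-write idempotence
  fp2 <- tempfile(fileext = ".pdb")
  write_pdb(back, fp2)
  back2 <- read_structure(fp2)
  expect_identical(as.matrix(back2[hiertls:::U_COLS]),
                   as.matrix(back[hiertls:::U_COLS]))

  fc <- tempfile(fileext = ".cif")
  write_cif(atoms, fc)
  backc <- read_structure(fc)
  expect_lt(max(abs(as.matrix(backc[hiertls:::U_COLS]) -
                    as.matrix(atoms[hiertls:::U_COLS]))), 5e-6 + 1e-12)
  fc2 <- tempfile(fileext = ".cif")
  write_cif(backc, fc2)
  expect_identical(as.matrix(read_structure(fc2)[hiertls:::U_COLS]),
                   as.matrix(backc[hiertls:::U_COLS]))
})

test_that("a structure with no ADPs at all is a hard error", {
  a <- atom_table(1)
  a$serial <- 1L; a$chain <- "A"; a$resseq <- 1L; a$resname <- "SER"
  a$atom <- "CA"; a$element <- "C"; a$b <- 0
  f <- tempfile(fileext = ".pdb")
  write_pdb(a, f)
  expect_error(read_structure(f), "no ADPs")
})

test_that("inconsistent B column vs anisotropic trace warns, not fails", {
  atoms <- make_adp_atoms()
  atoms$b[1] <- atoms$b[1] + 5
  f <- tempfile(fileext = ".pdb")
  write_pdb(atoms, f)
  expect_warning(read_structure(f), "inconsistent")
})

test_that("REMARK 3 TLS contributions can be included or excluded", {
  pep <- peptide_no_gap(4)
  pep$b <- 5  # residual isotropic ADPs
  g <- tls_group(seq_len(nrow(pep)),
                 tls_matrices(T = anisou(0.02, 0.02, 0.02),
                              L = anisou(0.001, 0.002, 0.001),
                              origin = colMeans(atom_positions(pep))),
                 amplitude = 1)
  attr(g, "selection_string") <- "CHAIN A AND RESID 1:4"
  f <- tempfile(fileext = ".pdb")
  write_pdb(pep, f, tls_groups = list(g))

  excl <- read_structure(f, tls_handling = "exclude")
  expect_false(any(atom_is_aniso(excl)))
  expect_equal(excl$b, rep(5, nrow(pep)))

  incl <- read_structure(f, tls_handling = "include", quiet = TRUE)
  expect_true(all(atom_is_aniso(incl)))
  want <- tls_uij(g$matrices, atom_positions(pep)) +
    u_as_rows(b_to_u(rep(5, nrow(pep))))
  got <- as.matrix(incl[hiertls:::U_COLS])
  dimnames(got) <- NULL
  # REMARK 3 stores 4 decimals in deg-based units
  expect_lt(max(abs(got - want)), 5e-4)
})

test_that("level structures are additive and readable back", {
  fx <- chain_fixture(n = 4)
  fit <- fit_echt(fx$atoms, fx$scheme, fast_config())
  outdir <- file.path(tempdir(), "lvl_out")
  files <- write_level_structures(fit, outdir)
  expect_true(any(grepl("level_00_chain\\.pdb$", files)))
  expect_true(any(grepl("total\\.pdb$", files)))
  lv_files <- sort(grep("level_.*\\.pdb$", files, value = TRUE))
  b_sum <- 0
  for (f in lv_files) b_sum <- b_sum + read_structure(f, quiet = TRUE)$b
  total <- read_structure(file.path(outdir, "total.pdb"), quiet = TRUE)
  expect_lt(max(abs(b_sum - total$b)), 0.01 * length(lv_files) + 1e-9)
  # tensors round-trip within ANISOU quantization
  mu <- model_uijs(fit)
  got <- as.matrix(read_structure(
    grep("level_00_chain\\.pdb$", files, value = TRUE))[hiertls:::U_COLS])
  dimnames(got) <- NULL
  expect_lt(max(abs(got - mu$levels[["chain"]])), 5e-5 + 1e-12)
})

test_that("summary percentages sum to 100 and empty trace errors", {
  fx <- chain_fixture(n = 4)
  fit <- fit_echt(fx$atoms, fx$scheme, fast_config())
  s <- level_summary(fit)
  expect_equal(sum(s$percent), 100, tolerance = 0.1)
  outdir <- file.path(tempdir(), "sum_out")
  files <- write_summary(fit, outdir)
  js <- jsonlite::fromJSON(files[1])
  expect_equal(length(js$levels$level), 3)
  expect_true(file.exists(files[2]))
  tr <- utils::read.csv(files[2])
  expect_true(all(c("macrocycle", "level", "mean_b", "omega_alpha") %in%
                  names(tr)))
  broken <- fit
  broken$trace <- broken$trace[0, ]
  expect_error(write_summary(broken, outdir), "empty")
})

test_that("reading a structure without ANISOU errors only when B is absent", {
  atoms <- make_adp_atoms(aniso = FALSE)
  f <- tempfile(fileext = ".pdb")
  write_pdb(atoms, f)
  back <- read_structure(f)
  expect_false(any(atom_is_aniso(back)))
  expect_equal(back$b, round(atoms$b, 2))
})
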