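# Synthetic fixtures: idealized peptides, forward-generated ground-truth
# disorder, and a rigid-body ensemble sampler that serves as a Monte-Carlo
# oracle for the closed-form TLS -> U relation.

# Place atom D bonded to C, given reference atoms A-B-C, bond length r (C-D),
# bond angle theta (B-C-D, degrees) and torsion phi (A-B-C-D, degrees).
place_atom <- function(a, b, c, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- phi * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Sidechain templates: heavy atoms beyond N/CA/C/O, each placed by NeRF from
# three previously placed atoms of the same residue. Geometry is idealized,
# not rotamer-accurate.
sidechain_templates <- list(
  GLY = list(),
  ALA = list(CB = list(refs = c("C", "N", "CA"), r = 1.521, ang = 110.4, tors = 122.5)),
  PRO = list(CB = list(refs = c("C", "N", "CA"), r = 1.521, ang = 103.0, tors = 115.0),
             CG = list(refs = c("N", "CA", "CB"), r = 1.495, ang = 104.5, tors = 30.0),
             CD = list(refs = c("CA", "CB", "CG"), r = 1.507, ang = 105.5, tors = -35.0)),
  SER = list(CB = list(refs = c("C", "N", "CA"), r = 1.521, ang = 110.4, tors = 122.5),
             OG = list(refs = c("N", "CA", "CB"), r = 1.417, ang = 110.8, tors = 180)),
  THR = list(CB = list(refs = c("C", "N", "CA"), r = 1.529, ang = 110.4, tors = 122.5),
             OG1 = list(refs = c("N", "CA", "CB"), r = 1.433, ang = 109.6, tors = 180),
             CG2 = list(refs = c("N", "CA", "CB"), r = 1.521, ang = 110.5, tors = -60)),
  VAL = list(CB = list(refs = c("C", "N", "CA"), r = 1.540, ang = 110.4, tors = 122.5),
             CG1 = list(refs = c("N", "CA", "CB"), r = 1.521, ang = 110.5, tors = 180),
             CG2 = list(refs = c("N", "CA", "CB"), r = 1.521, ang = 110.5, tors = -60)),
  LEU = list(CB = list(refs = c("C", "N", "CA"), r = 1.530, ang = 110.4, tors = 122.5),
             CG = list(refs = c("N", "CA", "CB"), r = 1.530, ang = 116.3, tors = 180),
             CD1 = list(refs = c("CA", "CB", "CG"), r = 1.521, ang = 110.7, tors = 60),
             CD2 = list(refs = c("CA", "CB", "CG"), r = 1.521, ang = 110.7, tors = 180)),
  ASP = list(CB = list(refs = c("C", "N", "CA"), r = 1.530, ang = 110.4, tors = 122.5),
             CG = list(refs = c("N", "CA", "CB"), r = 1.516, ang = 112.6, tors = 180),
             OD1 = list(refs = c("CA", "CB", "CG"), r = 1.249, ang = 118.4, tors = 0),
             OD2 = list(refs = c("CA", "CB", "CG"), r = 1.249, ang = 118.4, tors = 180)),
  ASN = list(CB = list(refs = c("C", "N", "CA"), r = 1.530, ang = 110.4, tors = 122.5),
             CG = list(refs = c("N", "CA", "CB"), r = 1.516, ang = 112.6, tors = 180),
             OD1 = list(refs = c("CA", "CB", "CG"), r = 1.231, ang = 120.8, tors = 0),
             ND2 = list(refs = c("CA", "CB", "CG"), r = 1.328, ang = 116.4, tors = 180))
)

element_of <- function(name) substr(gsub("[0-9]", "", name), 1, 1)

#' Build an idealized peptide structure
#'
#' Generates a polymer with standard backbone bond geometry from fixed
#' (phi, psi) torsions, plus C-beta and small idealized sidechains. Residue
#' names are drawn deterministically (given the seed) from a pool that
#' includes Gly/Ala/Pro as well as residues with sidechains, unless an
#' explicit sequence is supplied. Coordinates carry zero disorder; use
#' \code{\link{make_ground_truth}} to add ADPs.
#'
#' @param n_residues residues per chain (>= 1)
#' @param n_chains number of chains (IDs A, B, ...)
#' @param sequence optional character vector of three-letter residue names,
#'   recycled per chain
#' @param conformation "extended" (phi = -140, psi = 135) or "helix"
#'   (phi = -57, psi = -47); may be a vector recycled over residues to build
#'   mixed helix/loop geometries
#' @param seed RNG seed for the residue-name draw
#' @return atom table
#' @export
make_peptide <- function(n_residues, n_chains = 1, sequence = NULL,
                         conformation = c("extended", "helix"), seed = 1) {
  stopifnot(n_residues >= 1, n_chains >= 1)
  conformation <- rep_len(conformation, n_residues)
  if (!all(conformation %in% c("extended", "helix"))) {
    stop("conformation must be 'extended' or 'helix'")
  }
  tors_tab <- cbind(phi = ifelse(conformation == "helix", -57, -140),
                    psi = ifelse(conformation == "helix", -47, 135))
  if (is.null(sequence)) {
    pool <- names(sidechain_templates)
    sequence <- withr_seed(seed, sample(pool, n_residues, replace = TRUE))
  }
  sequence <- rep_len(toupper(sequence), n_residues)
  unknown <- setdiff(sequence, names(sidechain_templates))
  if (length(unknown)) stop("no template for residue(s): ",
                            paste(unknown, collapse = ", "))

  rows <- list()
  for (ci in seq_len(n_chains)) {
    chain_id <- LETTERS[ci]
    offset <- c(0, 25 * (ci - 1), 0)
    prev <- NULL
    for (ri in seq_len(n_residues)) {
      resname <- sequence[ri]
      crd <- list()
      if (is.null(prev)) {
        crd$N <- c(0, 0, 0)
        crd$CA <- c(1.458, 0, 0)
        ang <- 111.2 * pi / 180
        crd$C <- crd$CA + 1.525 * c(-cos(ang), sin(ang), 0)
      } else {
        crd$N <- place_atom(prev$N, prev$CA, prev$C, 1.329, 116.2,
                            tors_tab[ri - 1, "psi"])
        crd$CA <- place_atom(prev$CA, prev$C, crd$N, 1.458, 121.7, 180)
        crd$C <- place_atom(prev$C, crd$N, crd$CA, 1.525, 111.2,
                            tors_tab[ri, "phi"])
      }
      # carbonyl O anti to the next N direction
      crd$O <- place_atom(crd$N, crd$CA, crd$C, 1.231, 120.5,
                          tors_tab[ri, "psi"] + 180)
      for (nm in names(sidechain_templates[[resname]])) {
        tpl <- sidechain_templates[[resname]][[nm]]
        crd[[nm]] <- place_atom(crd[[tpl$refs[1]]], crd[[tpl$refs[2]]],
                                crd[[tpl$refs[3]]], tpl$r, tpl$ang, tpl$tors)
      }
      for (nm in names(crd)) {
        rows[[length(rows) + 1L]] <- list(chain = chain_id, resseq = ri,
                                          resname = resname, atom = nm,
                                          xyz = crd[[nm]] + offset)
      }
      prev <- crd[c("N", "CA", "C")]
    }
  }

  atoms <- atom_table(length(rows))
  atoms$serial <- seq_along(rows)
  atoms$chain <- vapply(rows, `[[`, "", "chain")
  atoms$resseq <- vapply(rows, `[[`, 0L, "resseq")
  atoms$resname <- vapply(rows, `[[`, "", "resname")
  atoms$atom <- vapply(rows, `[[`, "", "atom")
  atoms$element <- element_of(atoms$atom)
  xyz <- t(vapply(rows, `[[`, numeric(3), "xyz"))
  atoms$x <- round(xyz[, 1], 3)
  atoms$y <- round(xyz[, 2], 3)
  atoms$z <- round(xyz[, 3], 3)
  atoms
}

# Evaluate expr with a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Forward-generate ground-truth hierarchical disorder
#'
#' Assigns TLS contributions to chosen groups of a level scheme, sums them
#' per atom (plus optional truncated-Gaussian isotropic noise), and writes
#' the result into the atom table's ADP columns. Every output tensor is
#' positive semi-definite by construction (sum of valid TLS contributions and
#' non-negative isotropic noise).
#'
#' @param atoms atom table (coordinates only)
#' @param scheme \code{level_scheme} for the atoms
#' @param spec list of entries; each entry is a list with elements
#'   \code{level} (level name), \code{group} (group index within the level;
#'   NULL = all groups), \code{mean_b} (group-mean equivalent B, A^2), and
#'   optional \code{T}, \code{L}, \code{S} shape matrices (defaults:
#'   isotropic T = diag(1), zero L/S)
#' @param noise_b sd (A^2) of per-atom isotropic B noise, Gaussian truncated
#'   at zero; 0 = noise-free
#' @param seed RNG seed for the noise draw
#' @param isotropic_output if TRUE only the isotropic B column is populated
#'   (anisotropic tensors withheld), emulating an i-ADP refinement
#' @return list with \code{atoms} (ADPs filled in), \code{truth} (per-level
#'   n x 6 contribution matrices, per-group amplitudes, noise draw)
#' @export
make_ground_truth <- function(atoms, scheme, spec, noise_b = 0, seed = 1,
                              isotropic_output = FALSE) {
  pos <- atom_positions(atoms)
  n <- nrow(atoms)
  level_names <- vapply(scheme$levels, `[[`, "", "name")
  contrib <- lapply(level_names, function(nm) matrix(0, n, 6))
  names(contrib) <- level_names
  amps <- list()

  for (entry in spec) {
    li <- match(entry$level, level_names)
    if (is.na(li)) stop("ground-truth spec references unknown level: ",
                        entry$level)
    level <- scheme$levels[[li]]
    if (level$kind == "atomic") stop("assign atomic disorder via noise_b")
    gidx <- if (is.null(entry$group)) seq_along(level$groups) else entry$group
    if (any(gidx > length(level$groups))) {
      stop("ground-truth spec references unknown group in level ", entry$level)
    }
    for (gi in gidx) {
      g <- level$groups[[gi]]
      sel <- g$selection
      m <- tls_matrices(T = entry$T %||% c(1, 1, 1, 0, 0, 0),
                        L = entry$L %||% rep(0, 6),
                        S = entry$S %||% rep(0, 8),
                        origin = colMeans(pos[sel, , drop = FALSE]))
      if (!validate_tls(m)) stop("ground-truth spec TLS matrices are invalid")
      g$matrices <- m
      g$amplitude <- 1
      g <- normalize_group(g, pos)
      g$amplitude <- entry$mean_b / B_FROM_U
      contrib[[li]][sel, ] <- contrib[[li]][sel, ] + group_uijs(g, pos)
      amps[[length(amps) + 1L]] <- list(level = entry$level, group = gi,
                                        amplitude = g$amplitude)
    }
  }

  noise <- if (noise_b > 0) {
    pmax(0, withr_seed(seed, stats::rnorm(n, 0, noise_b)))
  } else {
    numeric(n)
  }
  total <- Reduce(`+`, contrib)
  if (any(noise > 0)) total <- total + u_as_rows(b_to_u(noise))

  atoms$b <- u_to_b(total)
  if (isotropic_output) {
    atoms[U_COLS] <- NA_real_
  } else {
    atoms[U_COLS] <- total
  }
  list(atoms = atoms,
       truth = list(levels = contrib, amplitudes = amps, noise_b = noise,
                    total = total))
}

#' Sample a rigid-body ensemble implied by TLS matrices
#'
#' Monte-Carlo oracle for \code{\link{tls_uij}}: draws (rotation, translation)
#' pairs from the joint Gaussian with blocks L, T and cross-covariance S,
#' applies the linearized displacement \code{delta = t + theta x (r - origin)}
#' to each atom, and returns empirical per-atom displacement covariances.
#' Intended for the small-angle regime (|L| <= ~0.01 rad^2).
#'
#' @param m \code{tls_matrices} (must pass \code{\link{validate_tls}})
#' @param positions n x 3 matrix of atom positions
#' @param n_samples number of ensemble members
#' @param seed RNG seed
#' @return n x 6 matrix of empirical covariance tensors
#' @export
sample_rigid_ensemble <- function(m, positions, n_samples, seed = 1) {
  stopifnot(n_samples >= 1)
  pos <- u_as_rows3(positions)
  Lm <- u_as_mat(m$L); Tm <- u_as_mat(m$T); Sm <- s_as_mat(m$S)
  Lp <- sym_pinv(Lm)
  cond <- Tm - t(Sm) %*% Lp %*% Sm
  cond <- (cond + t(cond)) / 2

  sqrt_sym <- function(mm) {
    e <- eigen(mm, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    e$vectors %*% (t(e$vectors) * sqrt(lam))
  }
  Lhalf <- sqrt_sym(Lm)
  Chalf <- sqrt_sym(cond)

  draws <- withr_seed(seed, {
    z1 <- matrix(stats::rnorm(3 * n_samples), n_samples, 3)
    z2 <- matrix(stats::rnorm(3 * n_samples), n_samples, 3)
    list(z1 = z1, z2 = z2)
  })
  theta <- draws$z1 %*% t(Lhalf)                       # n_samples x 3
  tvec <- theta %*% Lp %*% Sm + draws$z2 %*% t(Chalf)  # E[t|theta] + noise

  n_atoms <- nrow(pos)
  out <- matrix(0, n_atoms, 6)
  for (a in seq_len(n_atoms)) {
    d <- pos[a, ] - m$origin
    dx <- tvec[, 1] + theta[, 2] * d[3] - theta[, 3] * d[2]
    dy <- tvec[, 2] + theta[, 3] * d[1] - theta[, 1] * d[3]
    dz <- tvec[, 3] + theta[, 1] * d[2] - theta[, 2] * d[1]
    out[a, ] <- c(sum(dx * dx), sum(dy * dy), sum(dz * dz),
                  sum(dx * dy), sum(dx * dz), sum(dy * dz)) / n_samples
  }
  out
}

u_as_rows3 <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
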