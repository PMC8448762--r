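# Atom records are held in a plain data.frame with one row per atom:
#   serial, chain, resseq (integer, author numbering), icode, resname, atom,
#   element, x, y, z, occ, b (A^2), u11..u23 (A^2, NA when only an isotropic
#   B is known), het (HETATM flag), is_polymer.
# All disorder arithmetic works on the n x 6 U representation; b is kept
# consistent as the equivalent isotropic view.

U_COLS <- c("u11", "u22", "u33", "u12", "u13", "u23")

#' Create an empty atom table
#' @param n number of rows
#' @return data.frame with the package's atom-record columns
#' @export
atom_table <- function(n = 0) {
  df <- data.frame(serial = integer(n), chain = character(n),
                   resseq = integer(n), icode = character(n),
                   resname = character(n), atom = character(n),
                   element = character(n),
                   x = numeric(n), y = numeric(n), z = numeric(n),
                   occ = numeric(n), b = numeric(n),
                   u11 = numeric(n), u22 = numeric(n), u33 = numeric(n),
                   u12 = numeric(n), u13 = numeric(n), u23 = numeric(n),
                   het = logical(n), is_polymer = logical(n),
                   stringsAsFactors = FALSE)
  if (n > 0) {
    df$icode <- ""
    df$occ <- 1
    df[U_COLS] <- NA_real_
    df$is_polymer <- TRUE
  }
  df
}

#' Atom coordinates as an n x 3 matrix
#' @param atoms atom table
#' @export
atom_positions <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

#' Which atoms carry anisotropic ADPs?
#' @param atoms atom table
#' @export
atom_is_aniso <- function(atoms) {
  !is.na(atoms$u11)
}

#' Per-atom input ADPs as an n x 6 matrix
#'
#' Anisotropic tensors are used where present; isotropic atoms are embedded
#' as diag(b / 8pi^2).
#' @param atoms atom table
#' @export
atom_uijs <- function(atoms) {
  u <- as.matrix(atoms[U_COLS])
  dimnames(u) <- NULL
  iso <- !atom_is_aniso(atoms)
  if (any(iso)) u[iso, ] <- u_as_rows(b_to_u(atoms$b[iso]))
  u
}

# Residue-level key, unique within the structure (chain / seq / icode).
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resseq, atoms$icode, sep = "|")
}

# Drop hydrogens and keep the highest-occupancy altloc conformer. The reader
# tags altlocs before calling this; synthetic structures have none.
standardize_atoms <- function(atoms, altloc = NULL, quiet = FALSE) {
  h <- atoms$element %in% c("H", "D")
  if (any(h)) atoms <- atoms[!h, , drop = FALSE]
  if (!is.null(altloc) && any(nzchar(altloc))) {
    altloc <- altloc[!h]
    key <- paste(residue_key(atoms), atoms$atom)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
      if (length(idx) == 1L) return(idx)
      idx[which.max(atoms$occ[idx])]
    }), use.names = FALSE)
    keep <- sort(keep)
    if (!quiet && length(keep) < nrow(atoms)) {
      message("kept highest-occupancy conformer for ",
              nrow(atoms) - length(keep), " alternate-location atom(s)")
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  rownames(atoms) <- NULL
  atoms
}
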