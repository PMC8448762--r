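# PDB format I/O: ATOM/HETATM/ANISOU records, plus a REFMAC-style REMARK 3
# TLS block. ANISOU stores U * 1e4 as integers; REMARK 3 L tensors are in
# deg^2 and S in A*deg (converted to the radian-native internal units).

DEG2 <- (pi / 180)^2
DEG1 <- pi / 180

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "MSE", "PHE", "PRO", "SER", "THR",
            "TRP", "TYR", "VAL")

num_or_na <- function(s) {
  s <- trimws(s)
  ifelse(nzchar(s), suppressWarnings(as.numeric(s)), NA_real_)
}

parse_pdb_atom_line <- function(line) {
  list(record = trimws(substr(line, 1, 6)),
       serial = as.integer(num_or_na(substr(line, 7, 11))),
       atom = trimws(substr(line, 13, 16)),
       altloc = trimws(substr(line, 17, 17)),
       resname = trimws(substr(line, 18, 20)),
       chain = trimws(substr(line, 22, 22)),
       resseq = as.integer(num_or_na(substr(line, 23, 26))),
       icode = trimws(substr(line, 27, 27)),
       x = num_or_na(substr(line, 31, 38)),
       y = num_or_na(substr(line, 39, 46)),
       z = num_or_na(substr(line, 47, 54)),
       occ = num_or_na(substr(line, 55, 60)),
       b = num_or_na(substr(line, 61, 66)),
       element = trimws(substr(line, 77, 78)))
}

read_pdb_atoms <- function(lines) {
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  recs <- lapply(lines[is_atom], parse_pdb_atom_line)
  n <- length(recs)
  atoms <- atom_table(n)
  if (n == 0) return(list(atoms = atoms, altloc = character(0)))
  grab <- function(field, proto) vapply(recs, `[[`, proto, field)
  atoms$serial <- grab("serial", 0L)
  atoms$atom <- grab("atom", "")
  atoms$resname <- grab("resname", "")
  atoms$chain <- grab("chain", "")
  atoms$resseq <- grab("resseq", 0L)
  atoms$icode <- grab("icode", "")
  atoms$x <- grab("x", 0); atoms$y <- grab("y", 0); atoms$z <- grab("z", 0)
  atoms$occ <- grab("occ", 0)
  atoms$b <- grab("b", 0)
  el <- grab("element", "")
  atoms$element <- ifelse(nzchar(el), el, element_of(atoms$atom))
  atoms$het <- grab("record", "") == "HETATM"
  atoms$is_polymer <- !atoms$het & atoms$resname %in% AMINO3
  atoms[U_COLS] <- NA_real_

  # ANISOU records are matched to atoms by serial number
  aniso_lines <- lines[startsWith(lines, "ANISOU")]
  for (line in aniso_lines) {
    serial <- as.integer(num_or_na(substr(line, 7, 11)))
    vals <- suppressWarnings(as.integer(c(
      num_or_na(substr(line, 29, 35)), num_or_na(substr(line, 36, 42)),
      num_or_na(substr(line, 43, 49)), num_or_na(substr(line, 50, 56)),
      num_or_na(substr(line, 57, 63)), num_or_na(substr(line, 64, 70)))))
    row <- which(atoms$serial == serial)
    if (!length(row) || anyNA(vals)) {
      warning("skipping unparseable ANISOU record: ", substr(line, 1, 30))
      next
    }
    atoms[row[1], U_COLS] <- vals * 1e-4
  }
  list(atoms = atoms, altloc = grab("altloc", ""))
}

# REMARK 3 TLS block reader (REFMAC layout). Returns a list of groups:
# selection string, origin, and matrices in internal units.
read_pdb_tls <- function(lines) {
  r3 <- lines[startsWith(lines, "REMARK   3")]
  starts <- grep("TLS GROUP *:", r3)
  groups <- list()
  for (k in seq_along(starts)) {
    block <- r3[starts[k]:(if (k < length(starts)) starts[k + 1] - 1
                           else length(r3))]
    sel_line <- grep("SELECTION *:", block, value = TRUE)
    selection <- if (length(sel_line)) {
      trimws(sub(".*SELECTION *:", "", sel_line[1]))
    } else {
      "ALL"
    }
    org_line <- grep("ORIGIN FOR THE GROUP", block, value = TRUE)
    origin <- if (length(org_line)) {
      as.numeric(strsplit(trimws(sub(".*\\(A\\):", "", org_line[1])),
                          "[[:space:]]+")[[1]])[1:3]
    } else {
      c(0, 0, 0)
    }
    get_vals <- function(tags) {
      vapply(tags, function(tag) {
        ln <- grep(paste0(tag, ":"), block, value = TRUE)
        if (!length(ln)) return(0)
        m <- regmatches(ln[1], regexec(paste0(tag, ": *(-?[0-9.eE+-]+)"),
                                       ln[1]))[[1]]
        if (length(m) < 2) 0 else as.numeric(m[2])
      }, 0)
    }
    Tv <- get_vals(c("T11", "T22", "T33", "T12", "T13", "T23"))
    Lv <- get_vals(c("L11", "L22", "L33", "L12", "L13", "L23")) * DEG2
    Sv <- get_vals(c("S11", "S12", "S13", "S21", "S22", "S23",
                     "S31", "S32")) * DEG1
    groups[[length(groups) + 1L]] <-
      list(selection = selection,
           matrices = tls_matrices(T = Tv, L = Lv, S = Sv, origin = origin))
  }
  groups
}

# Resolve a REMARK 3 TLS selection string against the atom table. Supports
# "ALL", "CHAIN A", and "CHAIN A AND RESID 2:10" (RESID/RESSEQ synonyms,
# separators ':' or '-').
tls_selection_indices <- function(selection, atoms) {
  s <- toupper(trimws(selection))
  if (s %in% c("ALL", "")) return(seq_len(nrow(atoms)))
  chain <- sub(".*CHAIN +([A-Za-z0-9]).*", "\\1", s)
  idx <- which(atoms$chain == chain)
  if (grepl("RES(ID|SEQ)", s)) {
    rng <- sub(".*RES(?:ID|SEQ) +\\{?([0-9]+) *[:-] *([0-9]+).*", "\\1 \\2", s)
    nums <- as.integer(strsplit(rng, " ")[[1]])
    if (length(nums) == 2 && !anyNA(nums)) {
      idx <- idx[atoms$resseq[idx] >= nums[1] & atoms$resseq[idx] <= nums[2]]
    }
  }
  idx
}

#' Read a structure with ADPs from PDB or mmCIF
#'
#' Populates the package's atom table. ANISOU / anisotropic items are scaled
#' to A^2; hydrogens are dropped and only the highest-occupancy alternate
#' conformer is kept. When REMARK 3 TLS records are present,
#' \code{tls_handling = "include"} adds the TLS contribution to the atomic
#' ADPs (producing anisotropic totals), while \code{"exclude"} leaves the
#' residual ADPs untouched. A structure with no ADP information at all is an
#' error. Atoms whose anisotropic trace is inconsistent with the B column
#' beyond format rounding produce a warning, not an error.
#'
#' @param path PDB (.pdb/.ent) or mmCIF (.cif) file
#' @param tls_handling "exclude" (default) or "include"
#' @param quiet suppress informational messages
#' @return atom table
#' @export
read_structure <- function(path, tls_handling = c("exclude", "include"),
                           quiet = FALSE) {
  tls_handling <- match.arg(tls_handling)
  if (!file.exists(path)) stop("no such file: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  if (is_cif) {
    parsed <- read_cif_atoms(readLines(path, warn = FALSE))
  } else {
    parsed <- read_pdb_atoms(readLines(path, warn = FALSE))
  }
  atoms <- standardize_atoms(parsed$atoms, parsed$altloc, quiet = quiet)
  if (nrow(atoms) == 0) stop("no atoms found in ", path)
  if (all(atoms$b == 0 | is.na(atoms$b)) && !any(atom_is_aniso(atoms))) {
    stop("structure carries no ADPs (all B-factors zero/absent, no ",
         "anisotropic records)")
  }
  atoms$b[is.na(atoms$b)] <- 0

  aniso <- atom_is_aniso(atoms)
  if (any(aniso)) {
    beq <- u_to_b(as.matrix(atoms[aniso, U_COLS]))
    off <- abs(beq - atoms$b[aniso])
    if (any(off > 0.1)) {
      warning(sum(off > 0.1), " atom(s) have B-factor inconsistent with the ",
              "anisotropic trace beyond format rounding")
    }
  }

  if (!is_cif && tls_handling == "include") {
    tls <- read_pdb_tls(readLines(path, warn = FALSE))
    for (g in tls) {
      idx <- tls_selection_indices(g$selection, atoms)
      if (!length(idx)) next
      contrib <- tls_uij(g$matrices, atom_positions(atoms)[idx, , drop = FALSE])
      base <- atom_uijs(atoms)[idx, , drop = FALSE]
      atoms[idx, U_COLS] <- base + contrib
      atoms$b[idx] <- u_to_b(base + contrib)
    }
    if (length(tls) && !quiet) {
      message("added ", length(tls), " REMARK 3 TLS group contribution(s) ",
              "to the atomic ADPs")
    }
  }
  atoms
}

format_pdb_atom_name <- function(name, element) {
  # element symbols of one character start in column 14
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 1) sprintf("%-4s", paste0(" ", name))
  else sprintf("%-4s", name)
}

#' Write a structure to PDB format
#'
#' Emits ATOM/HETATM records (ANISOU where anisotropic tensors are present),
#' preserving author residue numbering and insertion codes. Optionally
#' prefixes a REMARK 3 TLS block.
#'
#' @param atoms atom table
#' @param path output file
#' @param tls_groups optional list of \code{tls_group} (with a
#'   \code{selection_string} attribute or chain-based selections) written as
#'   REMARK 3
#' @param write_anisou write ANISOU records for anisotropic atoms
#' @export
write_pdb <- function(atoms, path, tls_groups = NULL, write_anisou = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(tls_groups) && length(tls_groups)) {
    writeLines(format_pdb_tls(tls_groups, atoms), con)
  }
  aniso <- atom_is_aniso(atoms)
  for (i in seq_len(nrow(atoms))) {
    rec <- if (atoms$het[i]) "HETATM" else "ATOM  "
    nm <- format_pdb_atom_name(atoms$atom[i], atoms$element[i])
    writeLines(sprintf(
      "%s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, atoms$serial[i] %% 100000, nm, atoms$resname[i], atoms$chain[i],
      atoms$resseq[i], ifelse(nzchar(atoms$icode[i]), atoms$icode[i], " "),
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$occ[i], atoms$b[i],
      sprintf("%2s", atoms$element[i])), con)
    if (write_anisou && aniso[i]) {
      u <- round(as.numeric(atoms[i, U_COLS]) * 1e4)
      writeLines(sprintf(
        "ANISOU%5d %s %3s %1s%4d%1s %7d%7d%7d%7d%7d%7d      %2s",
        atoms$serial[i] %% 100000, nm, atoms$resname[i], atoms$chain[i],
        atoms$resseq[i], ifelse(nzchar(atoms$icode[i]), atoms$icode[i], " "),
        u[1], u[2], u[3], u[4], u[5], u[6],
        sprintf("%2s", atoms$element[i])), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

format_pdb_tls <- function(tls_groups, atoms) {
  out <- c("REMARK   3  TLS DETAILS",
           sprintf("REMARK   3   NUMBER OF TLS GROUPS  : %d",
                   length(tls_groups)))
  for (k in seq_along(tls_groups)) {
    g <- tls_groups[[k]]
    # physical (amplitude-scaled) matrices are written
    A <- g$amplitude
    Tm <- g$matrices$T * A
    Lm <- g$matrices$L * A / DEG2
    Sm <- g$matrices$S * A / DEG1
    sel_str <- attr(g, "selection_string")
    if (is.null(sel_str)) {
      ch <- unique(atoms$chain[g$selection])
      rs <- range(atoms$resseq[g$selection])
      sel_str <- sprintf("CHAIN %s AND RESID %d:%d", ch[1], rs[1], rs[2])
    }
    out <- c(out,
      sprintf("REMARK   3   TLS GROUP : %d", k),
      sprintf("REMARK   3    SELECTION: %s", sel_str),
      sprintf("REMARK   3    ORIGIN FOR THE GROUP (A): %9.4f %9.4f %9.4f",
              g$matrices$origin[1], g$matrices$origin[2],
              g$matrices$origin[3]),
      "REMARK   3    T TENSOR",
      sprintf("REMARK   3      T11: %9.4f T22: %9.4f", Tm[1], Tm[2]),
      sprintf("REMARK   3      T33: %9.4f T12: %9.4f", Tm[3], Tm[4]),
      sprintf("REMARK   3      T13: %9.4f T23: %9.4f", Tm[5], Tm[6]),
      "REMARK   3    L TENSOR",
      sprintf("REMARK   3      L11: %9.4f L22: %9.4f", Lm[1], Lm[2]),
      sprintf("REMARK   3      L33: %9.4f L12: %9.4f", Lm[3], Lm[4]),
      sprintf("REMARK   3      L13: %9.4f L23: %9.4f", Lm[5], Lm[6]),
      "REMARK   3    S TENSOR",
      sprintf("REMARK   3      S11: %9.4f S12: %9.4f S13: %9.4f",
              Sm[1], Sm[2], Sm[3]),
      sprintf("REMARK   3      S21: %9.4f S22: %9.4f S23: %9.4f",
              Sm[4], Sm[5], Sm[6]),
      sprintf("REMARK   3      S31: %9.4f S32: %9.4f", Sm[7], Sm[8]))
  }
  out
}
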