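# Minimal mmCIF I/O: the atom_site and atom_site_anisotrop loops, enough to
# round-trip this package's own output and read standard coordinate files.

cif_tokenize <- function(line) {
  toks <- character(0)
  i <- 1
  nc <- nchar(line)
  while (i <= nc) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1
      while (j <= nc && substr(line, j, j) != ch) j <- j + 1
      toks <- c(toks, substr(line, i + 1, j - 1))
      i <- j + 1
    } else {
      j <- i
      while (j <= nc && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1
      toks <- c(toks, substr(line, i, j - 1))
      i <- j
    }
  }
  toks
}

# Parse all loops in a CIF file; returns a named list of data.frames keyed by
# category (e.g. "_atom_site").
cif_read_loops <- function(lines) {
  lines <- lines[!startsWith(trimws(lines), "#")]
  out <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        tags <- c(tags, trimws(lines[i]))
        i <- i + 1
      }
      vals <- character(0)
      while (i <= n && !startsWith(trimws(lines[i]), "_") &&
             trimws(lines[i]) != "loop_" &&
             !startsWith(trimws(lines[i]), "data_") &&
             nzchar(trimws(lines[i]))) {
        vals <- c(vals, cif_tokenize(lines[i]))
        i <- i + 1
      }
      if (length(tags) && length(vals) %% length(tags) == 0 &&
          length(vals) > 0) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- tags
        cat_name <- sub("\\..*$", "", tags[1])
        out[[cat_name]] <- df
      }
    } else {
      i <- i + 1
    }
  }
  out
}

cif_col <- function(df, tag, default = NA_character_) {
  hit <- which(tolower(names(df)) == tolower(tag))
  if (length(hit)) df[[hit[1]]] else rep(default, nrow(df))
}

read_cif_atoms <- function(lines) {
  loops <- cif_read_loops(lines)
  site <- loops[["_atom_site"]]
  if (is.null(site)) stop("mmCIF file has no atom_site loop")
  n <- nrow(site)
  atoms <- atom_table(n)
  gv <- function(tag, default = NA_character_) cif_col(site, tag, default)
  nav <- function(x) ifelse(x %in% c(".", "?", NA), NA, x)
  atoms$serial <- as.integer(nav(gv("_atom_site.id")))
  atoms$atom <- nav(gv("_atom_site.label_atom_id"))
  atoms$resname <- nav(gv("_atom_site.label_comp_id"))
  auth_ch <- nav(gv("_atom_site.auth_asym_id"))
  atoms$chain <- ifelse(is.na(auth_ch), nav(gv("_atom_site.label_asym_id")),
                        auth_ch)
  auth_seq <- nav(gv("_atom_site.auth_seq_id"))
  lab_seq <- nav(gv("_atom_site.label_seq_id"))
  atoms$resseq <- as.integer(ifelse(is.na(auth_seq), lab_seq, auth_seq))
  ic <- nav(gv("_atom_site.pdbx_PDB_ins_code"))
  atoms$icode <- ifelse(is.na(ic), "", ic)
  atoms$x <- as.numeric(nav(gv("_atom_site.Cartn_x")))
  atoms$y <- as.numeric(nav(gv("_atom_site.Cartn_y")))
  atoms$z <- as.numeric(nav(gv("_atom_site.Cartn_z")))
  occ <- as.numeric(nav(gv("_atom_site.occupancy")))
  atoms$occ <- ifelse(is.na(occ), 1, occ)
  b <- as.numeric(nav(gv("_atom_site.B_iso_or_equiv")))
  atoms$b <- ifelse(is.na(b), 0, b)
  el <- nav(gv("_atom_site.type_symbol"))
  atoms$element <- ifelse(is.na(el), element_of(atoms$atom), toupper(el))
  grp <- nav(gv("_atom_site.group_PDB"))
  atoms$het <- !is.na(grp) & grp == "HETATM"
  atoms$is_polymer <- !atoms$het & atoms$resname %in% AMINO3
  atoms[U_COLS] <- NA_real_
  altloc <- nav(gv("_atom_site.label_alt_id"))
  altloc <- ifelse(is.na(altloc), "", altloc)

  anis <- loops[["_atom_site_anisotrop"]]
  if (!is.null(anis)) {
    ids <- as.integer(cif_col(anis, "_atom_site_anisotrop.id"))
    tagmap <- c("_atom_site_anisotrop.U[1][1]", "_atom_site_anisotrop.U[2][2]",
                "_atom_site_anisotrop.U[3][3]", "_atom_site_anisotrop.U[1][2]",
                "_atom_site_anisotrop.U[1][3]", "_atom_site_anisotrop.U[2][3]")
    uvals <- vapply(tagmap, function(tag) {
      as.numeric(cif_col(anis, tag))
    }, numeric(nrow(anis)))
    if (nrow(anis) == 1) uvals <- matrix(uvals, nrow = 1)
    for (k in seq_along(ids)) {
      row <- which(atoms$serial == ids[k])
      if (length(row)) atoms[row[1], U_COLS] <- uvals[k, ]
    }
  }
  list(atoms = atoms, altloc = altloc)
}

#' Write a structure to mmCIF format
#'
#' Emits atom_site and (for anisotropic atoms) atom_site_anisotrop loops.
#'
#' @param atoms atom table
#' @param path output file
#' @param block data block name
#' @export
write_cif <- function(atoms, path, block = "hiertls") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("data_", block), con)
  writeLines(c("loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.auth_asym_id",
               "_atom_site.label_seq_id", "_atom_site.auth_seq_id",
               "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv"), con)
  writeLines(sprintf(
    "%-6s %d %s %s . %s %s %s %d %d %s %.3f %.3f %.3f %.2f %.4f",
    ifelse(atoms$het, "HETATM", "ATOM"), atoms$serial, atoms$element,
    atoms$atom, atoms$resname, atoms$chain, atoms$chain, atoms$resseq,
    atoms$resseq, ifelse(nzchar(atoms$icode), atoms$icode, "?"),
    atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b), con)
  aniso <- atom_is_aniso(atoms)
  if (any(aniso)) {
    writeLines(c("#", "loop_",
                 "_atom_site_anisotrop.id", "_atom_site_anisotrop.type_symbol",
                 "_atom_site_anisotrop.U[1][1]", "_atom_site_anisotrop.U[2][2]",
                 "_atom_site_anisotrop.U[3][3]", "_atom_site_anisotrop.U[1][2]",
                 "_atom_site_anisotrop.U[1][3]", "_atom_site_anisotrop.U[2][3]"),
               con)
    a <- atoms[aniso, , drop = FALSE]
    writeLines(sprintf("%d %s %.5f %.5f %.5f %.5f %.5f %.5f",
                       a$serial, a$element, a$u11, a$u22, a$u33,
                       a$u12, a$u13, a$u23), con)
  }
  writeLines("#", con)
  invisible(path)
}
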