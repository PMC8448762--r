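# Hierarchical partitioning of a structure into ordered TLS levels.
# Default levels, largest scale first: chain; secondary-structure element;
# residue; backbone/sidechain; atomic. Within a level, group selections are
# pairwise disjoint; an atom may be absent from a level (e.g. Gly/Ala/Pro at
# the backbone/sidechain level) but is always present in the first level and
# in the atomic level.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "CB")
BB_SC_EXCLUDED <- c("GLY", "ALA", "PRO")

#' Construct a level
#' @param name level name
#' @param groups list of \code{tls_group} with pairwise-disjoint selections
#' @param kind "tls" or "atomic"
#' @return object of class \code{echt_level}
#' @export
level <- function(name, groups = list(), kind = c("tls", "atomic")) {
  kind <- match.arg(kind)
  if (kind == "tls") {
    sel <- unlist(lapply(groups, `[[`, "selection"))
    if (anyDuplicated(sel)) {
      dup <- unique(sel[duplicated(sel)])
      stop("level '", name, "': atoms in more than one group: ",
           paste(utils::head(dup, 10), collapse = ", "))
    }
  }
  structure(list(name = name, groups = groups, kind = kind),
            class = "echt_level")
}

#' Construct a level scheme
#'
#' Levels must be ordered largest scale first; an atomic level is appended if
#' missing so it is always last.
#' @param levels list of \code{echt_level}
#' @param atoms atom table the scheme refers to
#' @return object of class \code{level_scheme}
#' @export
level_scheme <- function(levels, atoms) {
  kinds <- vapply(levels, `[[`, "", "kind")
  if (!any(kinds == "atomic")) {
    levels <- c(levels, list(level("atomic", kind = "atomic")))
  } else if (which(kinds == "atomic") != length(levels)) {
    stop("the atomic level must be the last level")
  }
  poly <- which(atoms$is_polymer)
  first_cover <- unlist(lapply(levels[[1]]$groups, `[[`, "selection"))
  if (!all(poly %in% first_cover)) {
    stop("every polymer atom must be covered by the first level")
  }
  structure(list(levels = levels, n_atoms = nrow(atoms)),
            class = "level_scheme")
}

#' @export
print.level_scheme <- function(x, ...) {
  cat("Level scheme (", length(x$levels), " levels, ", x$n_atoms, " atoms)\n",
      sep = "")
  for (i in seq_along(x$levels)) {
    lv <- x$levels[[i]]
    if (lv$kind == "atomic") {
      cat(sprintf("  %2d %-20s per-atom ADPs\n", i, lv$name))
    } else {
      cat(sprintf("  %2d %-20s %d group(s)\n", i, lv$name, length(lv$groups)))
    }
  }
  invisible(x)
}

group_from_indices <- function(idx, name = NULL) {
  tls_group(selection = idx, name = name)
}

#' Build the default level scheme
#'
#' Levels: one group per chain; secondary-structure elements (helix/strand
#' segments from the built-in hydrogen-bond rule, other residues as singleton
#' groups); one group per residue; backbone and sidechain groups per residue
#' (C-beta counted as backbone; Gly/Ala/Pro omitted from this level); atomic.
#' Only polymer atoms enter default levels; non-polymer atoms (waters,
#' ligands) can be included through a custom level configuration.
#'
#' @param atoms atom table
#' @param levels subset of c("chain", "ss", "residue", "backbone_sidechain")
#'   to include, in this fixed order
#' @return \code{level_scheme}
#' @export
build_default_scheme <- function(atoms,
                                 levels = c("chain", "ss", "residue",
                                            "backbone_sidechain")) {
  poly <- which(atoms$is_polymer)
  if (length(poly) == 0L) stop("structure contains no polymer atoms")
  levels <- match.arg(levels, several.ok = TRUE)
  out <- list()

  if ("chain" %in% levels) {
    out <- c(out, list(level("chain", lapply(
      split(poly, atoms$chain[poly]),
      function(idx) group_from_indices(idx,
        name = paste0("chain_", atoms$chain[idx[1]]))))))
  }

  if ("ss" %in% levels) {
    out <- c(out, list(level("ss", ss_level_groups(atoms))))
  }

  if ("residue" %in% levels) {
    keys <- residue_key(atoms)[poly]
    grp <- split(poly, factor(keys, levels = unique(keys)))
    out <- c(out, list(level("residue", unname(lapply(
      names(grp), function(k) group_from_indices(grp[[k]],
        name = paste0("res_", gsub("\\|", "_", k))))))))
  }

  if ("backbone_sidechain" %in% levels) {
    out <- c(out, list(level("backbone_sidechain",
                             backbone_sidechain_groups(atoms))))
  }

  level_scheme(out, atoms)
}

backbone_sidechain_groups <- function(atoms) {
  poly <- which(atoms$is_polymer)
  keys <- residue_key(atoms)[poly]
  groups <- list()
  for (k in unique(keys)) {
    idx <- poly[keys == k]
    if (atoms$resname[idx[1]] %in% BB_SC_EXCLUDED) next
    bb <- idx[atoms$atom[idx] %in% BACKBONE_ATOMS]
    sc <- setdiff(idx, bb)
    tag <- gsub("\\|", "_", k)
    if (length(bb)) {
      groups[[length(groups) + 1L]] <-
        group_from_indices(bb, name = paste0("bb_", tag))
    }
    if (length(sc)) {
      groups[[length(groups) + 1L]] <-
        group_from_indices(sc, name = paste0("sc_", tag))
    }
  }
  groups
}

# --- secondary structure (simplified Kabsch-Sander) --------------------------

# Backbone amide H position: 1.0 A from N, anti to the preceding carbonyl.
amide_h <- function(n_pos, prev_c, prev_o) {
  dir <- prev_c - prev_o
  n_pos + dir / sqrt(sum(dir^2))
}

# Hydrogen-bond energy (kcal/mol) between donor NH(i) and acceptor CO(j),
# Kabsch-Sander electrostatic approximation: E = 0.084 * 332 *
# (1/rON + 1/rCH - 1/rOH - 1/rCN); bond when E < -0.5.
ks_energy <- function(n_i, h_i, c_j, o_j) {
  r <- function(a, b) sqrt(sum((a - b)^2))
  0.084 * 332 * (1 / r(o_j, n_i) + 1 / r(c_j, h_i) -
                 1 / r(o_j, h_i) - 1 / r(c_j, n_i))
}

#' Assign secondary structure from backbone geometry
#'
#' Simplified two-class DSSP: backbone amide hydrogens are reconstructed
#' geometrically, hydrogen bonds are scored with the Kabsch-Sander
#' electrostatic energy (cutoff -0.5 kcal/mol), helices (H) come from two
#' consecutive i -> i+4 turns, and strands (E) from ladders of at least two
#' consecutive parallel or antiparallel bridges. Everything else is coil.
#' Residues with missing backbone atoms are excluded (with a message).
#'
#' @param atoms atom table
#' @return data.frame with columns chain, start, end, type ("H" or "E"),
#'   one row per contiguous segment
#' @export
assign_secondary_structure <- function(atoms) {
  segs <- data.frame(chain = character(0), start = integer(0),
                     end = integer(0), type = character(0),
                     stringsAsFactors = FALSE)
  poly <- atoms[atoms$is_polymer, , drop = FALSE]
  for (ch in unique(poly$chain)) {
    ca <- poly[poly$chain == ch, , drop = FALSE]
    reskeys <- unique(paste(ca$resseq, ca$icode, sep = "|"))
    nres <- length(reskeys)
    bb <- vector("list", nres)
    ok <- logical(nres)
    for (i in seq_len(nres)) {
      sel <- paste(ca$resseq, ca$icode, sep = "|") == reskeys[i]
      res <- ca[sel, , drop = FALSE]
      need <- c("N", "CA", "C", "O")
      if (!all(need %in% res$atom)) {
        message("residue ", ch, " ", reskeys[i],
                " lacks backbone atoms; excluded from SS detection")
        next
      }
      bb[[i]] <- lapply(need, function(a) {
        r <- res[res$atom == a, , drop = FALSE][1, ]
        c(r$x, r$y, r$z)
      })
      names(bb[[i]]) <- need
      ok[i] <- TRUE
    }
    # hb[i, j]: NH of residue i donates to CO of residue j
    hb <- matrix(FALSE, nres, nres)
    for (i in seq_len(nres)) {
      if (!ok[i] || i == 1 || !ok[i - 1]) next  # no amide H at the N-terminus
      h_i <- amide_h(bb[[i]]$N, bb[[i - 1]]$C, bb[[i - 1]]$O)
      for (j in seq_len(nres)) {
        if (!ok[j] || abs(i - j) < 2) next
        e <- ks_energy(bb[[i]]$N, h_i, bb[[j]]$C, bb[[j]]$O)
        hb[i, j] <- e < -0.5
      }
    }
    co_nh <- function(i, j) {  # CO(i) accepts from NH(j)
      if (i < 1 || j < 1 || i > nres || j > nres) return(FALSE)
      hb[j, i]
    }
    cls <- rep("-", nres)
    # helix: turns at i and i+1 -> residues i+1 .. i+4 (un-bounded end trimmed)
    turn4 <- vapply(seq_len(nres), function(i) co_nh(i, i + 4), FALSE)
    for (i in seq_len(nres - 1)) {
      if (turn4[i] && turn4[i + 1]) {
        cls[(i + 1):min(i + 4, nres)] <- "H"
      }
    }
    # strands: bridges between residues at least 3 apart
    bridge <- matrix(FALSE, nres, nres)
    for (i in seq_len(nres)) {
      for (j in seq_len(nres)) {
        if (abs(i - j) < 3) next
        anti <- (co_nh(i, j) && co_nh(j, i)) ||
                (co_nh(i - 1, j + 1) && co_nh(j - 1, i + 1))
        para <- (co_nh(i - 1, j) && co_nh(j, i + 1)) ||
                (co_nh(j - 1, i) && co_nh(i, j + 1))
        bridge[i, j] <- anti || para
      }
    }
    in_ladder <- vapply(seq_len(nres), function(i) {
      js <- which(bridge[i, ])
      any(vapply(js, function(j) {
        any(bridge[pmax(i - 1, 1), c(j - 1, j + 1)[c(j - 1, j + 1) >= 1 &
                                                   c(j - 1, j + 1) <= nres]]) ||
        any(bridge[pmin(i + 1, nres), c(j - 1, j + 1)[c(j - 1, j + 1) >= 1 &
                                                      c(j - 1, j + 1) <= nres]])
      }, FALSE))
    }, FALSE)
    cls[in_ladder & cls != "H"] <- "E"

    # contiguous segments
    i <- 1
    while (i <= nres) {
      if (cls[i] %in% c("H", "E")) {
        j <- i
        while (j < nres && cls[j + 1] == cls[i]) j <- j + 1
        rs <- as.integer(sub("\\|.*", "", reskeys[c(i, j)]))
        segs <- rbind(segs, data.frame(chain = ch, start = rs[1], end = rs[2],
                                       type = cls[i],
                                       stringsAsFactors = FALSE))
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  rownames(segs) <- NULL
  segs
}

# SS-level groups: helix/strand segments, plus singleton per-residue groups
# for residues outside any segment (keeps the level covering the chain; the
# elastic net can zero the singletons out).
ss_level_groups <- function(atoms) {
  segs <- assign_secondary_structure(atoms)
  poly <- which(atoms$is_polymer)
  keys <- residue_key(atoms)[poly]
  ukeys <- unique(keys)
  assigned <- rep(NA_integer_, length(ukeys))
  if (nrow(segs) > 0) {
    for (si in seq_len(nrow(segs))) {
      for (ki in seq_along(ukeys)) {
        parts <- strsplit(ukeys[ki], "\\|")[[1]]
        if (parts[1] == segs$chain[si] &&
            as.integer(parts[2]) >= segs$start[si] &&
            as.integer(parts[2]) <= segs$end[si]) {
          assigned[ki] <- si
        }
      }
    }
  }
  groups <- list()
  for (si in seq_len(max(0, nrow(segs)))) {
    kidx <- which(assigned == si)
    if (!length(kidx)) next
    idx <- poly[keys %in% ukeys[kidx]]
    groups[[length(groups) + 1L]] <- group_from_indices(
      idx, name = paste0("ss_", segs$type[si], "_", segs$chain[si], "_",
                         segs$start[si], "_", segs$end[si]))
  }
  for (ki in which(is.na(assigned))) {
    idx <- poly[keys == ukeys[ki]]
    groups[[length(groups) + 1L]] <- group_from_indices(
      idx, name = paste0("ss_coil_", gsub("\\|", "_", ukeys[ki])))
  }
  groups
}
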