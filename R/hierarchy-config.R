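# Custom level definitions. A config is JSON of the form
#
#   {"levels": [
#      {"name": "molecule", "groups": [["A", "B", "C"]]},
#      {"name": "domain",   "groups": [["A:1-30"], ["A:31-60"]]},
#      {"builtin": "ss"},
#      {"builtin": "residue"},
#      {"builtin": "atomic"}
#   ]}
#
# listing the levels in order (largest scale first). Each custom group is an
# array of selection strings whose union forms the group; builtins pull in
# the corresponding default level. An empty config yields the default scheme.

#' Parse an atom selection string
#'
#' Syntax: \code{"A"} (all atoms of chain A), \code{"A:5-30"} (residues 5-30
#' of chain A, inclusive, author numbering), \code{"A:12"} (one residue).
#' Insertion codes are appended to the residue number (\code{"A:5A-30"}).
#' Unlike the default levels, custom selections may address non-polymer
#' atoms.
#'
#' @param sel selection string
#' @param atoms atom table
#' @return integer vector of atom indices
#' @export
parse_selection <- function(sel, atoms) {
  sel <- trimws(sel)
  if (!grepl(":", sel, fixed = TRUE)) {
    idx <- which(atoms$chain == sel)
  } else {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    chain <- parts[1]
    rng <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
    split_res <- function(tok) {
      m <- regmatches(tok, regexec("^([0-9]+)([A-Za-z]?)$", tok))[[1]]
      if (length(m) == 0) stop("cannot parse residue token '", tok,
                               "' in selection '", sel, "'")
      list(num = as.integer(m[2]), icode = m[3])
    }
    lo <- split_res(rng[1])
    hi <- if (length(rng) > 1) split_res(rng[2]) else lo
    in_chain <- atoms$chain == chain
    # order residues by (resseq, icode) and take the inclusive range
    ord_key <- atoms$resseq * 100 +
      ifelse(nzchar(atoms$icode), match(atoms$icode, LETTERS), 0)
    lo_key <- lo$num * 100 + ifelse(nzchar(lo$icode), match(lo$icode, LETTERS), 0)
    hi_key <- hi$num * 100 + ifelse(nzchar(hi$icode), match(hi$icode, LETTERS), 0)
    idx <- which(in_chain & ord_key >= lo_key & ord_key <= hi_key)
  }
  if (!length(idx)) stop("selection '", sel, "' matches no atoms")
  idx
}

#' Build a level scheme from a custom configuration
#'
#' @param config path to a JSON file, a JSON string, or an already-parsed
#'   list; an empty config yields \code{\link{build_default_scheme}}
#' @param atoms atom table
#' @return \code{level_scheme}
#' @export
parse_custom_levels <- function(config, atoms) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  if (is.null(config$levels) || length(config$levels) == 0) {
    return(build_default_scheme(atoms))
  }
  builtin_cache <- NULL
  get_builtin <- function(which_level) {
    if (which_level == "atomic") return(level("atomic", kind = "atomic"))
    if (is.null(builtin_cache)) {
      builtin_cache <<- build_default_scheme(atoms)
    }
    names_b <- vapply(builtin_cache$levels, `[[`, "", "name")
    li <- match(which_level, names_b)
    if (is.na(li)) stop("unknown builtin level '", which_level, "'")
    builtin_cache$levels[[li]]
  }
  levels <- lapply(config$levels, function(entry) {
    if (!is.null(entry$builtin)) return(get_builtin(entry$builtin))
    if (is.null(entry$name) || is.null(entry$groups)) {
      stop("custom level entries need 'name' and 'groups' (or 'builtin')")
    }
    groups <- lapply(seq_along(entry$groups), function(gi) {
      sels <- unlist(entry$groups[[gi]])
      idx <- sort(unique(unlist(lapply(sels, parse_selection, atoms = atoms))))
      group_from_indices(idx, name = paste0(entry$name, "_", gi))
    })
    level(entry$name, groups)
  })
  level_scheme(levels, atoms)
}
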