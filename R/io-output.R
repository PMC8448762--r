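# Output writers for fitted decompositions: one structure per level (B
# column and ANISOU carry that level's contribution), a total structure, a
# JSON summary in the per-level mean-B table layout, and the trace CSV.

#' Write per-level structures for a fitted decomposition
#'
#' One PDB (and optionally mmCIF) file per level, named
#' \code{level_00_<name>.pdb} onward, where each atom's B column holds the
#' equivalent B of that level's contribution (0 for atoms without a group at
#' that level) and ANISOU records hold the contribution tensor; plus a
#' \code{total} structure whose ADPs are the model sum.
#'
#' @param fit \code{echt_fit}
#' @param outdir output directory (created if needed)
#' @param formats subset of c("pdb", "cif")
#' @return invisible character vector of the files written
#' @export
write_level_structures <- function(fit, outdir, formats = c("pdb", "cif")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", outdir)
  }
  mu <- model_uijs(fit)
  files <- character(0)
  emit <- function(u, stem) {
    a <- fit$atoms
    a$b <- round(u_to_b(u), 2)
    a[U_COLS] <- u
    for (fmt in formats) {
      f <- file.path(outdir, paste0(stem, ".", fmt))
      if (fmt == "pdb") write_pdb(a, f) else write_cif(a, f, block = stem)
      files <<- c(files, f)
    }
  }
  for (li in seq_along(mu$levels)) {
    nm <- names(mu$levels)[li]
    emit(mu$levels[[li]], sprintf("level_%02d_%s", li - 1, nm))
  }
  emit(mu$total, "total")
  invisible(files)
}

#' Write the summary report and trace for a fitted decomposition
#'
#' \code{summary.json} holds the per-level mean-B table (A^2 and percent of
#' total), the complexity metrics, and the convergence verdict;
#' \code{trace.csv} holds the per-macrocycle, per-level optimization trace.
#'
#' @param fit \code{echt_fit}
#' @param outdir output directory (created if needed)
#' @return invisible character vector of the files written
#' @export
write_summary <- function(fit, outdir) {
  if (is.null(fit$trace) || nrow(fit$trace) == 0) {
    stop("fit has an empty optimization trace; nothing to summarize")
  }
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", outdir)
  }
  s <- level_summary(fit)
  cx <- model_complexity(fit)
  payload <- list(
    levels = lapply(seq_len(nrow(s)), function(i) {
      list(level = s$level[i], mean_b = s$mean_b[i], percent = s$percent[i])
    }),
    complexity = list(sum_amplitudes = cx$sum_amplitudes,
                      per_atom = cx$per_atom),
    converged = fit$converged,
    n_macrocycles = fit$n_macrocycles,
    rmsd = fit$rmsd,
    config = list(gamma = fit$config$gamma, delta = fit$config$delta,
                  db_cutoff = fit$config$db_cutoff,
                  eps_psd = fit$config$eps_psd, seed = fit$config$seed))
  json_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  csv_path <- file.path(outdir, "trace.csv")
  utils::write.csv(fit$trace, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
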