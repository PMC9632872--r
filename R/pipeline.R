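#' @name sapofold-package
#' @aliases sapofold
#' @title sapofold: structural analysis of disulfide-stabilized saposin-fold peptides
#' @description
#' Tools for the integrative structural characterization of small
#' disulfide-stabilized helix-hairpin peptides such as the surfactant
#' protein B construct Super Mini-B: disulfide dihedral strain energetics
#' over PDB conformer ensembles, HELANAL-style helix-axis geometry,
#' Ramachandran and superposition validation, in-silico pepsin
#' digest / crosslinked-mass connectivity mapping, and CD/FTIR spectral
#' quantification, plus seeded synthetic-data generators for all inputs.
#' @keywords internal
"_PACKAGE"

log_line <- function(log, ...) {
  msg <- paste0(...)
  if (!is.null(log)) cat(msg, "\n", sep = "", file = log, append = TRUE)
  invisible(msg)
}

#' Disulfide strain report over one or more structures
#'
#' Orchestrates [find_disulfides()], [ensemble_stats()] and [strain_table()]
#' over PDB files, writing a TSV report and a parameter log.
#'
#' @param paths Character vector of PDB file paths.
#' @param pairs Optional list of explicit pair data frames (see
#'   [find_disulfides()]); detected automatically when `NULL`.
#' @param n_lowest Leading conformers for ensemble statistics (default 10).
#' @param cutoff SG-SG detection cutoff, Angstrom.
#' @param resno_offset Residue-number offset applied on reading.
#' @param out_tsv Optional TSV output path.
#' @param log Optional log file path.
#' @return A `strain_table`, invisibly when `out_tsv` is given.
#' @export
run_ssbond <- function(paths, pairs = NULL, n_lowest = 10, cutoff = 2.3,
                       resno_offset = 0L, out_tsv = NULL, log = NULL) {
  log_line(log, "ssbond: n_lowest=", n_lowest, " cutoff=", cutoff,
           " resno_offset=", resno_offset)
  ensembles <- lapply(paths, read_pdb, resno_offset = resno_offset)
  if (is.null(pairs))
    pairs <- lapply(ensembles, find_disulfides, model_index = 1, cutoff = cutoff)
  tab <- strain_table(ensembles, pairs = pairs, n_lowest = n_lowest)
  for (i in seq_along(ensembles))
    log_line(log, "  ", ensembles[[i]]$source_id, ": models used ",
             min(n_lowest, n_models(ensembles[[i]])))
  if (!is.null(out_tsv)) {
    write_strain_table(tab, out_tsv)
    return(invisible(tab))
  }
  tab
}

#' Model validation: Ramachandran summary and optional segment RMSD
#'
#' @param model_path PDB path of the model to validate.
#' @param reference_path Optional PDB path of a reference structure.
#' @param ranges_model,ranges_reference Lists of `c(start, end)` residue
#'   ranges mapping model onto reference (required with `reference_path`).
#' @param out_tsv Optional TSV path for the per-residue Ramachandran table.
#' @param log Optional log file path.
#' @return List with `rama` (a `rama_summary`) and `rmsd` (numeric or NULL).
#' @export
run_validate <- function(model_path, reference_path = NULL,
                         ranges_model = NULL, ranges_reference = NULL,
                         out_tsv = NULL, log = NULL) {
  ens <- read_pdb(model_path)
  rs <- rama_summary(ens, 1)
  log_line(log, "validate: ", model_path, " pct_core=", rs$pct[["core"]])
  rmsd <- NULL
  if (!is.null(reference_path)) {
    ref <- read_pdb(reference_path)
    rmsd <- as.numeric(segment_rmsd(ens, ranges_model, ref, ranges_reference))
    log_line(log, "  segment RMSD vs ", reference_path, ": ",
             sprintf("%.2f", rmsd), " A")
  }
  if (!is.null(out_tsv))
    utils::write.table(rs$detail, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(rama = rs, rmsd = rmsd)
}

#' Disulfide connectivity inference from a mass list
#'
#' @param sequence Single-letter peptide string, or a FASTA path (requires
#'   the seqinr package).
#' @param masses Numeric vector of observed neutral monoisotopic masses, or
#'   a path to a one/two-column text file (mass, optional intensity).
#' @param tol_ppm Match tolerance, ppm.
#' @param max_missed Missed cleavages for the digest.
#' @param out_tsv Optional TSV path for the hypothesis ranking.
#' @param log Optional log file path.
#' @return A `connectivity_report`.
#' @export
run_connectivity <- function(sequence, masses, tol_ppm = 10, max_missed = 2,
                             out_tsv = NULL, log = NULL) {
  if (file.exists(sequence) && grepl("\\.(fa|fasta|txt)$", sequence,
                                     ignore.case = TRUE)) {
    if (!requireNamespace("seqinr", quietly = TRUE))
      stop("reading FASTA requires the seqinr package")
    sequence <- toupper(paste(seqinr::read.fasta(sequence,
      as.string = TRUE, seqonly = TRUE)[[1]], collapse = ""))
  }
  if (is.character(masses)) {
    if (file.size(masses) == 0) {
      masses <- numeric(0)
    } else {
      d <- utils::read.table(masses, header = FALSE, fill = TRUE)
      masses <- as.numeric(d[[1]])
      masses <- masses[is.finite(masses)]
    }
  }
  log_line(log, "connectivity: tol_ppm=", tol_ppm, " max_missed=", max_missed,
           " n_obs=", length(masses))
  rep <- infer_connectivity(sequence, masses, tol_ppm = tol_ppm,
                            max_missed = max_missed)
  if (rep$status == "inconclusive")
    warning("no observed mass matched any hypothesis; result inconclusive")
  if (!is.null(out_tsv))
    utils::write.table(rep$ranking, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rep
}

#' Isotope-shift analysis of an unlabeled/labeled FTIR spectrum pair
#'
#' @param unlabeled,labeled `spectrum` objects or two-column file paths.
#' @param blank Optional blank `spectrum` or path, subtracted from both.
#' @param ... Passed to [isotope_shift()].
#' @param log Optional log file path.
#' @return An `isotope_shift` result.
#' @export
run_spectra <- function(unlabeled, labeled, blank = NULL, ..., log = NULL) {
  load_sp <- function(s) if (is.character(s)) read_spectrum(s) else s
  u <- load_sp(unlabeled); l <- load_sp(labeled)
  if (!is.null(blank)) {
    b <- load_sp(blank)
    u <- subtract_blank(u, b); l <- subtract_blank(l, b)
  }
  res <- isotope_shift(u, l, ...)
  log_line(log, "spectra: shift=", sprintf("%.1f", res$shift),
           " assignment=", res$assignment)
  res
}

#' Write synthetic fixtures for downstream analyses
#'
#' Thin wrapper over the seeded generators: builds the requested fixture and
#' writes it in the matching plain-text format (PDB for structures, CSV for
#' spectra, one mass per line for digests).
#'
#' @param what One of `"helix"`, `"hairpin"`, `"disulfide"`, `"spectrum"`,
#'   `"digest"`.
#' @param out Output file path.
#' @param ... Passed to the matching builder ([build_ideal_helix()],
#'   [build_hairpin()], [build_disulfide_fixture()], [gaussian_spectrum()],
#'   [synth_digest_observations()]).
#' @param log Optional log file path.
#' @return The generated object, invisibly.
#' @export
run_simulate <- function(what = c("helix", "hairpin", "disulfide",
                                  "spectrum", "digest"),
                         out, ..., log = NULL) {
  what <- match.arg(what)
  obj <- switch(what,
    helix = build_ideal_helix(...),
    hairpin = build_hairpin(...),
    disulfide = build_disulfide_fixture(...),
    spectrum = gaussian_spectrum(...),
    digest = synth_digest_observations(...))
  log_line(log, "simulate: ", what, " -> ", out)
  if (inherits(obj, "structure_ensemble")) write_pdb(obj, out)
  else if (inherits(obj, "spectrum"))
    utils::write.table(obj, out, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  else writeLines(format(obj, digits = 10), out)
  invisible(obj)
}
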