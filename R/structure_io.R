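#' @importFrom stats sd setNames complete.cases
#' @importFrom utils write.table head
NULL

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
AA3_TO_1 <- setNames(
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  STANDARD_AA3)

#' Read a (multi-model) PDB coordinate file
#'
#' Parses ATOM/HETATM/MODEL records into a `structure_ensemble`: one entry
#' per MODEL record (a single implicit model if the file has none), with a
#' shared atom table and per-model coordinates. Hydrogens and waters are
#' dropped; HETATM records are kept only when they are amino-acid residues
#' sitting inside a chain (e.g. selenomethionine); alternate locations are
#' resolved to the highest occupancy, ties broken by the alphabetically
#' first altloc label.
#'
#' @param path Path to a PDB-format file.
#' @param source_id Free-text identifier; defaults to the file name.
#' @param resno_offset Integer added to author residue numbers on input,
#'   for mapping a publication's residue numbering onto the file's.
#' @return An object of class `structure_ensemble`: a list with
#'   `atom` (data frame: `elety`, `resid`, `chain`, `resno`, `insert`, `o`,
#'   `elesy`), `xyz` (matrix, one row per model, 3 columns per atom) and
#'   `source_id`.
#' @export
read_pdb <- function(path, source_id = basename(path), resno_offset = 0L) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM records in '", path, "'")
  keep <- rep(TRUE, nrow(at))
  # waters and non-amino-acid heteroatoms out; amino-acid HETATMs stay
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  is_aa <- at$resid %in% STANDARD_AA3 | at$resid %in% rownames(bio3d::aa.table)
  keep <- keep & (at$type == "ATOM" | is_aa)
  # hydrogens out
  elesy <- at$elesy
  elesy[is.na(elesy) | elesy == ""] <- substr(gsub("^[0-9]*", "", at$elety[is.na(elesy) | elesy == ""]), 1, 1)
  keep <- keep & !(toupper(elesy) %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz[, bio3d::atom2xyz(which(keep)), drop = FALSE]
  if (nrow(at) == 0) stop("no usable atoms in '", path, "'")

  # altloc resolution: highest occupancy, ties to the alphabetically first label
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])
  at <- at[sel, , drop = FALSE]
  xyz <- xyz[, bio3d::atom2xyz(sel), drop = FALSE]

  if (any(!is.finite(xyz)))
    stop("ensemble-consistency error: models in '", path,
         "' do not share the same atom set")
  at$resno <- at$resno + as.integer(resno_offset)
  at$insert[is.na(at$insert)] <- ""
  rownames(at) <- NULL
  structure(
    list(atom = at[, c("elety", "resid", "chain", "resno", "insert", "o", "elesy")],
         xyz = xyz,
         source_id = source_id),
    class = "structure_ensemble")
}

#' Write a structure ensemble as a PDB file
#'
#' Writes every model between MODEL/ENDMDL records (a bare single-model file
#' when the ensemble holds one model). Coordinates round-trip through
#' [read_pdb()] to PDB precision (1e-3 Angstrom).
#'
#' @param ensemble A `structure_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  at <- ensemble$atom
  o <- at$o
  o[is.na(o)] <- 1
  bio3d::write.pdb(file = path, xyz = ensemble$xyz,
                   resno = at$resno, chain = at$chain, resid = at$resid,
                   elety = at$elety, insert = at$insert, o = o,
                   elesy = at$elesy)
  invisible(path)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("structure_ensemble:", x$source_id, "\n")
  cat("  models:", n_models(x), "  atoms/model:", nrow(x$atom), "\n")
  ch <- split(x$atom$resno, x$atom$chain)
  for (nm in names(ch))
    cat("  chain ", nm, ": residues ", min(ch[[nm]]), "-", max(ch[[nm]]),
        " (", length(unique(ch[[nm]])), ")\n", sep = "")
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble A `structure_ensemble`.
#' @return Integer model count.
#' @export
n_models <- function(ensemble) nrow(ensemble$xyz)

#' Select atom coordinates from one model
#'
#' Returns coordinates in the residue order given, atoms within each residue
#' in the order of `names`. Selections are order-stable: permuting the
#' request permutes the rows identically.
#'
#' @param ensemble A `structure_ensemble`.
#' @param model_index Model number (1-based, file order).
#' @param chain Chain identifier.
#' @param seq_ids Integer vector of author residue numbers.
#' @param names Character vector of atom names (e.g. `c("N","CA","C","O")`).
#' @return Numeric matrix, `length(seq_ids) * length(names)` rows by 3.
#' @export
select_atoms <- function(ensemble, model_index, chain, seq_ids, names) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (model_index < 1 || model_index > n_models(ensemble))
    stop("model_index ", model_index, " out of range (1-", n_models(ensemble), ")")
  at <- ensemble$atom
  coords <- matrix(ensemble$xyz[model_index, ], ncol = 3, byrow = TRUE)
  out <- matrix(NA_real_, nrow = length(seq_ids) * length(names), ncol = 3)
  k <- 0L
  for (r in seq_ids) {
    for (nm in names) {
      k <- k + 1L
      i <- which(at$chain == chain & at$resno == r & at$elety == nm)
      if (length(i) != 1)
        stop("selection error: atom '", nm, "' of residue ", chain, ":", r,
             if (length(i) == 0) " not found" else " is ambiguous")
      out[k, ] <- coords[i, ]
    }
  }
  out
}

#' Extract the one-letter sequence of a chain
#'
#' One letter per residue in residue-number order; nonstandard residues
#' map to `"X"`.
#'
#' @param ensemble A `structure_ensemble`.
#' @param chain Chain identifier.
#' @return Single-letter character string.
#' @export
extract_sequence <- function(ensemble, chain) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  at <- ensemble$atom
  sel <- at$chain == chain
  if (!any(sel)) stop("unknown chain: ", chain)
  at <- at[sel, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert)), , drop = FALSE]
  at <- at[order(at$resno), , drop = FALSE]
  letters1 <- ifelse(at$resid %in% STANDARD_AA3, AA3_TO_1[at$resid], "X")
  paste(letters1, collapse = "")
}

#' Assemble an ensemble from a shared atom table and per-model coordinates
#'
#' @param atom Data frame with columns `elety`, `resid`, `chain`, `resno`
#'   (optionally `insert`, `o`, `elesy`).
#' @param xyz Numeric matrix, one row per model, `3 * nrow(atom)` columns,
#'   or a single numeric vector for a one-model ensemble.
#' @param source_id Free-text identifier.
#' @return A `structure_ensemble`.
#' @export
make_ensemble <- function(atom, xyz, source_id = "synthetic") {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  stopifnot(ncol(xyz) == 3 * nrow(atom))
  if (is.null(atom$insert)) atom$insert <- ""
  if (is.null(atom$o)) atom$o <- 1
  if (is.null(atom$elesy)) atom$elesy <- substr(gsub("^[0-9]*", "", atom$elety), 1, 1)
  rownames(atom) <- NULL
  structure(list(atom = atom[, c("elety", "resid", "chain", "resno",
                                 "insert", "o", "elesy")],
                 xyz = xyz, source_id = source_id),
            class = "structure_ensemble")
}

#' Stack single-model ensembles sharing an atom table into one ensemble
#'
#' @param ensembles List of `structure_ensemble` objects with identical atom
#'   tables (e.g. the same fixture built at different dihedrals).
#' @param source_id Identifier for the stacked ensemble.
#' @return A multi-model `structure_ensemble`.
#' @export
stack_models <- function(ensembles, source_id = "stacked") {
  stopifnot(length(ensembles) >= 1)
  ref <- ensembles[[1]]$atom
  for (e in ensembles)
    if (!identical(e$atom[, c("elety", "resid", "chain", "resno")],
                   ref[, c("elety", "resid", "chain", "resno")]))
      stop("ensemble-consistency error: models do not share one atom set")
  xyz <- do.call(rbind, lapply(ensembles, function(e) e$xyz))
  make_ensemble(ref, xyz, source_id = source_id)
}
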