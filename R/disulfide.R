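#' Katz-Kossiakoff disulfide dihedral strain energy
#'
#' Empirical cosine-series estimate of the conformational strain of a
#' cystine bridge from its five chi torsions:
#' \deqn{E = 8.37(1+\cos 3\chi_1) + 8.37(1+\cos 3\chi_1') +
#'           4.18(1+\cos 3\chi_2) + 4.18(1+\cos 3\chi_2') +
#'           14.64(1+\cos 2\chi_3) + 2.51(1+\cos 3\chi_3)}
#' in kJ/mol. Every term is nonnegative, so E lies in [0, 84.50]; the two
#' chi3 terms cannot vanish simultaneously, which puts the global minimum
#' near |chi3| = 83 deg at about 2.04 kJ/mol.
#'
#' @param chi1,chi1p,chi2,chi2p,chi3 Torsions in degrees (vectorized).
#' @return Strain energy in kJ/mol.
#' @examples
#' katz_energy(0, 0, 0, 0, 0)        # 84.50, every term maximal
#' katz_energy(60, 60, 60, 60, 90)   # 2.51
#' @export
katz_energy <- function(chi1, chi1p, chi2, chi2p, chi3) {
  stopifnot(all(is.finite(c(chi1, chi1p, chi2, chi2p, chi3))))
  d <- pi / 180
  8.37 * (1 + cos(3 * chi1 * d)) + 8.37 * (1 + cos(3 * chi1p * d)) +
    4.18 * (1 + cos(3 * chi2 * d)) + 4.18 * (1 + cos(3 * chi2p * d)) +
    14.64 * (1 + cos(2 * chi3 * d)) + 2.51 * (1 + cos(3 * chi3 * d))
}

#' Detect disulfide bridges in one model
#'
#' All unordered CYS SG-SG pairs with distance at most `cutoff`, assigned
#' greedily by ascending distance so each SG joins at most one pair.
#'
#' @param ensemble A `structure_ensemble`.
#' @param model_index Model number (default 1).
#' @param cutoff SG-SG distance cutoff in Angstrom. The default 2.3 covers
#'   the covalent bond (about 2.05) plus coordinate noise.
#' @return Data frame with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`, `ss_distance`.
#' @export
find_disulfides <- function(ensemble, model_index = 1, cutoff = 2.3) {
  at <- ensemble$atom
  coords <- matrix(ensemble$xyz[model_index, ], ncol = 3, byrow = TRUE)
  cys <- unique(at[at$resid == "CYS", c("chain", "resno"), drop = FALSE])
  sg <- integer(0)
  keep <- logical(0)
  if (nrow(cys)) for (i in seq_len(nrow(cys))) {
    j <- which(at$chain == cys$chain[i] & at$resno == cys$resno[i] &
               at$elety == "SG")
    if (length(j) == 0) {
      warning("cysteine ", cys$chain[i], ":", cys$resno[i],
              " lacks an SG atom; skipped")
      keep[i] <- FALSE
    } else {
      sg <- c(sg, j[1]); keep[i] <- TRUE
    }
  }
  cys <- cys[keep, , drop = FALSE]
  out <- data.frame(chain_a = character(0), resno_a = integer(0),
                    chain_b = character(0), resno_b = integer(0),
                    ss_distance = numeric(0), stringsAsFactors = FALSE)
  if (length(sg) < 2) return(out)
  dm <- as.matrix(stats::dist(coords[sg, , drop = FALSE]))
  cand <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0) return(out)
  cand <- cand[order(dm[cand]), , drop = FALSE]
  used <- logical(length(sg))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out <- rbind(out, data.frame(
      chain_a = cys$chain[i], resno_a = cys$resno[i],
      chain_b = cys$chain[j], resno_b = cys$resno[j],
      ss_distance = dm[i, j], stringsAsFactors = FALSE))
  }
  out
}

#' Disulfide geometry and strain of one Cys-Cys pair
#'
#' Measures the five chi torsions across the bridge
#' (chi1 = N-CA-CB-SG of a; chi2 = CA-CB-SG-SG'; chi3 = CB-SG-SG'-CB';
#' primed torsions from the partner), the SG-SG distance, and the
#' Katz strain energy.
#'
#' @param ensemble A `structure_ensemble`.
#' @param model_index Model number.
#' @param chain_a,resno_a,chain_b,resno_b The two cysteines.
#' @return Object of class `disulfide_bond`: list with `cys_a`, `cys_b`,
#'   `chi1`, `chi1p`, `chi2`, `chi2p`, `chi3`, `ss_distance`, `energy`.
#' @export
disulfide_geometry <- function(ensemble, model_index,
                               chain_a, resno_a, chain_b, resno_b) {
  need <- c("N", "CA", "CB", "SG")
  pa <- select_atoms(ensemble, model_index, chain_a, resno_a, need)
  pb <- select_atoms(ensemble, model_index, chain_b, resno_b, need)
  N_a <- pa[1, ]; CA_a <- pa[2, ]; CB_a <- pa[3, ]; SG_a <- pa[4, ]
  N_b <- pb[1, ]; CA_b <- pb[2, ]; CB_b <- pb[3, ]; SG_b <- pb[4, ]
  chi1 <- torsion_angle(N_a, CA_a, CB_a, SG_a)
  chi1p <- torsion_angle(N_b, CA_b, CB_b, SG_b)
  chi2 <- torsion_angle(CA_a, CB_a, SG_a, SG_b)
  chi2p <- torsion_angle(CA_b, CB_b, SG_b, SG_a)
  chi3 <- torsion_angle(CB_a, SG_a, SG_b, CB_b)
  ss <- vnorm(SG_a - SG_b)
  structure(list(cys_a = list(chain = chain_a, resno = resno_a),
                 cys_b = list(chain = chain_b, resno = resno_b),
                 chi1 = chi1, chi1p = chi1p, chi2 = chi2, chi2p = chi2p,
                 chi3 = chi3, ss_distance = ss,
                 energy = katz_energy(chi1, chi1p, chi2, chi2p, chi3)),
            class = "disulfide_bond")
}

#' @export
print.disulfide_bond <- function(x, ...) {
  cat(sprintf("disulfide %s:%d -- %s:%d\n", x$cys_a$chain, x$cys_a$resno,
              x$cys_b$chain, x$cys_b$resno))
  cat(sprintf("  chi1 %8.2f  chi1' %8.2f  chi2 %8.2f  chi2' %8.2f  chi3 %8.2f deg\n",
              x$chi1, x$chi1p, x$chi2, x$chi2p, x$chi3))
  cat(sprintf("  S-S %6.3f A   strain %10.6f kJ/mol\n", x$ss_distance, x$energy))
  invisible(x)
}

#' Conformer-ensemble statistics for one disulfide pair
#'
#' Mean and sample (n-1) standard deviation of the SG-SG distance and strain
#' energy over the first `min(n_lowest, n_models)` models in file order
#' (NMR depositions are conventionally deposited best conformer first).
#'
#' @inheritParams disulfide_geometry
#' @param n_lowest Number of leading models to use (default 10).
#' @return List of class `ensemble_disulfide_stats` with `pair`, `n_models`,
#'   `mean_distance`, `sd_distance`, `mean_energy`, `sd_energy`.
#' @export
ensemble_stats <- function(ensemble, chain_a, resno_a, chain_b, resno_b,
                           n_lowest = 10) {
  nm <- min(n_lowest, n_models(ensemble))
  if (nm < 1) stop("ensemble has no models")
  vals <- lapply(seq_len(nm), function(m)
    tryCatch(disulfide_geometry(ensemble, m, chain_a, resno_a, chain_b, resno_b),
             error = function(e) stop("pair ", chain_a, ":", resno_a, "-",
                                      chain_b, ":", resno_b,
                                      " unresolvable in model ", m, ": ",
                                      conditionMessage(e))))
  d <- vapply(vals, `[[`, numeric(1), "ss_distance")
  e <- vapply(vals, `[[`, numeric(1), "energy")
  structure(list(pair = sprintf("Cys-%d Cys-%d", resno_a, resno_b),
                 chain_a = chain_a, resno_a = resno_a,
                 chain_b = chain_b, resno_b = resno_b,
                 n_models = nm,
                 mean_distance = mean(d),
                 sd_distance = if (nm > 1) stats::sd(d) else 0,
                 mean_energy = mean(e),
                 sd_energy = if (nm > 1) stats::sd(e) else 0),
            class = "ensemble_disulfide_stats")
}

#' Disulfide strain report over structures
#'
#' One row per (structure, pair), in the style of published saposin-family
#' strain tables: identifier, residue pair, S-S distance and strain energy
#' as mean over the leading conformers with sample SD (blank SD for
#' single-model structures), energies formatted to 6 decimals.
#'
#' @param ensembles List of `structure_ensemble` objects.
#' @param pairs Optional list (parallel to `ensembles`) of data frames as
#'   returned by [find_disulfides()]; detected automatically from model 1
#'   when `NULL`.
#' @param n_lowest Leading conformer count for the statistics.
#' @param labels Optional character vector of structure labels.
#' @return Data frame of class `strain_table` with numeric columns plus
#'   formatted `distance_label` / `energy_label` columns.
#' @export
strain_table <- function(ensembles, pairs = NULL, n_lowest = 10, labels = NULL) {
  if (inherits(ensembles, "structure_ensemble")) ensembles <- list(ensembles)
  if (is.null(labels))
    labels <- vapply(ensembles, `[[`, character(1), "source_id")
  rows <- list()
  for (i in seq_along(ensembles)) {
    ens <- ensembles[[i]]
    pr <- if (is.null(pairs)) find_disulfides(ens, 1) else pairs[[i]]
    if (is.null(pr) || nrow(pr) == 0) next
    for (j in seq_len(nrow(pr))) {
      st <- ensemble_stats(ens, pr$chain_a[j], pr$resno_a[j],
                           pr$chain_b[j], pr$resno_b[j], n_lowest = n_lowest)
      multi <- st$n_models > 1
      rows[[length(rows) + 1]] <- data.frame(
        structure = labels[i],
        pair = st$pair,
        n_models = st$n_models,
        ss_distance = st$mean_distance,
        sd_distance = st$sd_distance,
        energy = st$mean_energy,
        sd_energy = st$sd_energy,
        distance_label = if (multi)
          sprintf("%.3f ± %.4f", st$mean_distance, st$sd_distance)
          else sprintf("%.2f", st$mean_distance),
        energy_label = if (multi)
          sprintf("%.6f ± %.6f", st$mean_energy, st$sd_energy)
          else sprintf("%.6f", st$mean_energy),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(0), pair = character(0),
               n_models = integer(0), ss_distance = numeric(0),
               sd_distance = numeric(0), energy = numeric(0),
               sd_energy = numeric(0), distance_label = character(0),
               energy_label = character(0), stringsAsFactors = FALSE)
  class(out) <- c("strain_table", "data.frame")
  out
}

#' Write a strain table as TSV
#' @param x A `strain_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strain_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
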