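#' Backbone phi/psi torsions of a chain
#'
#' phi_i = C(i-1)-N(i)-CA(i)-C(i); psi_i = N(i)-CA(i)-C(i)-N(i+1).
#' Chain termini carry `NA` on the missing side; residues with missing
#' backbone atoms get `NA` for the affected angle with a warning.
#'
#' @param ensemble A `structure_ensemble`.
#' @param model_index Model number.
#' @param chain Chain identifier.
#' @return Data frame with `chain`, `resno`, `resid`, `phi`, `psi`.
#' @export
phi_psi <- function(ensemble, model_index, chain) {
  at <- ensemble$atom
  coords <- matrix(ensemble$xyz[model_index, ], ncol = 3, byrow = TRUE)
  sel <- at$chain == chain
  if (!any(sel)) stop("unknown chain: ", chain)
  res <- unique(at$resno[sel])
  res <- res[order(res)]
  getatom <- function(r, nm) {
    i <- which(sel & at$resno == r & at$elety == nm)
    if (length(i) != 1) NULL else coords[i[1], ]
  }
  n <- length(res)
  phi <- psi <- rep(NA_real_, n)
  resid <- character(n)
  for (k in seq_len(n)) {
    r <- res[k]
    resid[k] <- at$resid[which(sel & at$resno == r)[1]]
    Ni <- getatom(r, "N"); CAi <- getatom(r, "CA"); Ci <- getatom(r, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) {
      warning("residue ", chain, ":", r, " lacks backbone atoms; angles undefined")
      next
    }
    if (k > 1) {
      Cm <- getatom(res[k - 1], "C")
      if (!is.null(Cm)) phi[k] <- torsion_angle(Cm, Ni, CAi, Ci)
    }
    if (k < n) {
      Np <- getatom(res[k + 1], "N")
      if (!is.null(Np)) psi[k] <- torsion_angle(Ni, CAi, Ci, Np)
    }
  }
  data.frame(chain = chain, resno = res, resid = resid, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

# Procheck-style Ramachandran region map on a 10-degree grid, composed from
# rectangles following the Morris et al. data-derived regions: "core" are the
# most-favoured A (alpha), B (beta) and L (left-handed alpha) areas,
# surrounded by additional-allowed, then generous rings.
rama_rects <- list(
  core = list(c(-140, -40, -60, -10),    # A
              c(-170, -50, 90, 180),     # B
              c(-170, -60, -180, -170),  # B, psi wrap
              c(40, 80, 10, 60)),        # L
  additional = list(c(-180, -20, -120, 45),
                    c(-180, -40, 60, 180),
                    c(-180, -40, -180, -140),
                    c(20, 100, -20, 90),
                    c(-180, -140, 140, 180)),
  generous = list(c(-180, 0, -180, 180),
                  c(0, 130, -90, 120),
                  c(60, 180, 120, 180))
)

#' Classify a phi/psi pair into Procheck-style regions
#'
#' Lookup in an embedded 10-degree rectangle-composed region map following
#' the Morris/Procheck classification: `core` (most favoured A, B, L),
#' `additional`, `generous`, `disallowed`.
#'
#' @param phi,psi Torsions in degrees (vectorized).
#' @return Character vector of classes.
#' @examples
#' classify_rama(-57, -47)   # "core" (alpha)
#' classify_rama(-119, 113)  # "core" (beta)
#' classify_rama(60, 60)     # not core
#' @export
classify_rama <- function(phi, psi) {
  wrap <- function(a) ifelse(a >= 180, a - 360, ifelse(a < -180, a + 360, a))
  phi <- wrap(phi); psi <- wrap(psi)
  one <- function(f, s) {
    if (is.na(f) || is.na(s)) return(NA_character_)
    inr <- function(r) f >= r[1] && f < r[2] && s >= r[3] && s < r[4]
    for (cls in c("core", "additional", "generous"))
      if (any(vapply(rama_rects[[cls]], inr, logical(1)))) return(cls)
    "disallowed"
  }
  mapply(one, phi, psi, USE.NAMES = FALSE)
}

#' Ramachandran summary with Procheck counting conventions
#'
#' Counts classes over residues excluding glycine, proline and chain-terminal
#' residues; percentages reported to 1 decimal.
#'
#' @param ensemble A `structure_ensemble`.
#' @param model_index Model number.
#' @param chains Chains to include (default: all).
#' @return Object of class `rama_summary`: list with `n_counted`, `counts`,
#'   `pct` (named numeric over core/additional/generous/disallowed) and the
#'   per-residue `detail` data frame.
#' @export
rama_summary <- function(ensemble, model_index = 1, chains = NULL) {
  if (is.null(chains)) chains <- unique(ensemble$atom$chain)
  detail <- do.call(rbind, lapply(chains, function(ch)
    phi_psi(ensemble, model_index, ch)))
  detail$class <- classify_rama(detail$phi, detail$psi)
  term_vec <- rep(FALSE, nrow(detail))
  for (ch in chains) {
    idx <- which(detail$chain == ch)
    r <- detail$resno[idx]
    term_vec[idx[r == min(r) | r == max(r)]] <- TRUE
  }
  counted <- !(detail$resid %in% c("GLY", "PRO")) & !term_vec &
    !is.na(detail$class)
  if (!any(counted)) stop("no countable residues for a Ramachandran summary")
  cls <- factor(detail$class[counted],
                levels = c("core", "additional", "generous", "disallowed"))
  counts <- table(cls)
  pct <- round(100 * as.numeric(counts) / sum(counts), 1)
  names(pct) <- names(counts)
  detail$counted <- counted
  structure(list(n_counted = sum(counts), counts = counts, pct = pct,
                 detail = detail),
            class = "rama_summary")
}

#' @export
print.rama_summary <- function(x, ...) {
  cat("Ramachandran summary (", x$n_counted, " counted residues)\n", sep = "")
  for (nm in names(x$pct))
    cat(sprintf("  %-11s %3d  (%5.1f%%)\n", nm, x$counts[[nm]], x$pct[[nm]]))
  invisible(x)
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `points_b` onto
#' `points_a` (reflections corrected), with
#' rmsd = sqrt(mean |a_i - (R b_i + t)|^2).
#'
#' @param points_a,points_b Equal-length coordinate matrices (n x 3, n >= 3,
#'   non-collinear).
#' @return Object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation`, `rmsd`, `n_atoms`.
#' @export
kabsch_superpose <- function(points_a, points_b) {
  A <- as.matrix(points_a); B <- as.matrix(points_b)
  if (nrow(A) != nrow(B)) stop("point sets differ in length")
  if (nrow(A) < 3) stop("need at least 3 paired points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (svd(A0)$d[2] < 1e-9 || svd(B0)$d[2] < 1e-9)
    stop("degenerate (collinear) point configuration")
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- ca - as.numeric(R %*% cb)
  resid <- A - (B %*% t(R) + matrix(t, nrow(A), 3, byrow = TRUE))
  structure(list(rotation = R, translation = t,
                 rmsd = sqrt(mean(rowSums(resid^2))), n_atoms = nrow(A)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d atoms: rmsd %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to an ensemble (transform the mobile model)
#'
#' @param ensemble A `structure_ensemble` (the mobile structure).
#' @param sup A `superposition` from [kabsch_superpose()].
#' @return The transformed `structure_ensemble`.
#' @export
transform_ensemble <- function(ensemble, sup) {
  xyz <- ensemble$xyz
  for (m in seq_len(nrow(xyz))) {
    pts <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    pts <- pts %*% t(sup$rotation) +
      matrix(sup$translation, nrow(pts), 3, byrow = TRUE)
    xyz[m, ] <- as.numeric(t(pts))
  }
  ensemble$xyz <- xyz
  ensemble
}

#' Global backbone RMSD over mapped residue segments
#'
#' Pairs residues positionally within the stated ranges (no sequence
#' alignment), superposes all mapped backbone atoms of all segments jointly,
#' and returns the global RMSD.
#'
#' @param ens_a,ens_b `structure_ensemble` objects.
#' @param ranges_a,ranges_b Lists of `c(start, end)` residue ranges; paired
#'   ranges must have equal lengths.
#' @param chain_a,chain_b Chain identifiers.
#' @param model_a,model_b Model numbers.
#' @param atom_names Backbone atom set (default N, CA, C, O).
#' @return RMSD in Angstrom, with the full `superposition` in attribute
#'   `"superposition"`.
#' @export
segment_rmsd <- function(ens_a, ranges_a, ens_b, ranges_b,
                         chain_a = ens_a$atom$chain[1],
                         chain_b = ens_b$atom$chain[1],
                         model_a = 1, model_b = 1,
                         atom_names = c("N", "CA", "C", "O")) {
  if (length(ranges_a) != length(ranges_b))
    stop("mapping error: ", length(ranges_a), " vs ", length(ranges_b),
         " segments")
  ids_a <- integer(0); ids_b <- integer(0)
  for (k in seq_along(ranges_a)) {
    ra <- ranges_a[[k]]; rb <- ranges_b[[k]]
    sa <- ra[1]:ra[2]; sb <- rb[1]:rb[2]
    if (length(sa) != length(sb))
      stop("mapping error: segment ", k, " lengths differ (",
           ra[1], "-", ra[2], " vs ", rb[1], "-", rb[2], ")")
    ids_a <- c(ids_a, sa); ids_b <- c(ids_b, sb)
  }
  A <- select_atoms(ens_a, model_a, chain_a, ids_a, atom_names)
  B <- select_atoms(ens_b, model_b, chain_b, ids_b, atom_names)
  sup <- kabsch_superpose(A, B)
  structure(sup$rmsd, superposition = sup)
}
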