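# Standard backbone internal coordinates used by the builders.
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

#' Build a full backbone chain from per-residue phi/psi
#'
#' Places N, CA, C, O for every residue by natural-extension (Z-matrix)
#' chaining with standard bond lengths and angles and omega = 180, so that
#' [phi_psi()] recovers the requested torsions exactly (phi of the first and
#' psi of the last residue are undefined and ignored).
#'
#' @param sequence Single-letter peptide string.
#' @param phi,psi Numeric vectors (recycled) of backbone torsions, degrees.
#' @param chain Chain identifier.
#' @param source_id Ensemble identifier.
#' @return A single-model `structure_ensemble`.
#' @export
build_backbone <- function(sequence, phi = -57, psi = -47, chain = "A",
                           source_id = "synthetic backbone") {
  aa <- split_seq(sequence)
  n <- length(aa)
  if (n < 2) stop("need at least 2 residues")
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  g <- BB_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_n, g$ang_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$n_ca, g$ang_c_n_ca, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c,
                             g$ang_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(n))
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o,
                         if (i < n) psi[i] + 180 else 0)
  res3 <- names(AA3_TO_1)[match(aa, AA3_TO_1)]
  res3[is.na(res3)] <- "UNK"
  atom <- data.frame(
    elety = rep(c("N", "CA", "C", "O"), n),
    resid = rep(res3, each = 4),
    chain = chain,
    resno = rep(seq_len(n), each = 4),
    stringsAsFactors = FALSE)
  xyz <- numeric(0)
  for (i in seq_len(n)) xyz <- c(xyz, N[i, ], CA[i, ], C[i, ], O[i, ])
  make_ensemble(atom, xyz, source_id = source_id)
}

#' Build an ideal alpha-helix
#'
#' CA-only mode places CA atoms on a helix of the stated rise, twist and
#' radius; full-backbone mode chains standard geometry at the stated phi/psi
#' via [build_backbone()]. The helix is rotated so its construction axis
#' lies along `axis` and translated to `origin`.
#'
#' @param n_res Number of residues (>= 4).
#' @param rise Rise per residue, Angstrom (default 1.5).
#' @param twist Twist per residue, degrees (default 100).
#' @param radius Helix radius for CA-only mode, Angstrom (default 2.3).
#' @param phi,psi Backbone torsions for full-backbone mode (defaults -57/-47).
#' @param axis Desired helix axis direction.
#' @param origin Translation applied after orientation.
#' @param full_backbone Build N/CA/C/O instead of CA only.
#' @param sequence Residue string (default poly-alanine).
#' @param chain Chain identifier.
#' @return A single-model `structure_ensemble`.
#' @export
build_ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                              phi = -57, psi = -47,
                              axis = c(0, 0, 1), origin = c(0, 0, 0),
                              full_backbone = FALSE,
                              sequence = strrep("A", n_res), chain = "A") {
  if (n_res < 4) stop("an ideal helix needs at least 4 residues")
  if (rise <= 0 || twist <= 0 || twist >= 180) stop("invalid rise/twist")
  if (full_backbone) {
    ens <- build_backbone(sequence, phi = phi, psi = psi, chain = chain,
                          source_id = "synthetic ideal helix")
    ca <- select_atoms(ens, 1, chain, seq_len(n_res), "CA")
    cur <- global_axis(local_axes(ca))
  } else {
    th <- (seq_len(n_res) - 1) * twist * pi / 180
    ca <- cbind(radius * cos(th), radius * sin(th), (seq_len(n_res) - 1) * rise)
    res3 <- names(AA3_TO_1)[match(split_seq(sequence), AA3_TO_1)]
    res3[is.na(res3)] <- "UNK"
    atom <- data.frame(elety = "CA", resid = res3, chain = chain,
                       resno = seq_len(n_res), stringsAsFactors = FALSE)
    ens <- make_ensemble(atom, as.numeric(t(ca)),
                         source_id = "synthetic ideal helix")
    cur <- c(0, 0, 1)
  }
  R <- rotation_between(cur, unitv(axis))
  pts <- matrix(ens$xyz[1, ], ncol = 3, byrow = TRUE) %*% t(R)
  pts <- sweep(pts, 2, origin, `+`)
  ens$xyz <- matrix(as.numeric(t(pts)), nrow = 1)
  ens
}

#' Build a two-helix hairpin at a set inter-axis angle
#'
#' Two CA-only ideal helices whose construction axes subtend the requested
#' undirected angle (the second helix runs back antiparallel, as in a
#' helix-hairpin), joined by a seeded pseudo-random coil linker. Helix
#' residue ranges are attached as attributes `helix_a` and `helix_b`.
#'
#' @param n_a,n_b Residue counts of the two helices.
#' @param angle Undirected inter-axis angle in degrees, 0-90.
#' @param linker_res Number of coil linker residues (default 4).
#' @param seed Integer seed for the linker jitter.
#' @param separation Axis-to-axis offset of the second helix, Angstrom.
#' @return A single-model `structure_ensemble` with attributes `helix_a`,
#'   `helix_b` giving `c(start, end)` residue ranges.
#' @export
build_hairpin <- function(n_a, n_b, angle, linker_res = 4, seed = 1,
                          separation = 9) {
  if (angle < 0 || angle > 90) stop("hairpin angle must be in [0, 90]")
  a <- build_ideal_helix(n_a)
  ca_a <- matrix(a$xyz[1, ], ncol = 3, byrow = TRUE)
  # second helix runs downward (antiparallel), tilted by `angle` about x
  ax_b <- as.numeric(rotation_between(c(0, 0, 1),
    c(0, sin(angle * pi / 180), cos(angle * pi / 180))) %*% c(0, 0, -1))
  top_a <- ca_a[n_a, ]
  origin_b <- top_a + c(separation, 0, 0)
  b <- build_ideal_helix(n_b, axis = ax_b, origin = origin_b)
  ca_b <- matrix(b$xyz[1, ], ncol = 3, byrow = TRUE)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  tfrac <- seq_len(linker_res) / (linker_res + 1)
  link <- t(vapply(tfrac, function(f)
    (1 - f) * ca_a[n_a, ] + f * ca_b[1, ] + stats::rnorm(3, sd = 0.5),
    numeric(3)))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  ca <- rbind(ca_a, link, ca_b)
  n <- nrow(ca)
  atom <- data.frame(elety = "CA", resid = "ALA", chain = "A",
                     resno = seq_len(n), stringsAsFactors = FALSE)
  ens <- make_ensemble(atom, as.numeric(t(ca)), source_id = "synthetic hairpin")
  attr(ens, "helix_a") <- c(1, n_a)
  attr(ens, "helix_b") <- c(n_a + linker_res + 1, n)
  ens
}

#' Build a two-cysteine disulfide fixture realizing specified chi dihedrals
#'
#' Places the internal-coordinate chain N-CA-CB-SG -- SG'-CB'-CA'-N' so that
#' [disulfide_geometry()] recovers every specified torsion exactly and the
#' SG-SG distance equals `ss_len`. Default stereochemistry: C-S 1.81, S-S
#' 2.05 Angstrom, tetrahedral-like 114/104-degree angles.
#'
#' @param chi1,chi1p,chi2,chi2p,chi3 Target torsions in degrees.
#' @param ss_len SG-SG distance (default 2.05).
#' @param cb_sg_len CB-SG bond (default 1.81).
#' @param ang_ca_cb_sg CA-CB-SG angle, degrees (default 114).
#' @param ang_cb_sg_sg CB-SG-SG angle, degrees (default 104).
#' @return A single-model `structure_ensemble` with two CYS residues.
#' @export
build_disulfide_fixture <- function(chi1, chi1p, chi2, chi2p, chi3,
                                    ss_len = 2.05, cb_sg_len = 1.81,
                                    ang_ca_cb_sg = 114, ang_cb_sg_sg = 104) {
  if (ss_len <= 0 || cb_sg_len <= 0) stop("bond lengths must be positive")
  ca_cb <- 1.53; n_ca <- 1.458; ang_n_ca_cb <- 110.5
  N_a <- c(0, 0, 0)
  CA_a <- c(n_ca, 0, 0)
  th <- ang_n_ca_cb * pi / 180
  CB_a <- CA_a + ca_cb * c(-cos(th), sin(th), 0)
  SG_a <- place_atom(N_a, CA_a, CB_a, cb_sg_len, ang_ca_cb_sg, chi1)
  SG_b <- place_atom(CA_a, CB_a, SG_a, ss_len, ang_cb_sg_sg, chi2)
  CB_b <- place_atom(CB_a, SG_a, SG_b, cb_sg_len, ang_cb_sg_sg, chi3)
  CA_b <- place_atom(SG_a, SG_b, CB_b, ca_cb, ang_ca_cb_sg, chi2p)
  N_b <- place_atom(SG_b, CB_b, CA_b, n_ca, ang_n_ca_cb, chi1p)
  atom <- data.frame(
    elety = rep(c("N", "CA", "CB", "SG"), 2),
    resid = "CYS", chain = "A",
    resno = rep(1:2, each = 4), stringsAsFactors = FALSE)
  atom$elesy <- rep(c("N", "C", "C", "S"), 2)
  xyz <- c(N_a, CA_a, CB_a, SG_a, N_b, CA_b, CB_b, SG_b)
  make_ensemble(atom, xyz, source_id = "synthetic disulfide fixture")
}

#' Seeded Gaussian band spectrum
#'
#' Sum of Gaussian bands on a uniform grid plus seeded Gaussian noise; a
#' deterministic stand-in for amide I FTIR measurements.
#'
#' @param centers,widths,amps Equal-length numeric vectors: band centers
#'   (cm^-1), Gaussian sigmas (cm^-1) and amplitudes.
#' @param x_range `c(lo, hi)` abscissa range (default 1580-1720).
#' @param step Grid step (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Integer seed (default 1).
#' @return A `spectrum`.
#' @export
gaussian_spectrum <- function(centers, widths, amps,
                              x_range = c(1580, 1720), step = 1,
                              noise_sd = 0, seed = 1) {
  if (length(centers) != length(widths) || length(centers) != length(amps))
    stop("centers, widths and amps must have equal lengths")
  if (step <= 0) stop("step must be positive")
  x <- seq(x_range[1], x_range[2], by = step)
  y <- rep(0, length(x))
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-0.5 * ((x - centers[i]) / widths[i])^2)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    y <- y + stats::rnorm(length(x), sd = noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  as_spectrum(x, y, "ftir")
}

#' Seeded synthetic digest mass observations
#'
#' Masses of the theoretical digest species under a known connectivity,
#' each perturbed by seeded uniform ppm jitter, with a seeded fraction
#' dropped — a stand-in for deconvoluted LC-MS observations.
#'
#' @param seq Parent peptide string.
#' @param pairing A k x 2 cysteine-pair matrix (the generating hypothesis).
#' @param ppm_jitter Maximum |jitter| in ppm (default 0).
#' @param dropout_frac Fraction of species dropped (default 0).
#' @param seed Integer seed.
#' @param max_missed Missed cleavages for the digest (default 1).
#' @return Numeric vector of observed masses in Da.
#' @export
synth_digest_observations <- function(seq, pairing, ppm_jitter = 0,
                                      dropout_frac = 0, seed = 1,
                                      max_missed = 1) {
  hyps <- enumerate_pairings(cys_positions(seq))
  ok <- any(vapply(hyps, function(h)
    identical(apply(h, 1, sort), apply(pairing, 1, sort)), logical(1)))
  if (!ok && nrow(pairing) > 0) {
    pp <- sort(as.integer(pairing))
    if (!identical(pp, sort(cys_positions(seq))))
      stop("invalid hypothesis: pairing must be a perfect matching of the cysteines")
  }
  fr <- pepsin_digest(seq, max_missed = max_missed)
  sp <- theoretical_species(fr, pairing)
  m <- sp$mono_mass
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  if (ppm_jitter > 0)
    m <- m * (1 + stats::runif(length(m), -ppm_jitter, ppm_jitter) * 1e-6)
  if (dropout_frac > 0) {
    keep <- stats::runif(length(m)) >= dropout_frac
    if (!any(keep)) keep[1] <- TRUE
    m <- m[keep]
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  m
}

#' Synthetic stand-in model of the SMB peptide
#'
#' A full-backbone model built from the real SMB sequence with alpha-helical
#' torsions over the experimentally assigned helix domains (residues 6-21
#' and 30-37) and non-helical torsions elsewhere. This is a geometric
#' stand-in for a refined coordinate set, intended for exercising the
#' Ramachandran machinery: of its 32 counted residues (41 minus Gly, Pro and
#' the two termini) exactly `n_additional` are placed in additional-allowed
#' territory and the rest in core regions.
#'
#' @param n_additional Number of counted residues placed outside the core
#'   (default 3, i.e. 29/32 core).
#' @return A single-model `structure_ensemble`.
#' @export
build_smb_standin <- function(n_additional = 3) {
  seq <- smb_sequence()
  n <- nchar(seq)
  aa <- split_seq(seq)
  phi <- rep(-57, n); psi <- rep(-47, n)
  coil <- setdiff(which(!(seq_len(n) %in% c(6:21, 30:37))), c(1, n))
  phi[coil] <- -119; psi[coil] <- 113       # extended, core B
  counted_coil <- coil[!(aa[coil] %in% c("G", "P"))]
  off <- head(counted_coil, n_additional)   # push into additional-allowed
  phi[off] <- -75; psi[off] <- 70
  build_backbone(seq, phi = phi, psi = psi,
                 source_id = "synthetic SMB stand-in model")
}
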