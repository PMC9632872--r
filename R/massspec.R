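# Monoisotopic residue masses (Da, 5 decimals), cysteine counted reduced.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

MASS_WATER <- 18.010565
MASS_2H <- 2.015650  # lost per disulfide bond formed

#' Super Mini-B (SMB) peptide sequence
#'
#' The 41-residue surfactant protein B construct: the 7-residue N-terminal
#' insertion sequence followed by the Mini-B helix-hairpin, with cysteines
#' at positions 8, 11, 34 and 40 (native pairing Cys8-Cys40, Cys11-Cys34).
#' @return Single-letter character string, 41 residues.
#' @export
smb_sequence <- function() "FPIPLPYCWLCRALIKRIQAMIPKGGRMLPQLVCRLVLRCS"

split_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0)
    stop("sequence must be a nonempty single-letter string")
  strsplit(toupper(seq), "")[[1]]
}

#' Positions of cysteines in a sequence
#' @param seq Single-letter peptide string.
#' @return Increasing integer vector of 1-based positions.
#' @export
cys_positions <- function(seq) which(split_seq(seq) == "C")

#' Monoisotopic mass of a reduced peptide
#'
#' Sum of standard monoisotopic residue masses plus one water (18.010565 Da).
#'
#' @param seq Single-letter peptide string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("G")  # 75.03203
#' @export
monoisotopic_mass <- function(seq) {
  aa <- split_seq(seq)
  bad <- which(!(aa %in% names(AA_MONO)))
  if (length(bad))
    stop("unknown residue '", aa[bad[1]], "' at position ", bad[1])
  sum(AA_MONO[aa]) + MASS_WATER
}

#' Monoisotopic mass of an oxidized (disulfide-bonded) peptide
#'
#' Each disulfide removes two hydrogens (2.015650 Da).
#'
#' @param seq Single-letter peptide string.
#' @param n_ss Number of disulfide bonds formed.
#' @return Mass in Da.
#' @export
oxidized_mass <- function(seq, n_ss) {
  if (2 * n_ss > length(cys_positions(seq)))
    stop("sequence has too few cysteines for ", n_ss, " disulfide bonds")
  monoisotopic_mass(seq) - MASS_2H * n_ss
}

#' In-silico pepsin digest (pH 1.4 specificity)
#'
#' Cleaves after every Phe and Leu (the near-exclusive pepsin specificity at
#' pH 1.4, which leaves disulfides intact), optionally suppressing cleavage
#' when the next residue is proline. Returns all products with at most
#' `max_missed` missed cleavages, deduplicated by span.
#'
#' @param seq Single-letter peptide string.
#' @param max_missed Maximum missed cleavages (default 2, tolerant of
#'   incomplete digestion of a short peptide).
#' @param block_before_proline Suppress cleavage before Pro (default off).
#' @return Data frame with `start`, `end` (1-based inclusive), `sequence`,
#'   `missed`, `mono_mass` (reduced form).
#' @export
pepsin_digest <- function(seq, max_missed = 2, block_before_proline = FALSE) {
  aa <- split_seq(seq)
  n <- length(aa)
  sites <- which(aa %in% c("F", "L"))
  sites <- sites[sites < n]
  if (block_before_proline) sites <- sites[aa[sites + 1] != "P"]
  bounds <- c(0, sites, n)  # fragment i spans bounds[i]+1 .. bounds[i+1]
  rows <- list()
  nb <- length(bounds)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):min(nb, i + 1 + max_missed)) {
      st <- bounds[i] + 1; en <- bounds[j]
      sub <- substr(seq, st, en)
      rows[[length(rows) + 1]] <- data.frame(
        start = st, end = en, sequence = sub,
        missed = j - i - 1, mono_mass = monoisotopic_mass(sub),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
}

#' Enumerate all disulfide connectivity hypotheses
#'
#' All perfect matchings of the cysteine positions into unordered pairs;
#' there are (2k)!/(k! 2^k) of them (three for four cysteines).
#'
#' @param cys Increasing integer vector of cysteine positions (even count).
#' @return List of k x 2 matrices, each row one Cys-Cys pair.
#' @export
enumerate_pairings <- function(cys) {
  n <- length(cys)
  if (n %% 2 != 0) stop("odd number of cysteines cannot be fully paired")
  if (n == 0) return(list(matrix(integer(0), 0, 2)))
  rec <- function(pos) {
    if (length(pos) == 0) return(list(matrix(integer(0), 0, 2)))
    a <- pos[1]
    out <- list()
    for (b in pos[-1]) {
      rest <- setdiff(pos, c(a, b))
      for (sub in rec(rest))
        out[[length(out) + 1]] <- rbind(c(a, b), sub)
    }
    out
  }
  rec(cys)
}

pairing_label <- function(pairing) {
  paste(apply(pairing, 1, function(p)
    sprintf("Cys-%d-Cys-%d", p[1], p[2])), collapse = " / ")
}

#' Theoretical digest species under a connectivity hypothesis
#'
#' Enumerates single fragments and disjoint fragment pairs consistent with
#' the hypothesis: a species is emitted when no disulfide bond crosses its
#' boundary (every bonded cysteine inside is bonded inside), with the mass
#' decremented 2.015650 Da per internal bond. Two-fragment species require
#' at least one bond linking the two fragments; both pairs linking the same
#' two fragments aggregate into one species.
#'
#' @param fragments Data frame from [pepsin_digest()].
#' @param pairing A k x 2 matrix of cysteine-position pairs (one hypothesis
#'   over the parent peptide's cysteines).
#' @return Data frame with `frag_a`, `frag_b` (NA for single-fragment
#'   species), `span`, `n_ss`, `mono_mass`.
#' @export
theoretical_species <- function(fragments, pairing) {
  fr <- fragments
  nf <- nrow(fr)
  inside <- function(pos, i) pos >= fr$start[i] & pos <= fr$end[i]
  if (nrow(pairing) > 0) {
    allpos <- as.integer(pairing)
    covered <- vapply(allpos, function(p) any(p >= fr$start & p <= fr$end),
                      logical(1))
    if (!all(covered))
      stop("cysteine position ", allpos[!covered][1],
           " falls outside every fragment")
  }
  bonds_in_set <- function(idx) {
    # classify each bond: 0 ends in set, 1 end (crossing), or 2 ends (internal)
    if (nrow(pairing) == 0)
      return(list(internal = 0L, crossing = FALSE, linking = 0L))
    in_a <- apply(pairing, 1, function(p) any(vapply(idx, inside, logical(1), pos = p[1])))
    in_b <- apply(pairing, 1, function(p) any(vapply(idx, inside, logical(1), pos = p[2])))
    internal <- sum(in_a & in_b)
    crossing <- any(xor(in_a, in_b))
    linking <- if (length(idx) == 2)
      sum(apply(pairing, 1, function(p)
        (inside(p[1], idx[1]) && inside(p[2], idx[2])) ||
        (inside(p[1], idx[2]) && inside(p[2], idx[1])))) else 0L
    list(internal = internal, crossing = crossing, linking = linking)
  }
  rows <- list()
  for (i in seq_len(nf)) {
    b <- bonds_in_set(i)
    if (b$crossing) next
    rows[[length(rows) + 1]] <- data.frame(
      frag_a = i, frag_b = NA_integer_,
      span = sprintf("%d-%d", fr$start[i], fr$end[i]),
      n_ss = b$internal,
      mono_mass = fr$mono_mass[i] - MASS_2H * b$internal,
      stringsAsFactors = FALSE)
  }
  if (nf >= 2) for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    if (fr$start[j] <= fr$end[i] && fr$start[i] <= fr$end[j]) next  # overlap
    b <- bonds_in_set(c(i, j))
    if (b$crossing || b$linking == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      frag_a = i, frag_b = j,
      span = sprintf("%d-%d+%d-%d", fr$start[i], fr$end[i],
                     fr$start[j], fr$end[j]),
      n_ss = b$internal,
      mono_mass = fr$mono_mass[i] + fr$mono_mass[j] - MASS_2H * b$internal,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out$span), , drop = FALSE]
}

#' Infer disulfide connectivity from observed digest masses
#'
#' Scores every pairing hypothesis by matching its theoretical digest
#' species against the observed neutral monoisotopic masses (greedy unique
#' matching, best ppm first, each observed mass and each species consumed
#' once). Hypotheses are ranked by matches (descending), then mean absolute
#' ppm error (ascending); exact ties are flagged ambiguous, all-zero scores
#' inconclusive.
#'
#' @param seq Single-letter parent peptide string.
#' @param observed_masses Numeric vector of neutral monoisotopic masses (Da).
#' @param tol_ppm Match tolerance in ppm (default 10).
#' @param max_missed Missed cleavages for the in-silico digest.
#' @param block_before_proline Passed to [pepsin_digest()].
#' @return Object of class `connectivity_report`: list with `ranking` (data
#'   frame: `pairing`, `n_matched`, `score`, `mean_abs_ppm`), `matches`
#'   (per-hypothesis data frames), `status` ("ok", "ambiguous" or
#'   "inconclusive").
#' @export
infer_connectivity <- function(seq, observed_masses, tol_ppm = 10,
                               max_missed = 2, block_before_proline = FALSE) {
  if (length(observed_masses) < 1) {
    hyps <- enumerate_pairings(cys_positions(seq))
    ranking <- data.frame(pairing = vapply(hyps, pairing_label, character(1)),
                          n_matched = 0L, score = 0,
                          mean_abs_ppm = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(ranking = ranking, matches = list(),
                          status = "inconclusive"),
                     class = "connectivity_report"))
  }
  fr <- pepsin_digest(seq, max_missed = max_missed,
                      block_before_proline = block_before_proline)
  hyps <- enumerate_pairings(cys_positions(seq))
  score_one <- function(pairing) {
    sp <- theoretical_species(fr, pairing)
    cand <- expand.grid(obs = seq_along(observed_masses),
                        th = seq_len(nrow(sp)))
    cand$ppm <- (observed_masses[cand$obs] - sp$mono_mass[cand$th]) /
      sp$mono_mass[cand$th] * 1e6
    cand <- cand[abs(cand$ppm) <= tol_ppm, , drop = FALSE]
    cand <- cand[order(abs(cand$ppm)), , drop = FALSE]
    used_obs <- logical(length(observed_masses))
    used_th <- logical(nrow(sp))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      o <- cand$obs[k]; t <- cand$th[k]
      if (used_obs[o] || used_th[t]) next
      used_obs[o] <- used_th[t] <- TRUE
      keep[k] <- TRUE
    }
    m <- cand[keep, , drop = FALSE]
    data.frame(observed = observed_masses[m$obs],
               theoretical = sp$mono_mass[m$th],
               ppm = m$ppm, species = sp$span[m$th],
               n_ss = sp$n_ss[m$th], stringsAsFactors = FALSE)
  }
  matches <- lapply(hyps, score_one)
  ranking <- data.frame(
    pairing = vapply(hyps, pairing_label, character(1)),
    n_matched = vapply(matches, nrow, integer(1)),
    score = vapply(matches, nrow, integer(1)) / length(observed_masses),
    mean_abs_ppm = vapply(matches, function(m)
      if (nrow(m)) mean(abs(m$ppm)) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(-ranking$n_matched, ranking$mean_abs_ppm)
  ranking <- ranking[ord, , drop = FALSE]
  matches <- matches[ord]
  rownames(ranking) <- NULL
  status <- if (all(ranking$n_matched == 0)) "inconclusive"
  else if (nrow(ranking) > 1 &&
           ranking$n_matched[1] == ranking$n_matched[2] &&
           isTRUE(all.equal(ranking$mean_abs_ppm[1], ranking$mean_abs_ppm[2])))
    "ambiguous" else "ok"
  structure(list(ranking = ranking, matches = matches, status = status),
            class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("disulfide connectivity report (", x$status, ")\n", sep = "")
  print(x$ranking)
  if (x$status == "ok")
    cat("winning pairing:", x$ranking$pairing[1], "\n")
  invisible(x)
}
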