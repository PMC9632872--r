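# Independent oracles, kept deliberately separate from the package's own
# formulations.

# Dihedral via the atan2-of-plane-normals formulation.
dihedral_oracle <- function(p1, p2, p3, p4) {
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- xp(b1, b2); n2 <- xp(b2, b3)
  u2 <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(xp(n1, n2) * u2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Monoisotopic peptide mass from elemental composition (residue formulas
# C/H/N/O/S), independent of the package's residue-mass table.
elemental_mass_oracle <- function(seq) {
  em <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
          O = 15.9949146221, S = 31.97207069)
  # residue (amino acid minus water) compositions: C, H, N, O, S
  comp <- list(
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
  aa <- strsplit(seq, "")[[1]]
  tot <- Reduce(`+`, comp[aa]) + c(0, 2, 0, 1, 0)  # plus one water
  sum(tot * em[c("C", "H", "N", "O", "S")])
}

# Horn quaternion-method superposition: optimal RMSD mapping B onto A.
quaternion_rmsd_oracle <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  S <- t(B0) %*% A0
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
  resid <- A0 - B0 %*% t(R)
  sqrt(mean(rowSums(resid^2)))
}

# Brute-force count of perfect matchings over 2k labelled points.
matching_count_oracle <- function(k) {
  if (k == 0) return(1)
  factorial(2 * k) / (factorial(k) * 2^k)
}

random_points <- function(n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 3), n, 3)
}

random_rigid <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(R = R, t = stats::rnorm(3, sd = 5))
}

apply_rigid <- function(pts, rig) {
  pts %*% t(rig$R) + matrix(rig$t, nrow(pts), 3, byrow = TRUE)
}

# Disulfide strain energy evaluated straight from the printed cosine series.
katz_oracle <- function(ch) {
  co <- c(8.37, 8.37, 4.18, 4.18)
  mult <- c(3, 3, 3, 3)
  e <- sum(co * (1 + cos(mult * ch[1:4] * pi / 180)))
  e + 14.64 * (1 + cos(2 * ch[5] * pi / 180)) +
    2.51 * (1 + cos(3 * ch[5] * pi / 180))
}

# Chi torsions and S-S distance of a two-cysteine model, via the oracle
# dihedral, from whatever coordinates a file actually carries.
disulfide_oracle <- function(ens, model = 1) {
  pa <- sapofold::select_atoms(ens, model, "A", 1, c("N", "CA", "CB", "SG"))
  pb <- sapofold::select_atoms(ens, model, "A", 2, c("N", "CA", "CB", "SG"))
  ch <- c(dihedral_oracle(pa[1, ], pa[2, ], pa[3, ], pa[4, ]),
          dihedral_oracle(pb[1, ], pb[2, ], pb[3, ], pb[4, ]),
          dihedral_oracle(pa[2, ], pa[3, ], pa[4, ], pb[4, ]),
          dihedral_oracle(pb[2, ], pb[3, ], pb[4, ], pa[4, ]),
          dihedral_oracle(pa[3, ], pa[4, ], pb[4, ], pb[3, ]))
  list(chi = ch, ss = sqrt(sum((pa[4, ] - pb[4, ])^2)),
       energy = katz_oracle(ch))
}
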