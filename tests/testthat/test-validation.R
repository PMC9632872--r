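test_that("phi_psi recovers construction torsions and handles termini", {
  bb <- build_backbone("AAAAAAAAAA", phi = -57, psi = -47)
  pp <- phi_psi(bb, 1, "A")
  expect_true(all(abs(pp$phi[-1] + 57) < 0.5))
  expect_true(all(abs(pp$psi[-10] + 47) < 0.5))
  expect_true(is.na(pp$phi[1]) && is.na(pp$psi[10]))
  two <- build_backbone("AA", phi = -57, psi = -47)
  pp2 <- phi_psi(two, 1, "A")
  expect_true(is.na(pp2$phi[1]) && is.na(pp2$psi[2]))
  ext <- build_backbone("AAAAA", phi = 180, psi = 180)
  pe <- phi_psi(ext, 1, "A")
  expect_equal(abs(pe$phi[3]), 180, tolerance = 1e-6)
  expect_equal(abs(pe$psi[3]), 180, tolerance = 1e-6)
})

test_that("classify_rama places canonical conformations and mixed summaries add up", {
  expect_equal(classify_rama(-57, -47), "core")     # alpha (A)
  expect_equal(classify_rama(-119, 113), "core")    # beta (B)
  expect_false(classify_rama(60, 60) == "core")     # left-handed territory
  expect_true(is.na(classify_rama(NA, 10)))
  # mixed fixture: 3 of 4 counted residues in core -> 75.0
  seqs <- "AAAAAA"
  phi <- c(-57, -57, -57, -57, -75, -57)
  psi <- c(-47, -47, -47, -47, 70, -47)
  ens <- build_backbone(seqs, phi = phi, psi = psi)
  rs <- rama_summary(ens, 1)
  expect_equal(rs$n_counted, 4)
  expect_equal(rs$pct[["core"]], 75.0)
  expect_equal(sum(rs$pct), 100, tolerance = 0.1)
})

test_that("rama_summary follows Procheck counting: Gly, Pro and termini excluded", {
  ens <- build_backbone("AAPGAAA", phi = -57, psi = -47)
  rs <- rama_summary(ens, 1)
  expect_equal(rs$n_counted, 3)  # termini, Pro and Gly excluded
  expect_equal(rs$pct[["core"]], 100.0)
  all_core <- build_backbone("AAAAAAAA", phi = -57, psi = -47)
  expect_equal(rama_summary(all_core, 1)$pct[["core"]], 100.0)
})

test_that("kabsch_superpose is exact on rigid motions and optimal vs a quaternion oracle", {
  A <- random_points(10, 1)
  s0 <- kabsch_superpose(A, A)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  rig <- random_rigid(2)
  B <- apply_rigid(A, rig)
  s1 <- kabsch_superpose(A, B)
  expect_equal(s1$rmsd, 0, tolerance = 1e-9)
  expect_equal(s1$rotation %*% rig$R, diag(3), tolerance = 1e-9)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-9)
  for (seed in 1:50) {
    A <- random_points(10, seed)
    B <- random_points(10, seed + 1000)
    s <- kabsch_superpose(A, B)
    expect_equal(s$rmsd, quaternion_rmsd_oracle(A, B), tolerance = 1e-9)
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("superposition RMSD is invariant under rigid motion of either input", {
  A <- random_points(12, 4); B <- random_points(12, 5)
  base <- kabsch_superpose(A, B)$rmsd
  for (seed in 6:9) {
    rig <- random_rigid(seed)
    expect_equal(kabsch_superpose(apply_rigid(A, rig), B)$rmsd, base,
                 tolerance = 1e-9)
    expect_equal(kabsch_superpose(A, apply_rigid(B, rig))$rmsd, base,
                 tolerance = 1e-9)
  }
  # optimality: no random rigid transform does better
  for (seed in 10:19) {
    rig <- random_rigid(seed)
    trial <- sqrt(mean(rowSums((A - apply_rigid(B, rig))^2)))
    expect_gte(trial, base - 1e-12)
  }
})

test_that("segment_rmsd maps ranges jointly and matches the oracle", {
  m1 <- build_backbone(strrep("A", 20), phi = -57, psi = -47)
  expect_equal(as.numeric(
    segment_rmsd(m1, list(c(1, 10), c(11, 20)), m1, list(c(1, 10), c(11, 20)))),
    0, tolerance = 1e-9)
  # a different conformation of the same length: joint superposition equals
  # a single Kabsch fit over the concatenated backbone atoms
  m2 <- build_backbone(strrep("A", 20), phi = c(rep(-57, 12), rep(-119, 8)),
                       psi = c(rep(-47, 12), rep(113, 8)))
  r <- segment_rmsd(m1, list(c(1, 10), c(11, 20)), m2, list(c(1, 10), c(11, 20)))
  A <- select_atoms(m1, 1, "A", 1:20, c("N", "CA", "C", "O"))
  B <- select_atoms(m2, 1, "A", 1:20, c("N", "CA", "C", "O"))
  expect_equal(as.numeric(r), quaternion_rmsd_oracle(A, B), tolerance = 1e-9)
  expect_gt(as.numeric(r), 0.5)
  # positional mapping across different numbering (offset second range)
  r2 <- segment_rmsd(m1, list(c(1, 10), c(11, 20)),
                     m2, list(c(1, 10), c(11, 20)),
                     atom_names = c("N", "CA", "C"))
  expect_true(is.finite(as.numeric(r2)))
  expect_error(segment_rmsd(m1, list(c(1, 10)), m2, list(c(1, 9))),
               "mapping error")
  expect_error(segment_rmsd(m1, list(c(1, 10), c(11, 20)), m2, list(c(1, 10))),
               "mapping error")
})

test_that("a displaced segment raises the RMSD by a hand-computable bound", {
  m1 <- build_backbone(strrep("A", 20), phi = -57, psi = -47)
  ens2 <- m1
  pts <- matrix(ens2$xyz[1, ], ncol = 3, byrow = TRUE)
  idx <- which(ens2$atom$resno >= 11)
  pts[idx, 1] <- pts[idx, 1] + 1            # shift segment 2 by 1 A
  ens2$xyz <- matrix(as.numeric(t(pts)), nrow = 1)
  r <- as.numeric(segment_rmsd(m1, list(c(1, 10), c(11, 20)),
                               ens2, list(c(1, 10), c(11, 20))))
  # optimal joint fit cannot beat the translation-only optimum
  # (half the atoms off by 1 A -> rmsd 0.5 after centering) and cannot
  # exceed the displacement split evenly
  expect_gt(r, 0.2)
  expect_lte(r, 0.5 + 1e-9)
  expect_equal(r, quaternion_rmsd_oracle(
    select_atoms(m1, 1, "A", 1:20, c("N", "CA", "C", "O")),
    select_atoms(ens2, 1, "A", 1:20, c("N", "CA", "C", "O"))),
    tolerance = 1e-9)
})

test_that("transform_ensemble applies the fitted rigid motion", {
  m1 <- build_backbone("AAAAAAAA", phi = -57, psi = -47)
  rig <- random_rigid(21)
  m2 <- m1
  pts <- apply_rigid(matrix(m2$xyz[1, ], ncol = 3, byrow = TRUE), rig)
  m2$xyz <- matrix(as.numeric(t(pts)), nrow = 1)
  A <- select_atoms(m1, 1, "A", 1:8, c("N", "CA", "C", "O"))
  B <- select_atoms(m2, 1, "A", 1:8, c("N", "CA", "C", "O"))
  sup <- kabsch_superpose(A, B)
  m2t <- transform_ensemble(m2, sup)
  expect_equal(m2t$xyz, m1$xyz, tolerance = 1e-6)
})
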