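test_that("torsion_angle matches the atan2-of-normals oracle on random quadruples", {
  set.seed(42)
  for (i in 1:50) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    mine <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(mine, dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  expect_equal(torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  expect_error(torsion_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
  expect_error(torsion_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "degenerate")
})

test_that("katz_energy reproduces its closed-form anchor points and bounds", {
  expect_equal(katz_energy(0, 0, 0, 0, 0), 84.50)
  expect_equal(katz_energy(60, 60, 60, 60, 90), 2.51)
  # parity: cosine series is even in every torsion
  set.seed(3)
  for (i in 1:20) {
    ch <- runif(5, -180, 180)
    expect_equal(katz_energy(ch[1], ch[2], ch[3], ch[4], ch[5]),
                 katz_energy(-ch[1], -ch[2], -ch[3], -ch[4], -ch[5]))
    expect_gte(katz_energy(ch[1], ch[2], ch[3], ch[4], ch[5]), 0)
    expect_lte(katz_energy(ch[1], ch[2], ch[3], ch[4], ch[5]), 84.50)
  }
})

test_that("the global strain minimum sits near |chi3| = 83 deg at about 2.04 kJ/mol", {
  # the chi1/chi1'/chi2/chi2' terms vanish independently at staggered
  # angles; a coarse 5D grid confirms the minimum basin is there
  g <- seq(-180, 165, by = 15)
  coarse <- expand.grid(c1 = g, c3 = g)
  emin_c <- min(katz_energy(coarse$c1, coarse$c1, coarse$c1, coarse$c1, coarse$c3))
  # fine 1D grid over chi3 with the other torsions staggered
  chi3 <- seq(-180, 180, by = 0.01)
  e <- katz_energy(60, 60, 60, 60, chi3)
  emin <- min(e)
  expect_lt(abs(emin - 2.04), 0.01)
  expect_lte(emin, emin_c + 1e-9)
  expect_lt(abs(abs(chi3[which.min(e)]) - 83), 1)
})

test_that("find_disulfides pairs SG atoms greedily under the distance cutoff", {
  fx <- build_disulfide_fixture(-60, -60, 80, 80, 95)      # S-S 2.05 A
  found <- find_disulfides(fx, 1)
  expect_equal(nrow(found), 1)
  expect_equal(found$ss_distance, 2.05, tolerance = 1e-9)
  far <- build_disulfide_fixture(-60, -60, 80, 80, 95, ss_len = 3.5)
  expect_equal(nrow(find_disulfides(far, 1)), 0)
  # cysteine lacking SG is skipped with a warning
  broken <- fx
  keep <- !(broken$atom$resno == 2 & broken$atom$elety == "SG")
  broken <- make_ensemble(broken$atom[keep, ],
                          broken$xyz[1, rep(keep, each = 3)])
  expect_warning(out <- find_disulfides(broken, 1), "lacks an SG")
  expect_equal(nrow(out), 0)
})

test_that("disulfide_geometry inverts the fixture construction", {
  specs <- list(c(-60, -60, 80, 80, 95), c(-60, 60, -85, 100, -85),
                c(45, -170, 10, -10, 120))
  for (s in specs) {
    fx <- build_disulfide_fixture(s[1], s[2], s[3], s[4], s[5])
    g <- disulfide_geometry(fx, 1, "A", 1, "A", 2)
    expect_equal(c(g$chi1, g$chi1p, g$chi2, g$chi2p, g$chi3), s,
                 tolerance = 1e-6)
    expect_equal(g$ss_distance, 2.05, tolerance = 1e-9)
    expect_equal(g$energy, katz_energy(s[1], s[2], s[3], s[4], s[5]),
                 tolerance = 1e-6)
  }
})

test_that("swapping the pair swaps primed and unprimed torsions, E invariant", {
  fx <- build_disulfide_fixture(-55, 170, 75, -90, 100)
  g1 <- disulfide_geometry(fx, 1, "A", 1, "A", 2)
  g2 <- disulfide_geometry(fx, 1, "A", 2, "A", 1)
  expect_equal(g1$energy, g2$energy, tolerance = 1e-9)
  expect_equal(g1$ss_distance, g2$ss_distance, tolerance = 1e-12)
  expect_equal(g1$chi1, g2$chi1p, tolerance = 1e-9)
  expect_equal(g1$chi2, g2$chi2p, tolerance = 1e-9)
  expect_equal(abs(g1$chi3), abs(g2$chi3), tolerance = 1e-9)
})

test_that("ensemble_stats uses leading models with sample SD, zero for one model", {
  single <- build_disulfide_fixture(-60, -60, 80, 80, 95)
  st1 <- ensemble_stats(single, "A", 1, "A", 2)
  expect_equal(st1$n_models, 1)
  expect_equal(st1$sd_energy, 0)
  expect_equal(st1$mean_energy, katz_energy(-60, -60, 80, 80, 95),
               tolerance = 1e-6)
  # ten distinct conformers: mean/sd must equal direct statistics
  chis <- seq(-80, -35, by = 5)
  ens <- stack_models(lapply(chis, function(ch)
    build_disulfide_fixture(ch, -60, 80, 80, 95)))
  st <- ensemble_stats(ens, "A", 1, "A", 2, n_lowest = 10)
  ee <- katz_energy(chis, -60, 80, 80, 95)
  expect_equal(st$mean_energy, mean(ee), tolerance = 1e-6)
  expect_equal(st$sd_energy, sd(ee), tolerance = 1e-6)
  # n_lowest restricts to the first models in file order
  st5 <- ensemble_stats(ens, "A", 1, "A", 2, n_lowest = 5)
  expect_equal(st5$mean_energy, mean(ee[1:5]), tolerance = 1e-6)
  # degenerate ensemble of identical copies has sd exactly 0
  same <- stack_models(replicate(10, single, simplify = FALSE))
  expect_equal(ensemble_stats(same, "A", 1, "A", 2)$sd_energy, 0)
})

test_that("strain_table emits one formatted row per detected pair", {
  e1 <- build_disulfide_fixture(-60, -60, 80, 80, 95)
  e2 <- build_disulfide_fixture(50, 50, -70, -70, -100)
  tab <- strain_table(list(e1, e2), labels = c("fix1", "fix2"))
  expect_s3_class(tab, "strain_table")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$energy,
               c(katz_energy(-60, -60, 80, 80, 95),
                 katz_energy(50, 50, -70, -70, -100)), tolerance = 1e-6)
  expect_match(tab$energy_label[1], "^\\d+\\.\\d{6}$")
  empty <- strain_table(list())
  expect_equal(nrow(empty), 0)
})
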