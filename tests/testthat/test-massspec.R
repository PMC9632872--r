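test_that("monoisotopic masses match an elemental-composition oracle", {
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("GG"), 132.05349, tolerance = 1e-4)
  for (s in c("G", "GG", "ACDEFGHIKLMNPQRSTVWY", smb_sequence()))
    expect_equal(monoisotopic_mass(s), elemental_mass_oracle(s),
                 tolerance = 1e-3)
  expect_error(monoisotopic_mass(""), "nonempty")
  expect_error(monoisotopic_mass("AZB"), "position 2")
})

test_that("mass additivity: concatenation loses one water", {
  set.seed(12)
  aa <- names(sapofold:::AA_MONO)
  for (i in 1:10) {
    s1 <- paste(sample(aa, 6, replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    expect_equal(monoisotopic_mass(paste0(s1, s2)),
                 monoisotopic_mass(s1) + monoisotopic_mass(s2) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("each disulfide removes exactly two hydrogens", {
  expect_equal(oxidized_mass("ACCA", 0), monoisotopic_mass("ACCA"))
  expect_equal(oxidized_mass("CC", 1), monoisotopic_mass("CC") - 2.015650)
  expect_equal(oxidized_mass(smb_sequence(), 2),
               monoisotopic_mass(smb_sequence()) - 4.031300)
  expect_error(oxidized_mass("CC", 2), "too few cysteines")
})

test_that("pepsin digest cleaves after Phe and Leu with missed-cleavage control", {
  f0 <- pepsin_digest("AAAA", max_missed = 0)
  expect_equal(nrow(f0), 1)
  expect_equal(f0$sequence, "AAAA")
  f1 <- pepsin_digest("AFAA", max_missed = 0)
  expect_equal(f1$sequence, c("AF", "AA"))
  f2 <- pepsin_digest("CWLC", max_missed = 0)
  expect_equal(f2$sequence, c("CWL", "C"))
  # completeness: zero-missed fragments tile the parent exactly
  for (s in c("AFAA", "CWLC", smb_sequence())) {
    fr <- pepsin_digest(s, max_missed = 0)
    expect_equal(fr$start, c(1, head(fr$end, -1) + 1))
    expect_equal(fr$end[nrow(fr)], nchar(s))
    expect_equal(paste(fr$sequence, collapse = ""), s)
  }
  # missed cleavages add merged spans, deduplicated
  fm <- pepsin_digest("AFAFA", max_missed = 1)
  expect_true("AFAF" %in% fm$sequence)
  expect_false(any(duplicated(fm[, c("start", "end")])))
  # proline blocking suppresses F|P and L|P sites
  fp <- pepsin_digest("AFPA", max_missed = 0, block_before_proline = TRUE)
  expect_equal(fp$sequence, "AFPA")
  # terminal F/L is not a site
  expect_equal(nrow(pepsin_digest("AAF", max_missed = 0)), 1)
})

test_that("pairing enumeration follows the (2k)!/(k! 2^k) law", {
  expect_equal(length(enumerate_pairings(c(8, 40))), 1)
  expect_equal(length(enumerate_pairings(c(8, 11, 34, 40))), 3)
  expect_equal(length(enumerate_pairings(1:6)), 15)
  for (k in 1:4) {
    hyps <- enumerate_pairings(seq_len(2 * k))
    expect_equal(length(hyps), matching_count_oracle(k))
    # all matchings distinct and each a perfect matching
    canon <- vapply(hyps, function(h)
      paste(apply(t(apply(h, 1, sort)), 1, paste, collapse = "-")[
        order(apply(h, 1, min))], collapse = "|"), character(1))
    expect_false(any(duplicated(canon)))
    for (h in hyps) expect_setequal(as.integer(h), seq_len(2 * k))
  }
  expect_error(enumerate_pairings(1:3), "odd")
})

test_that("theoretical species apply the per-bond mass decrement correctly", {
  # intra-fragment bond: single species, mass - 2.01565
  fr <- pepsin_digest("ACCA", max_missed = 0)
  sp <- theoretical_species(fr, rbind(c(2, 3)))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$mono_mass, monoisotopic_mass("ACCA") - 2.015650)
  # cross-fragment bond joins two fragments
  fr2 <- pepsin_digest("CWLC", max_missed = 0)
  sp2 <- theoretical_species(fr2, rbind(c(1, 4)))
  cross <- sp2[!is.na(sp2$frag_b), ]
  expect_equal(nrow(cross), 1)
  expect_equal(cross$mono_mass,
               monoisotopic_mass("CWL") + monoisotopic_mass("C") - 2.015650)
  # no unbonded-cysteine fragments leak through
  expect_false(any(is.na(sp2$frag_b) & grepl("C", fr2$sequence[sp2$frag_a])))
})

test_that("the SMB digest under the native pairing yields the two crosslinked pairs", {
  fr <- pepsin_digest(smb_sequence(), max_missed = 0)
  sp <- theoretical_species(fr, rbind(c(8, 40), c(11, 34)))
  cross <- sp[!is.na(sp$frag_b), ]
  expect_equal(nrow(cross), 2)
  expect_setequal(cross$span, c("6-10+39-41", "11-14+33-36"))
  expect_equal(cross$n_ss, c(1, 1))
})

test_that("connectivity inference recovers the generating hypothesis", {
  seq <- smb_sequence()
  true <- rbind(c(8, 40), c(11, 34))
  label <- "Cys-8-Cys-40 / Cys-11-Cys-34"
  # noise-free self-consistency
  obs0 <- synth_digest_observations(seq, true, ppm_jitter = 0, seed = 1)
  r0 <- infer_connectivity(seq, obs0)
  expect_equal(r0$ranking$pairing[1], label)
  expect_equal(r0$ranking$score[1], 1.0)
  # 5 ppm jitter over 20 seeds
  for (s in 1:20) {
    obs <- synth_digest_observations(seq, true, ppm_jitter = 5, seed = s)
    r <- infer_connectivity(seq, obs, tol_ppm = 10)
    expect_equal(r$ranking$pairing[1], label)
    expect_equal(r$status, "ok")
  }
  # observations matching nothing -> inconclusive, scores zero
  rbad <- infer_connectivity(seq, c(100.0, 200.0, 300.0))
  expect_equal(rbad$status, "inconclusive")
  expect_true(all(rbad$ranking$score == 0))
  rempty <- infer_connectivity(seq, numeric(0))
  expect_equal(rempty$status, "inconclusive")
})
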