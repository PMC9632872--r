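---
title: "Methods: structural analysis of disulfide-stabilized saposin-fold peptides"
author: "sapofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural analysis of disulfide-stabilized saposin-fold peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapofold)
```

## The scientific problem

Saposin-fold proteins — the saposins proper, NK-lysin, granulysin, amoebapore
and lung surfactant protein B (SP-B) — share a helix-hairpin architecture in
which N- and C-terminal amphipathic helices are clamped together by a
stereotyped pair of disulfide bridges: the cysteines nearest the termini pair
with each other, and so do the two inner cysteines. Synthetic surfactant
peptides such as Super Mini-B (SMB), a 41-residue SP-B construct with
cysteines at positions 8, 11, 34 and 40, are designed to emulate this fold.
Because no high-resolution experimental structure of such constructs exists,
their characterization is integrative: disulfide connectivity from
proteolytic mass spectrometry, residue-specific secondary structure from
isotope-edited FTIR, overall helicity from CD, and geometric validation of
the resulting models. sapofold implements every quantitative step of that
workflow on plain data structures, with seeded generators that produce
synthetic versions of all required inputs.

## Disulfide dihedral strain

A cystine bridge has five torsions: chi1 = N–CA–CB–SG and chi1' on the
partner, chi2 = CA–CB–SG–SG' and chi2', and chi3 = CB–SG–SG'–CB' across the
S–S bond. The Katz–Kossiakoff empirical strain estimate is the cosine series

E = 8.37(1+cos 3chi1) + 8.37(1+cos 3chi1') + 4.18(1+cos 3chi2)
  + 4.18(1+cos 3chi2') + 14.64(1+cos 2chi3) + 2.51(1+cos 3chi3)  [kJ/mol]

Each term is nonnegative, so 0 ≤ E ≤ 84.50 (the bound is attained with every
torsion at 0). The chi1/chi2 terms vanish at staggered angles, but the two
chi3 terms cannot vanish simultaneously; a fine grid shows the global
minimum near |chi3| = 83 degrees at about 2.04 kJ/mol:

```{r katz}
katz_energy(0, 0, 0, 0, 0)
katz_energy(60, 60, 60, 60, 90)
chi3 <- seq(-180, 180, by = 0.01)
min(katz_energy(60, 60, 60, 60, chi3))
```

`find_disulfides()` pairs CYS SG atoms greedily by ascending distance under a
2.3 Å default cutoff (covalent S–S is about 2.05 Å; the margin absorbs
coordinate noise, and each SG joins at most one bridge).
`ensemble_stats()` summarizes a pair over the first ten models of a
multi-model file with a sample (n−1) standard deviation. NMR depositions
carry no per-model energies, so "lowest-energy conformers" is operationalized
as leading file order, the convention by which ensembles are deposited
best-first; `n_lowest` is configurable. Torsions are degrees at every
interface (radians only inside trigonometric evaluation), and the torsion
sign convention is IUPAC, verified against an independent implementation to
1e-12 degrees.

## Helix-axis geometry

Local helix axes use the HELANAL construction: for each window of four
consecutive CA atoms, the axis is the unit cross product of the two second
differences of the positions, oriented along the chain. The global axis is
the normalized mean of the local axes; the angle between two helices is the
undirected line angle acos(|u·v|) in [0, 90] degrees, because hairpin
helices run antiparallel and a directed angle would read near 180 degrees
for an almost-parallel hairpin. Segment boundaries are user inputs (they
come from experimental assignments), never auto-detected.

On ideal helices the local-axis construction is exact by geometry. The
principal-component axis of the raw CA cloud, often used as a cross-check,
is itself biased for short helices: a fraction of a turn of unbalanced
radial positions tilts the first principal component by several degrees at
8–12 residues. The cross-method agreement test therefore uses helices of at
least five full turns, where the two axes agree to better than 2 degrees.

## Model validation

`phi_psi()` measures backbone torsions (phi from the preceding carbonyl
carbon, psi from the following amide nitrogen; termini undefined on the
missing side). `classify_rama()` looks the pair up in an embedded
10-degree-resolution region map composed of rectangles following the
Morris/Procheck classification: most-favoured "core" regions A (alpha),
B (beta) and L (left-handed alpha), surrounded by additional-allowed and
generous rings. The map is a faithful rectangle rendering, not the original
Procheck masks, so classifications within about one grid cell of a region
boundary may differ from Procheck's; summaries are quoted with a one-residue
tolerance for that reason. `rama_summary()` counts with the Procheck
convention — glycine, proline and chain-terminal residues excluded — and for
a 41-residue construct that leaves 32 counted residues, which is why core
percentages appear in steps of 1/32 (29/32 = 90.6%).

`kabsch_superpose()` computes the optimal proper rotation by SVD with
reflection correction; degenerate (collinear) inputs are refused.
`segment_rmsd()` maps residue ranges positionally (no sequence alignment —
the use case is stated residue ranges of homologous constructs), selects the
backbone atoms N, CA, C, O (configurable), and performs one joint
superposition over all segments, returning the global RMSD. The suite pins
the result to an independent quaternion-method (Horn) oracle at 1e-9 Å.

## Mass-spectrometric connectivity mapping

Peptide masses are monoisotopic: residue masses to five decimals plus one
water (18.010565 Da); each disulfide removes two hydrogens (2.015650 Da).
Inputs are deconvoluted neutral monoisotopic masses — charge states and
isotope envelopes are upstream of this package.

In-silico pepsin digestion models the pH 1.4 specificity: cleavage after
every Phe and Leu, disulfides left intact. The common "no cleavage before
proline" refinement is available but off by default, implementing the
specificity exactly as stated for these conditions. Up to two missed
cleavages are kept by default, realistic for a 41-mer with nine sites.

Connectivity inference enumerates all perfect matchings of the cysteines
((2k)!/(k! 2^k) hypotheses; three for four cysteines) and, for each,
predicts the digest species: single fragments and disjoint fragment pairs
such that no disulfide crosses the species boundary, with the mass
decremented per internal bond. Observed masses are matched greedily (best
ppm first, each observation and each species consumed once, 10 ppm default
tolerance), and hypotheses are ranked by matches then mean |ppm|; ties are
reported ambiguous and zero-match results inconclusive. For SMB under the
native pairing the zero-missed digest yields exactly two crosslinked
species, one carrying Cys8–Cys40 and one Cys11–Cys34 — the fragments that
discriminate the three hypotheses.

## CD and isotope-edited FTIR

`mre()` converts measured ellipticity to mean residue ellipticity,
(theta × 100)/(l × C × N) with theta in millidegrees, l in cm, C in mM and N
residues. Secondary-structure deconvolution of CD spectra is out of scope;
only the unit conversion is provided.

For FTIR, the amide I band of an alpha-helix sits near 1654 cm⁻¹; replacing
backbone carbonyls with ¹³C shifts the labeled residues' band about 35–40
wavenumbers lower (to 1618–1619 cm⁻¹ for helical cassettes).
`find_band_max()` smooths with a Savitzky–Golay filter (default window 7,
order 3) and refines the discrete maximum with a least-squares parabola over
a neighborhood of about one band FWHM (up to 21 points), clamped to that
neighborhood. The wider-than-3-point parabola is a deliberate numerical
choice: at a signal-to-noise ratio of 20 (band amplitude over rms noise),
3-point interpolation has a center standard error of roughly 0.6 cm⁻¹ and
cannot reliably deliver sub-wavenumber shifts, while the FWHM-scale fit is
unbiased for a symmetric band and recovers a constructed 36 cm⁻¹ shift
within 1 cm⁻¹ across seeded noise realizations. `isotope_shift()` accepts a
shifted band only when the labeled-minus-unlabeled difference spectrum gains
at least 20% of the unlabeled helix peak inside the shifted window (the
"increase in absorption near 1618 cm⁻¹" criterion); shifts of 30–45 cm⁻¹
are assigned alpha-helix, smaller genuine shifts fall into beta-sheet
overlap territory and are flagged ambiguous, and an absent shifted band
reports shift 0. Beta-sheet content is reported only qualitatively.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of its parameters and an explicit seed;
identical calls are bit-identical and the session RNG stream is left
untouched. Internal-coordinate (Z-matrix) placement is the single geometric
primitive, which guarantees exact realization of specified torsions:

* `build_ideal_helix()` — CA-only helices (rise 1.5 Å, twist 100°/residue,
  radius 2.3 Å, the canonical alpha-helix values) or full backbones chained
  at stated phi/psi with standard bond geometry and omega = 180.
* `build_hairpin()` — two CA helices at a requested undirected axis angle
  (the second running antiparallel, as in the fold), joined by a seeded coil
  linker; defaults emulate the construct's 16- and 8–10-residue helices.
* `build_disulfide_fixture()` — a two-cysteine chain realizing all five chi
  torsions exactly, with S–S 2.05 Å (the distance constraint used when such
  bridges are imposed on models), C–S 1.81 Å and 114/104-degree angles from
  standard stereochemistry.
* `gaussian_spectrum()` — Gaussian amide I bands (default sigma 8 cm⁻¹ on a
  1 cm⁻¹ grid over 1580–1720) plus seeded noise.
* `synth_digest_observations()` — theoretical digest species masses with
  seeded uniform ppm jitter and dropout.
* `build_smb_standin()` — a full-backbone model of the real SMB sequence
  with helical torsions over the experimentally assigned domains (6–21,
  30–37); it is a geometric stand-in, clearly synthetic, whose purpose is
  exercising the validation machinery at the construct's actual residue
  composition (32 counted residues, 29 of them in core regions).

These fixtures are idealized: real conformer ensembles have correlated
coordinate noise, side chains, helix fraying and solvent effects; real FTIR
bands are asymmetric overlapping mixtures; real digests contain
non-specific cleavages and adducts. Passing tests on these fixtures
therefore demonstrate correctness of the computations and their numerical
robustness at stated noise levels — not that the biological conclusions
would survive arbitrary experimental artifacts. Analyses of deposited PDB
entries require the user to supply the coordinate files; the package
deliberately contains no download client.

## Numerical choices and limitations

* PDB coordinates quantize at 1e-3 Å; through five torsions this moves a
  strain energy by up to ~0.02 kJ/mol, which bounds the agreement achievable
  between a file-based result and an exact closed form.
* Altloc resolution keeps the highest occupancy, ties broken by the
  alphabetically first label; hydrogens and waters are dropped; HETATM
  records are kept only for amino-acid residues.
* The problem sizes used by the test suite and the acceptance script
  (41-residue constructs, 10-model ensembles, 50 noise realizations,
  20 digest seeds, 0.01-degree 1-D energy grids) were chosen as the natural
  scale of the study design; everything runs in seconds.
* Degenerate inputs error early and descriptively: coincident/collinear
  torsion points, helices under four residues, cancelling local axes,
  collinear superposition inputs, odd cysteine counts, non-monotone spectra.
* Out of scope by design: MD refinement and trajectory analysis, structure
  prediction itself, CD deconvolution, MS/MS fragment analysis, Procheck's
  full validation suite, and automatic accession fetching.
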