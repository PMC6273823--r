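---
title: "Conceptual-DFT reactivity analysis of piperidone curcuminoid electrophiles"
author: "cdftkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conceptual-DFT reactivity analysis of piperidone curcuminoid electrophiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdftkit)
```

## The scientific problem

Monocarbonyl curcumin analogues built on an *N*-substituted
piperidin-4-one core are Michael acceptors: their biological activity is
driven by conjugate addition of cellular nucleophiles (above all thiols)
to the cross-conjugated dienone. Two questions decide how such a
molecule reacts. Globally, how strong an electrophile is it, and how
readily does it pick up an extra electron to form a radical anion?
Locally, does a nucleophile add 1,4 at the β-carbon (C7 in the
conventional numbering of the C7=C8–C9=O9 enone fragment) or 1,2 at the
carbonyl carbon (C9)?

cdftkit is the post-processing layer for answering those questions from
electronic-structure output. It deliberately does **not** run any
quantum chemistry: it consumes per-species records (energies, ZPVEs,
orbital energies and occupations, and optionally overlap/density/MO
matrices or pre-condensed populations) and turns them into the standard
conceptual-DFT reactivity quantities. A twelve-compound reference set —
the piperidone curcuminoids with H, 4-Cl, 4-Br, 4-NMe~2~, 4-CN and
4-CF~3~ aryl substituents crossed with *N*-methyl and *N*-benzyl — ships
as packaged tables, and a family of synthetic generators inverts every
analysis stage so the whole pipeline has exact ground truth at zero
compute cost.

## Global reactivity indices

From the frontier orbital energies (eV) of a closed-shell neutral the
package computes

$$\mathrm{GAP} = \varepsilon_L - \varepsilon_H,\qquad
\mu = \tfrac{1}{2}(\varepsilon_H + \varepsilon_L),\qquad
\eta = \tfrac{1}{2}(\varepsilon_L - \varepsilon_H),\qquad
\omega = \frac{\mu^2}{2\eta}.$$

Two conventions for the hardness coexist in the literature (with and
without the ½); the packaged reference table itself fixes the choice,
since its η column equals half its gap column. ω is always computed
from unrounded μ and η. The HOMO is the highest orbital with occupation
above a 0.5 threshold per spin orbital (1.0 for a restricted channel),
which makes the split robust to fractionally printed occupations; for
open-shell records the α channel defines the frontier, so the SOMO
plays the HOMO role.

```{r global}
gi <- global_reactivity(-6.01, -2.09)   # unsubstituted N-methyl compound
report_round(c(mu = gi$mu, eta = gi$eta, omega = gi$omega), 2)
```

Ranking the packaged table by ω reproduces the familiar substituent
order CN > CF~3~ > Cl = Br > H > NMe~2~ in both series; ω differences
below 0.005 eV (the Cl/Br congeners) are reported as tied ranks.

## Electron attachment bookkeeping

Radical-anion formation is characterized by three differences, all in
the "neutral minus anion" sign convention so that positive values mean
the anion lies lower:

* AEA = E(optimized neutral) − E(optimized anion), both ZPVE-corrected;
* VEA = E(optimized neutral) − E(anion at the neutral geometry);
* VDE = E(neutral at the anion geometry) − E(optimized anion).

Stationary-point energies are E = E~elec~ + ZPVE. Vertical species are
single points with no vibrational analysis, so the vertical quantities
use electronic energies only; this is equivalent to assigning the
parent stationary species' ZPVE to its vertical twin, and it is the
only self-consistent reading of a blanket "add ZPVE" rule, because no
ZPVE exists at a non-stationary geometry. The composite-basis protocol
(large-basis single-point energies on small-basis geometries, corrected
by the small-basis ZPVE) is a one-line sum, `composite_energy()`, with
its own level tag so records from the two levels never mix silently.

When neutral and anion geometries are similar, VEA ≤ AEA ≤ VDE.
`check_bounds()` verifies the bracket with 10⁻⁹ eV slack — pure float
noise, three orders below the 10⁻³ eV reporting precision. On the
packaged attachment table the bracket holds for 23 of 24 rows; the one
exception (compound 5 at the composite level, AEA 1.902 < VEA 2.181) is
shipped exactly as printed because every cross-check says it is a
transcription error in the source: it violates the bracket, and it sits
0.37 eV from its own *N*-benzyl congener while every other
methyl/benzyl pair differs by under 0.01 eV. The checker flags it; the
fixture does not "fix" it.

The packaged frontier-energy table carries one analogous anomaly: the
compound-6 GAP cell prints 3.84 where its own HOMO/LUMO difference is
3.77 — and its own hardness column (1.89 = 3.77/2) confirms that the
GAP cell, not the orbital energies, is the misprint. Recomputation is
expected to expose exactly that cell and reproduce the other eleven
rows within ±0.01 eV (±0.03 eV for ω, which absorbs the source's
mixed rounding of intermediate quantities).

## Condensed local indices and site selectivity

Site selectivity toward nucleophiles is read from two condensed
indices. The Fukui function for nucleophilic attack is the
finite-difference form on atomic charges at the fixed neutral geometry,

$$f^+_k = q_k(N) - q_k(N+1),$$

which sums to 1 over atoms (one added electron). The Parr function
$P^+$ is the atomic spin population of the radical anion — where the
just-attached electron sits — renormalized to unit sum by default. The
spin populations are taken at the anion's optimized geometry, because
that is the species the anion analysis optimizes; a vertical variant is
just a different input record. Condensation uses Mulliken populations
(`mulliken_populations()`: gross population of atom A is
$\sum_{\mu\in A}(\mathbf{PS})_{\mu\mu}$), the default scheme of the
mainstream quantum-chemistry codes; externally condensed charges from
any other scheme can be attached to records directly and flow through
unchanged.

`site_selectivity()` compares C7 against C9 with a tie threshold of
5×10⁻⁴, half a unit in the last printed digit of the three-decimal
report table. C7 preferred means 1,4- (conjugate) addition; C9
preferred means 1,2-addition. On the packaged table C7 wins in all
twelve rows for both indices, with the largest C7–C9 split for the
dimethylamino compounds and the smallest for the nitriles within each
series.

## Valence- versus dipole-bound anions

Whether the excess electron is spread over the molecular frame
(valence-bound) or held in a small region (dipole-bound) is diagnosed
from the SOMO's fragment composition: Mulliken weights of the orbital
over named fragments (piperidone ring, exo alkenes, aryl rings,
N-substituent). The packaged rule calls an anion dipole-bound when one
fragment carries ≥ 0.85 of the orbital and the runner-up < 0.10. These
thresholds are heuristic — the underlying physics is a continuum and
the literature diagnoses it from orbital pictures — so they are
explicit, configurable arguments, and the continuous
`delocalization_ratio()` (participation ratio over fragments,
normalized to 1 for uniform spread) is always reported alongside the
binary call. Small negative Mulliken weights, a known artifact of the
scheme, are reported raw but clipped to zero for classification.

## Hammett analysis

Substituent control of any descriptor (AEA, VEA, VDE, ω) is quantified
by ordinary least squares against Hammett σ~p~, in closed form with
R² = S²~xy~/(S~xx~S~yy~). The packaged σ~p~ values are the standard
Hansch–Leo–Taft compilation (H 0.00, Cl 0.23, Br 0.23, NMe~2~ −0.83,
CN 0.66, CF~3~ 0.54); because σ compilations differ in the second
decimal, reproducing a published R² is meaningful only to a few
hundredths, and the packaged checks use ±0.03. With these defaults the
small-basis AEAs of the *N*-methyl series give R² = 0.90 against a
reference value of 0.89. Plain (not adjusted) R² is used: series of
six compounds are compared descriptively, not inferentially.

```{r hammett}
t3 <- load_fixture("table3"); t1 <- load_fixture("table1")
b1 <- t3[t3$level_tag == "basis1", ]
hammett_screen(setNames(b1$aea_ev, b1$compound),
               setNames(t1$substituent, t1$compound),
               series = as.character(1:6))
```

## Torsion scans

The conformational stage mirrors the rotor analysis used to prepare the
*N*-benzyl scaffold: a rigid two-dihedral grid scan about the N11–C12
and C12–C(aryl) bonds. `set_dihedral()` partitions the molecule at the
rotated bond using covalent-radius connectivity (radii × 1.2, the
standard practical cutoff), refuses ring bonds, and applies a
rigid-body rotation, so every distance within the rotated group is
preserved exactly. `grid_scan()` evaluates a pluggable energy callback
over the full grid cross-product — the callback may wrap a
semiempirical or DFT engine, or one of the packaged analytic cosine
surfaces used in tests — and returns the argmin with ties broken
toward the lexicographically smallest angle pair. The default grid is
15° per dihedral (24 × 24 points), a common survey resolution;
refinement tests at 15°/5°/1° confirm the located minimum converges to
an off-grid analytic minimum at the grid-spacing rate. The scan is
rigid (no relaxation), so it brackets rotamers rather than ranking
them finely; no numeric anchor for the original scan exists, which is
why this stage is validated purely by analytic properties.

## Synthetic data: what it does and does not show

Every generator inverts its analysis stage: `make_orbital_record()`
builds a valid closed-shell record whose frontier extraction returns a
prescribed (HOMO, LUMO) pair; `make_species_quadruple()` builds four
records whose attachment energies equal prescribed (AEA, VEA, VDE);
`make_population_pair()` builds charge vectors whose Fukui difference
is a prescribed f⁺; `make_hammett_series()` draws
y = ρσ + c + N(0, sd); `make_mock_wavefunction()` draws a
positive-definite unit-diagonal overlap, S-orthonormal orbitals and the
corresponding density. Absolute energy origins are randomized under the
seed so no downstream test can pass by matching hard-coded absolutes,
and all generators are bit-reproducible given a seed while leaving the
global RNG stream untouched.

This design gives exact ground truth for the *bookkeeping* — sign
conventions, ZPVE placement, unit conversion, normalization,
conservation laws — which is precisely what a post-processing package
can get wrong. It does not emulate the physics of real DFT output:
basis-set incompleteness, scheme-dependence of condensed charges, or
correlated noise across compounds. Accordingly, the packaged reference
tables for the twelve real compounds are consistency anchors (internal
identities, orderings, correlations reproduced from their own printed
values), not recomputation targets: recomputing their absolute values
would require the original hybrid-functional optimizations and
frequency jobs on 40–60-atom molecules.

## Numerical choices

* Energies are Hartree internally; conversion to eV happens once, at
  reporting, through a single CODATA constant (27.211386245988 eV/Ha).
  The source tables' precision (0.01/0.001 eV) is far above any
  difference between conversion constants in circulation.
* Report rounding is half-away-from-zero (so −3.185 prints −3.19),
  implemented with a 9-decimal pre-round to keep binary representation
  error from flipping ties. The reference tables mix conventions in a
  few cells; the ±0.01 eV tolerances absorb this.
* Occupied/virtual split at occupation 0.5 per spin orbital; degenerate
  frontier orbitals are value-invariant by construction.
* Bound checks use 10⁻⁹ eV slack; Fukui normalization is enforced at
  10⁻⁶; Mulliken conservation at 10⁻⁸; MO normalization at 10⁻⁶ on
  cᵀSc.
* Closed-shell records store one spin channel (`closed`, occupations up
  to 2); open-shell records store `alpha`/`beta`. The channel name is
  the dialect flag, matching how mainstream QC codes print restricted
  versus unrestricted output.

## Problem sizes in the test suite

The property suites run on deliberately small objects: random
wavefunctions of 3–10 basis functions over 2–3 atoms (100 draws against
elementwise brute-force oracles), 100 synthetic quadruples, 200
Monte-Carlo Hammett replicates of six points, and torsion grids up to
360 × 360 points for the 1° refinement check. These sizes make every
oracle exactly computable and keep the default test run fast while
exercising each code path; nothing in the implementation is specific to
small systems — the matrix operations scale as ordinary dense linear
algebra in the basis dimension.

## Known limitations

* Only Mulliken condensation is implemented; Hirshfeld/NPA/Löwdin
  values must be condensed externally and attached to records.
* The dipole-bound heuristic is a threshold rule on fragment weights,
  not an electrostatics-based diagnosis; treat borderline calls as
  "inspect the orbital".
* Torsion scans are rigid; relaxed scans and gradient optimization are
  out of scope, as is any electronic-structure engine.
* f⁻/f⁰ Fukui variants, the condensed dual descriptor, σ⁺/σ⁻ scales
  and multi-parameter substituent fits are intentionally not provided.
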