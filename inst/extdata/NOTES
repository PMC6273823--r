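Packaged reference tables
=========================

table1.csv  compound roster: aromatic-ring substituent (para position)
            and N-substituent for the twelve piperidone curcuminoids.
table2.csv  frontier orbital energies and global reactivity indices
            (eV, 2 decimals) at the small-basis level.
table3.csv  adiabatic/vertical electron affinities and vertical
            detachment energies (eV, 3 decimals), tidy long form:
            basis1 = small basis, basis2_composite = large-basis single
            points on small-basis geometries with small-basis ZPVE.
table4.csv  condensed Fukui f+ and Parr P+ at the enone sites C7
            (beta carbon) and C9 (carbonyl carbon), 3 decimals.
sigma_p.csv default Hammett sigma_para values (Hansch-Leo-Taft
            compilation) for the substituents of table1.

All table values are shipped exactly as printed in the source tables.
Known anomaly, shipped as-is: in table2.csv the compound-6 GAP cell
(3.84) disagrees with the difference of its own HOMO/LUMO columns
(-2.59 - (-6.36) = 3.77) and with its own hardness column (1.89 =
3.77/2); every other column of that row is internally consistent, so
the GAP cell is the misprint. Recomputation is expected to flag it.
Known anomaly, shipped as-is: compound 5 at level basis2_composite has
AEA (1.902) below its own VEA (2.181), violating the physical ordering
VEA <= AEA <= VDE that every other row obeys, and sitting far from its
close analogue compound 11 (2.271). This is almost certainly a
transcription error in the source; the bounds checker is expected to
flag exactly this one cell. Do not "fix" the value here.

toy_enone_synthetic.xyz is a synthetic methyl-vinyl-ketone-like
geometry constructed from idealized bond lengths and angles (not taken
from any calculation); it exists so geometry-handling code and torsion
scans have a small realistic input.

mock_wavefunction.json is a pinned random-but-valid closed-shell
wavefunction (overlap, S-orthonormal MOs, density) for population
analysis round-trips.
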