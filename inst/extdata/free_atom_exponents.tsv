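# Exponents (zeta, 1/bohr) of the packaged single-exponential spherical
# free-atom model densities rho(r) = N * exp(-zeta * r), with N chosen so the
# density integrates to n_electrons. These are deliberately simple,
# valence-like Slater exponents: they define a self-contained, analytically
# integrable promolecule reference for Hirshfeld partitioning and for the
# synthetic fixture generator. They are NOT tabulated Hartree-Fock atomic
# densities; replace via free_atom_density(element, table = ...) for
# production-grade partitioning.
symbol	zeta
H	2.00
C	3.25
N	3.90
O	4.55
F	5.20
Na	2.20
Mg	2.60
P	3.30
S	3.60
Cl	3.90
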