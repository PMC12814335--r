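# Free-atom reference data for the Tkatchenko-Scheffler volume-scaling scheme.
# alpha_free: static dipole polarizability (a.u.); c6_free: homonuclear C6
# coefficient (hartree*bohr^6); r_vdw_free: free-atom vdW radius (bohr);
# n_electrons: electron count. Values are the standard Chu-Dalgarno-derived
# free-atom reference set used by TS-vdW implementations. User-overridable via
# load_element_params(path).
symbol	alpha_free	c6_free	r_vdw_free	n_electrons
H	4.50	6.50	3.10	1
C	12.00	46.60	3.59	6
N	7.40	24.20	3.34	7
O	5.40	15.60	3.19	8
F	3.80	9.52	3.04	9
Na	162.70	1556.00	3.73	11
Mg	71.00	627.00	4.22	12
P	25.00	185.00	4.01	15
S	19.60	134.00	3.86	16
Cl	15.00	94.60	3.71	17
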