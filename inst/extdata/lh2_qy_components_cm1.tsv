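# MD-averaged components of the Q_y site energies of the three symmetry-
# distinct BChl-a types in the LH2 antenna complex of Rhodoblastus
# acidophilus, as published for the polarizable QM/MMPol-cLR3 embedding
# scheme (200-snapshot averages, rounded to integer cm^-1).
# total_published is the independently published assembled site energy; it
# can differ from the sum of the rounded components by 1 cm^-1 because the
# publication averaged before rounding. assemble_clr3() recomputes totals
# from the components; total_published is kept for cross-checking only and
# is ignored by read_component_table().
# units: cm-1
label	frame	de_gs_pol	r_ss_pol	r_lr_disp	r_ss_disp	total_published
B850alpha	1	14214	-14	-714	235	13722
B850beta	1	14295	-14	-699	235	13816
B800gamma	1	14385	-13	-611	204	13964
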