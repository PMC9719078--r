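# Nonbonded parameters by element, AutoDock4-flavoured.
# rmin_half: Lennard-Jones Rii/2 (Angstrom); epsilon: well depth (kcal/mol).
# volume: atomic volume (A^3) and asp: atomic solvation parameter for the
# Gaussian-contact desolvation term (Huey et al. 2007 conventions);
# solvation S_i = asp + 0.01097*|q_i|.
element	rmin_half	epsilon	volume	asp
H	1.000	0.020	0.000	0.00051
C	2.000	0.150	33.510	-0.00143
N	1.750	0.160	22.449	-0.00162
O	1.600	0.200	17.157	-0.00251
F	1.545	0.080	15.448	-0.00110
P	2.100	0.200	38.792	-0.00110
S	2.000	0.200	33.510	-0.00214
Cl	2.045	0.276	35.823	-0.00110
Br	2.165	0.389	42.566	-0.00110
I	2.360	0.550	55.058	-0.00110
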