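# Synthetic base-pair-step elastic parameters (NOT a published compilation).
# Constructed stand-in with crystallography-scale magnitudes, exact
# reverse-complement symmetry (tilt/shift flip sign; twist/roll/slide/rise
# invariant) and diagonal stiffness matrices. The A/T dinucleotide class is
# flexible in roll/tilt with positive equilibrium roll; the G/C class is
# stiff with negative equilibrium roll. Units: degrees / Angstrom for
# equilibrium values; kT per squared unit for force constants.
# Columns: step, 6 equilibrium values, 21 unique stiffness entries
# (upper triangle in column-major order, i.e. (1,1),(1,2),(2,2),(1,3),...;
# parameter order twist roll tilt shift slide rise).
step	t0_twist	t0_roll	t0_tilt	t0_shift	t0_slide	t0_rise	k_twist_twist	k_twist_roll	k_roll_roll	k_twist_tilt	k_roll_tilt	k_tilt_tilt	k_twist_shift	k_roll_shift	k_tilt_shift	k_shift_shift	k_twist_slide	k_roll_slide	k_tilt_slide	k_shift_slide	k_slide_slide	k_twist_rise	k_roll_rise	k_tilt_rise	k_shift_rise	k_slide_rise	k_rise_rise
AA	35.6	3.3	-0.4	0	-0.1	3.32	0.068	0	0.02	0	0	0.038	0	0	0	1.7	0	0	0	0	2.2	0	0	0	0	0	5
AC	34.4	0	0.2	0	-0.3	3.32	0.06	0	0.026	0	0	0.048	0	0	0	1.6	0	0	0	0	2.2	0	0	0	0	0	5
AG	32.7	1	0.3	0	-0.1	3.32	0.055	0	0.025	0	0	0.045	0	0	0	1.5	0	0	0	0	2	0	0	0	0	0	5
AT	31.5	3	0	0	-0.6	3.32	0.06	0	0.022	0	0	0.042	0	0	0	1.8	0	0	0	0	2.5	0	0	0	0	0	5.2
CA	34.5	0.5	0.3	0	0.2	3.32	0.045	0	0.023	0	0	0.04	0	0	0	1.4	0	0	0	0	1.8	0	0	0	0	0	4.6
CC	33.7	-3.5	0.1	0	-0.2	3.32	0.065	0	0.038	0	0	0.06	0	0	0	1.8	0	0	0	0	2.8	0	0	0	0	0	5.4
CG	29.8	-3	0	0	0.4	3.32	0.04	0	0.032	0	0	0.055	0	0	0	1.3	0	0	0	0	1.7	0	0	0	0	0	4.5
CT	32.7	1	-0.3	0	-0.1	3.32	0.055	0	0.025	0	0	0.045	0	0	0	1.5	0	0	0	0	2	0	0	0	0	0	5
GA	36.9	1	-0.3	0	-0.1	3.32	0.06	0	0.025	0	0	0.045	0	0	0	1.6	0	0	0	0	2.1	0	0	0	0	0	5
GC	40	-4	0	0	-0.4	3.32	0.05	0	0.04	0	0	0.065	0	0	0	1.6	0	0	0	0	2.6	0	0	0	0	0	5.3
GG	33.7	-3.5	-0.1	0	-0.2	3.32	0.065	0	0.038	0	0	0.06	0	0	0	1.8	0	0	0	0	2.8	0	0	0	0	0	5.4
GT	34.4	0	-0.2	0	-0.3	3.32	0.06	0	0.026	0	0	0.048	0	0	0	1.6	0	0	0	0	2.2	0	0	0	0	0	5
TA	36	4	0	0	0.1	3.32	0.05	0	0.016	0	0	0.033	0	0	0	1.3	0	0	0	0	1.6	0	0	0	0	0	4.4
TC	36.9	1	0.3	0	-0.1	3.32	0.06	0	0.025	0	0	0.045	0	0	0	1.6	0	0	0	0	2.1	0	0	0	0	0	5
TG	34.5	0.5	-0.3	0	0.2	3.32	0.045	0	0.023	0	0	0.04	0	0	0	1.4	0	0	0	0	1.8	0	0	0	0	0	4.6
TT	35.6	3.3	0.4	0	-0.1	3.32	0.068	0	0.02	0	0	0.038	0	0	0	1.7	0	0	0	0	2.2	0	0	0	0	0	5
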