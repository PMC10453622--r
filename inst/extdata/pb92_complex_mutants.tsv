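mutant_id	substitutions	t_half_min	fold_increase_reported	composite_score_reported
WT		23.14	1.00	10000
M2	N18L/R143L	49.00	2.12	16141.99
M3-1	N18L/R143L/S97A	105.42	4.55	34207.01
M3-2	N18L/R143L/G98R	232.45	10.04	6692.22
M3-3	N18L/R143L/S99L	90.87	3.93	29739.52
M3-4	N18L/R143L/G100A	91.42	3.95	30752.94
M6	N18L/R143L/S97A/G98R/S99L/G100A	224.62	9.71	3544.60
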