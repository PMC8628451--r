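name	kind	base	low	high	dist_family	dist_arg1	dist_arg2	dist_arg3	source_tag
p_ww_treat	probability	0.02	0.01	0.04	beta	15.66	767.34		assumption
p_treat_exit	probability	0.05	0.03	0.08	beta	23.7	450.3		assumption
p_death_ww	probability	0.0015	0.001	0.003	beta	14.03990625	9345.89759375		assumption
p_death_treat	probability	0.004	0.002	0.008	beta	15.932	3967.068		assumption
p_death_relapse	probability	0.02	0.01	0.04	beta	15.66	767.34		assumption
hr_ttnt	hazard_ratio	0.5	0.11	1	lognormal	-0.693147180559945	0.563090681920797		assumption
p_highrisk	probability	0.3	0.2	0.4	beta	24.9	58.1		assumption
u_ww	utility	0.75	0.65	0.85	beta	55.5	18.5		assumption
u_early	utility	0.75	0.65	0.85	beta	55.5	18.5		assumption
u_treat	utility	0.65	0.55	0.75	beta	58.5	31.5		assumption
u_relapse	utility	0.55	0.45	0.65	beta	53.9	44.1		assumption
c_ww_cycle	cost	120	60	240	gamma	9	13.3333333333333		assumption
c_ibrutinib_cycle	cost	5084	2542	7626	gamma	25.847056	196.69551534225		assumption
c_venetoclax_cycle	cost	5462	2731	8193	gamma	29.833444	183.08311973636		assumption
c_relapse_cycle	cost	600	300	1200	gamma	16	37.5		assumption
c_analytics	cost	1000	100	2000	gamma	11.1111111111111	90		assumption
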