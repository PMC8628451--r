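name	kind	base	low	high	dist_family	dist_arg1	dist_arg2	dist_arg3	source_tag
p_crbsi	probability	0.05	0.01	0.15	beta	10.5055555555556	199.605555555556		assumption
p_death_icu_nocrbsi	probability	0.1	0.05	0.2	beta	22.4	201.6		assumption
p_death_icu_late	probability	0.3	0.2	0.4	beta	24.9	58.1		assumption
p_death_icu_early	probability	0.2	0.1	0.3	beta	12.6	50.4		assumption
los_icu_base	count	8	5	12	gamma	28.4444444444444	0.28125		assumption
los_extra_late	count	12	6	18	gamma	16	0.75		assumption
los_extra_early	count	5	2	8	gamma	11.1111111111111	0.45		assumption
c_icu_day	cost	2531	1500	3500	gamma	40.03725625	63.2161201106282		assumption
c_antibiotics	cost	400	200	800	gamma	11.1111111111111	36		assumption
c_ward_cycle	cost	3000	1500	4500	gamma	25	120		assumption
price_per_bed	cost	0	0	50000					assumption
patients_per_bed	count	21.7	10	40	gamma	29.430625	0.737327188940092		assumption
p_ward_discharge	probability	0.85	0.7	0.95	beta	42.5	7.5		assumption
p_ward_death	probability	0.02	0.01	0.04	beta	15.66	767.34		assumption
p_death_discharged	probability	0.0028	0.002	0.005	beta	21.714	7733.286		assumption
u_ward	utility	0.55	0.45	0.65	beta	53.9	44.1		assumption
u_discharged	utility	0.75	0.65	0.85	beta	55.5	18.5		assumption
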