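# Per-species shared-strain (transmission) events in the ten-dyad cohort,
# with infant breastfeeding status at six months.
species	total	exclusive	partial	none
Bacteroides_ovatus	4	0	4	0
Bacteroides_dorei	3	1	2	0
Bacteroides_sp_3_1_33FAA	3	1	1	1
Bacteroides_sp_3_1_40A	3	1	1	1
Bacteroides_sp_4_3_47FAA	3	1	1	1
Bacteroides_sp_D1	3	0	3	0
Bacteroides_caccae	2	0	2	0
Bacteroides_sp_2_1_16	2	2	0	0
Bacteroides_sp_2_1_7	2	1	1	0
Bacteroides_sp_9_1_42FAA	2	1	1	0
Bifidobacterium_adolescentis	2	0	2	0
Bifidobacterium_longum	2	0	2	0
Parabacteroides_distasonis	2	1	1	0
Parabacteroides_sp_20_3	2	1	1	0
Bacteroides_cellulosilyticus	1	1	0	0
Bacteroides_fragilis	1	1	0	0
Bacteroides_sp_1_1_30	1	0	1	0
Bacteroides_sp_2_1_22	1	0	1	0
Bacteroides_sp_2_2_4	1	0	1	0
Bacteroides_sp_4_1_36	1	0	1	0
Bacteroides_thetaiotaomicron	1	1	0	0
Bacteroides_uniformis	1	0	1	0
Bacteroides_vulgatus	1	0	0	1
Bifidobacterium_bifidum	1	0	1	0
Bifidobacterium_sp_12_1_47BFAA	1	0	1	0
Clostridium_sp_SS2_1	1	1	0	0
Collinsella_aerofaciens	1	1	0	0
Lachnospiraceae_bacterium_5_1_63FAA	1	1	0	0
Parabacteroides_merdae	1	0	1	0
Roseburia_inulinivorans	1	1	0	0
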