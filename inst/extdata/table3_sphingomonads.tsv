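genome_id	genus	n_canonical	n_double	double_topologies	n_luxI_solo	n_luxR_solo
Novosphingobium_lindaniclasticum_LE124	Novosphingobium	1	0		0	0
Novosphingobium_pentaromativorans_PP1Y	Novosphingobium	2	0		0	1
Novosphingobium_pentaromativorans_US6-1	Novosphingobium	1	0		0	0
Novosphingobium_resinovorum_KF1	Novosphingobium	2	0		0	2
Novosphingobium_sp_AP12	Novosphingobium	1	0		0	0
Novosphingobium_sp_RR_2-17	Novosphingobium	1	0		0	0
Novosphingobium_tardaugens_NBRC_16725	Novosphingobium	0	0		0	2
Sphingobium_baderi_LL03	Sphingobium	0	2	T3;T5	1	3
Sphingobium_chinhatense_IP26	Sphingobium	1	0		1	0
Sphingobium_chlorophenolicum_NBRC_16172	Sphingobium	2	0		1	1
Sphingobium_chlorophenolicum_L1	Sphingobium	0	1	T1	1	1
Sphingobium_herbicidovorans_NBRC_16415	Sphingobium	1	1	T3	0	1
Sphingobium_indicum_B90A	Sphingobium	0	1	T1	1	1
Sphingobium_japonicum_UT26S	Sphingobium	2	1	T1	0	1
Sphingobium_lactosutens_DS20	Sphingobium	2	1	T1	0	0
Sphingobium_sp_ANT17	Sphingobium	1	0		0	0
Sphingobium_sp_AP49	Sphingobium	1	0		0	0
Sphingobium_sp_DC-2	Sphingobium	0	0		0	1
Sphingobium_sp_HDIP04	Sphingobium	0	1	T4	1	1
Sphingobium_sp_KK22	Sphingobium	1	1	T3	2	0
Sphingobium_sp_SYK6	Sphingobium	2	1	T1	0	1
Sphingobium_sp_YL23	Sphingobium	0	1	T3	0	0
Sphingobium_xenophagum_QYY	Sphingobium	0	1	T2	0	1
Sphingobium_yanoikuyae_ATCC_51230	Sphingobium	2	0		1	5
Sphingobium_yanoikuyae_B1	Sphingobium	2	0		0	1
Sphingomonas_elodea_ATCC_31461	Sphingomonas	0	0		0	1
Sphingomonas_paucimobilis_EPA505	Sphingomonas	2	0		0	1
Sphingomonas_sp_KC8	Sphingomonas	1	0		0	0
Sphingomonas_sp_MM1	Sphingomonas	0	1	T6	0	0
Sphingomonas_sp_PAMC_26617	Sphingomonas	0	0		0	1
Sphingomonas_sp_PAMC_26621	Sphingomonas	0	0		0	1
Sphingomonas_sp_S17	Sphingomonas	0	0		0	1
Sphingomonas_sp_SKA58	Sphingomonas	1	1	T1	0	0
Sphingomonas_sp_UNC305MFCOL5.2	Sphingomonas	1	0		0	0
Sphingomonas_sp_YL-JM2C	Sphingomonas	2	0		0	2
Sphingomonas_wittichii_RW1	Sphingomonas	0	0		0	3
Sphingopyxis_alaskensis_RB2256	Sphingopyxis	2	0		0	0
Sphingopyxis_sp_LC363	Sphingopyxis	1	0		0	0
Sphingopyxis_sp_LC81	Sphingopyxis	2	0		0	0
Sphingopyxis_sp_MC1	Sphingopyxis	1	0		0	0
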