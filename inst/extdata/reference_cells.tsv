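# Transcription of the published significant first-order transition tables
# (virgin/once-mated male and female groups). Printed Exp/chi2/T values are
# kept verbatim as strings to preserve the printed precision (the source
# truncates to the printed decimals). significant = starred cells.
# The virgin_female FW->FMM cell is NOT printed in the source table; it is
# inferred from the printed margins (row FW 35, col FMM 29, grand 213 each
# exceed the starred-cell sums by exactly 13) and flagged inferred = TRUE.
group	antecedent	subsequent	obs	exp	chi_sq	t_pct	significant	inferred
virgin_male	MW	MHAM	9	1	64	3.48	TRUE	FALSE
virgin_male	MW	MTDF	20	3.14	90.52	7.75	TRUE	FALSE
virgin_male	MHAM	MW	5	0.7	26.14	1.93	TRUE	FALSE
virgin_male	MHAM	MTDF	8	1.41	30.8	3.1	TRUE	FALSE
virgin_male	MTDF	MWDF	30	3.48	202.1	11.62	TRUE	FALSE
virgin_male	MWDF	MATFB	30	3.95	171.7	11.62	TRUE	FALSE
virgin_male	MATFB	MHFAR	34	4.48	194.5	13.17	TRUE	FALSE
virgin_male	MHFAR	MW	9	1.95	24.48	3.48	TRUE	FALSE
virgin_male	MHFAR	MEE	27	3.76	143.6	10.46	TRUE	FALSE
virgin_male	MEE	MIE	27	3.76	143.6	10.46	TRUE	FALSE
virgin_male	MIE	MM	27	3.76	143.6	10.46	TRUE	FALSE
virgin_male	MM	MG	27	3.76	143.6	10.46	TRUE	FALSE
virgin_male	MG	MWP	5	0.09	267.8	1.93	TRUE	FALSE
mated_male	MQ	MW	8	0.96	51.6	5.3	TRUE	FALSE
mated_male	MQ	MHAM	4	0.64	17.6	2.7	TRUE	FALSE
mated_male	MW	MQ	7	1.22	27.3	4.7	TRUE	FALSE
mated_male	MW	MHAM	4	1.39	4.9	2.6	TRUE	FALSE
mated_male	MW	MTDF	10	2.44	23.4	6.7	TRUE	FALSE
mated_male	MW	MATFB	5	3.31	0.86	3.35	TRUE	FALSE
mated_male	MHAM	MTDF	4	0.37	35.6	2.68	TRUE	FALSE
mated_male	MTDF	MWDF	14	1.31	123	9.4	TRUE	FALSE
mated_male	MWDF	MATFB	14	1.78	83.8	9.4	TRUE	FALSE
mated_male	MATFB	MHFAR	10	0.67	130	6.7	TRUE	FALSE
mated_male	MHFAR	MW	4	1.45	4.4	2.68	TRUE	FALSE
mated_male	MHFAR	MEE	14	1.69	89.6	9.4	TRUE	FALSE
mated_male	MEE	MIE	14	1.31	123	9.4	TRUE	FALSE
mated_male	MIE	MM	14	1.31	123	9.4	TRUE	FALSE
mated_male	MM	MG	14	1.31	123	9.4	TRUE	FALSE
mated_male	MG	MWP	5	0.3	73.6	3.3	TRUE	FALSE
mated_male	MG	MQP	4	0.24	58.9	2.7	TRUE	FALSE
virgin_female	FW	FHMCA	10	2.3	25.77	4.69	TRUE	FALSE
virgin_female	FW	FMA	5	1.97	4.66	2.34	TRUE	FALSE
virgin_female	FW	FTDM	7	2.62	7.32	3.28	TRUE	FALSE
virgin_female	FW	FMM	13				FALSE	TRUE
virgin_female	FQ	FHMCA	4	0.26	53.12	1.87	TRUE	FALSE
virgin_female	FHMCA	FMA	7	0.61	66.93	3.28	TRUE	FALSE
virgin_female	FHMCA	FTDM	4	0.82	12.33	1.87	TRUE	FALSE
virgin_female	FMA	FW	4	0.54	22.17	1.87	TRUE	FALSE
virgin_female	FMA	FTDM	5	0.67	27.98	2.34	TRUE	FALSE
virgin_female	FTDM	FWDM	17	1.35	181.4	7.98	TRUE	FALSE
virgin_female	FWDM	FMM	16	2.17	88.14	7.51	TRUE	FALSE
virgin_female	FMM	FWK	34	5.42	150.7	15.96	TRUE	FALSE
virgin_female	FWK	FW	9	2.13	22.15	4.22	TRUE	FALSE
virgin_female	FWK	FM	26	4.27	110.5	12.2	TRUE	FALSE
virgin_female	FM	FQHM	26	3.17	164.41	12.2	TRUE	FALSE
virgin_female	FQHM	FWP	26	3.17	164.4	12.2	TRUE	FALSE
mated_female	FW	FTDM	10	1.6	41.6	8.7	TRUE	FALSE
mated_female	FW	FMM	9	3.16	10.7	7.9	TRUE	FALSE
mated_female	FTDM	FWDM	10	0.87	94.8	8.77	TRUE	FALSE
mated_female	FWDM	FMM	10	1.66	41.6	8.7	TRUE	FALSE
mated_female	FMM	FWK	21	3.86	75.8	18.4	TRUE	FALSE
mated_female	FWK	FW	6	1.1	21.6	5.26	TRUE	FALSE
mated_female	FWK	FM	15	2.76	54.1	13.15	TRUE	FALSE
mated_female	FM	FQHM	18	2.84	80.8	15.7	TRUE	FALSE
mated_female	FQHM	FWP	15	1.97	85.9	13.15	TRUE	FALSE
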