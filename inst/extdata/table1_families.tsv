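# embryophase table1_families v1
# Per-family PGT outcomes for the 36 carrier couples (transcribed study table).
# Columns:
#   family            family number (1-36)
#   pgt_cycles        PGT (biopsy) cycles performed
#   fet_cycles        frozen-embryo-transfer cycles
#   oocytes           oocytes retrieved
#   mii               metaphase-II oocytes injected (ICSI)
#   fertilized_2pn    two-pronuclear zygotes
#   cleavage          cleavage-stage embryos
#   blastocysts       blastocysts formed
#   biopsied          blastocysts of biopsy quality (trophectoderm biopsy)
#   unaffected        embryos diagnosed non-carrier or carrier
#   transferable      unaffected AND euploid embryos
#   clinical_pregnancy  FET cycles with clinical pregnancy
#   live_birth_cycles   FET cycles ending in live birth
#   live_birth_babies   babies born (family 15: monochorionic twins after a
#                       single-blastocyst transfer, so babies > cycles)
#   pgt_m / amniocentesis / after_born  confirmatory genetic testing of the
#                       transferred embryo (NA = not applicable/unavailable)
# Family 27 blastocysts printed ambiguously in the source table; stored as 6
# so the biopsy count (pinned by the cohort total of 217) fits the funnel.
family	pgt_cycles	fet_cycles	oocytes	mii	fertilized_2pn	cleavage	blastocysts	biopsied	unaffected	transferable	clinical_pregnancy	live_birth_cycles	live_birth_babies	pgt_m	amniocentesis	after_born
1	1	1	26	25	18	17	12	9	6	3	1	1	1	Wild type	Wild type	Wild type
2	1	1	22	17	15	15	8	8	6	4	1	1	1	Heterozygote	Heterozygote	Heterozygote
3	1	1	13	12	10	10	6	3	2	1	1	1	1	Wild type	NA	Wild type
4	1	1	11	10	9	9	7	5	2	2	1	1	1	Wild type	NA	Wild type
5	1	1	12	12	11	11	11	9	6	3	1	1	1	Heterozygote	Heterozygote	Heterozygote
6	1	2	15	14	12	11	10	7	6	2	1	1	1	Heterozygote	Heterozygote	Heterozygote
7	1	1	24	20	15	14	8	4	4	1	1	1	1	Heterozygote	Heterozygote	Heterozygote
8	2	2	44	31	21	21	15	8	6	4	1	1	1	Heterozygote	NA	Heterozygote
9	1	2	35	27	21	21	6	6	6	6	1	0	0	Wild type	Miscarriage	NA
10	1	1	28	16	11	11	7	4	1	1	1	0	0	Wild type	Miscarriage	NA
11	1	1	15	11	10	10	6	5	3	2	1	1	1	Wild type	Wild type	NA
12	1	3	21	16	13	13	7	4	4	3	1	1	1	Heterozygote	NA	Heterozygote
13	1	2	26	20	16	16	13	9	7	5	1	1	1	Wild type	Wild type	NA
14	1	2	7	5	4	4	3	3	1	1	0	0	0	Heterozygote	NA	NA
15	2	1	48	36	29	29	23	11	7	2	1	1	2	Wild type	NA	Wild type
16	1	1	19	12	9	9	7	4	3	2	1	1	1	Heterozygote	Heterozygote	NA
17	1	0	6	4	3	3	3	2	0	0	0	0	0	NA	NA	NA
18	1	1	19	10	4	4	4	3	2	2	1	1	1	Heterozygote	Heterozygote	NA
19	1	3	40	33	27	27	24	15	11	11	1	1	1	Heterozygote	NA	Heterozygote
20	1	2	25	21	13	12	10	4	4	3	1	1	1	Heterozygote	NA	Heterozygote
21	1	1	19	14	13	13	9	8	8	4	1	1	1	Wild type	Wild type	NA
22	1	1	19	13	10	10	8	5	5	3	1	1	1	Heterozygote	Heterozygote	NA
23	1	1	29	27	25	25	19	6	4	4	1	0	0	Heterozygote	NA	NA
24	1	1	16	15	15	14	10	7	4	4	1	1	1	Heterozygote	Heterozygote	NA
25	1	1	19	19	19	18	8	5	3	2	1	0	0	Wild type	Miscarriage	NA
26	1	2	8	7	4	4	4	4	4	4	1	0	0	Wild type	Miscarriage	NA
27	1	2	11	9	8	8	6	6	5	3	1	0	0	Wild type	Miscarriage	NA
28	1	1	11	11	7	7	3	3	2	1	0	0	0	Wild type	NA	NA
29	1	2	17	13	8	8	8	5	3	3	0	0	0	Wild type	NA	NA
30	2	4	47	40	33	33	16	10	7	6	2	0	0	Wild type	Miscarriage	NA
31	2	3	27	26	14	14	8	7	6	5	1	1	1	Heterozygote	Heterozygote	Heterozygote
32	1	2	21	15	13	13	11	6	5	5	1	1	1	Heterozygote	Heterozygote	Heterozygote
33	1	0	15	14	12	12	3	3	1	0	0	0	0	NA	NA	NA
34	1	1	12	11	11	11	11	9	7	7	1	1	1	Wild type	NA	Wild type
35	2	1	28	28	20	20	9	4	4	1	1	0	0	Heterozygote	Heterozygote	NA
36	1	1	22	17	16	15	8	6	5	2	1	0	0	Heterozygote	Heterozygote	NA
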