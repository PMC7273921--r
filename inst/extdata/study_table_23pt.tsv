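patient_id	ez_side	ez_lobes	injection_time_s	visual_label	siscom_label	operated	engel
1	left	frontal	4	discordant	concordant	FALSE	NA
2	right	temporal	5	concordant	concordant	TRUE	III-A
3	left	temporal	5	discordant	concordant	FALSE	NA
4	right	temporal	10	concordant	concordant	FALSE	NA
5	left	temporal	60	concordant	concordant	FALSE	NA
6	right	temporal	3	concordant	concordant	FALSE	NA
7	left	temporal	28	concordant	concordant	FALSE	NA
8	right	insular	21	discordant	concordant	FALSE	NA
9	right	temporal	15	concordant	discordant	FALSE	NA
10	left	temporal	4	concordant	concordant	FALSE	NA
11	right	frontal;occipital	10	partially_concordant	concordant	TRUE	I-A
12	left	frontal	22	concordant	concordant	FALSE	NA
13	right	insular	13	discordant	concordant	FALSE	NA
14	left	frontal	20	discordant	discordant	FALSE	NA
15	right	temporal	34	concordant	concordant	FALSE	NA
16	left	insular	8	discordant	concordant	FALSE	NA
17	left	temporal	20	concordant	concordant	TRUE	I-A
18	left	temporal	41	concordant	discordant	FALSE	NA
19	bilateral	temporal;frontal	14	partially_concordant	partially_concordant	TRUE	III-A
20	left	temporal	NA	concordant	concordant	FALSE	NA
21	right	frontal;temporal	28	partially_concordant	discordant	TRUE	III-A
22	left	insular	2	discordant	concordant	FALSE	NA
23	left	temporal	24	concordant	concordant	TRUE	I-A
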