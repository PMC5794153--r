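# Published fine-scale SGS summaries for the Acacia aroma populations
# (QUA/QUB are the two spatial subgroups of QU). Sp statistic, first-class
# kinship F1, log-distance regression slope b_F (significant = 1 where
# P < 0.01), neighbourhood size N_b (reported only where SGS significant),
# census density D_E in trees/ha, and gene-dispersal distances sigma_g (m)
# under effective densities D_E, D_E/2, D_E/4 and D_E/10.
pop	Sp	F1	b_F	significant	N_b	D_E	sigma_DE	sigma_DE2	sigma_DE4	sigma_DE10
LA	0.02	0.04	-0.01	1	64.3	0.69	273.1	386.3	546.3	863.7
MI	0.01	0.01	-0.01	0	NA	22.05	NA	NA	NA	NA
RO	0.05	0.05	-0.05	1	20.5	8.19	44.6	63.1	89.2	141.1
TA	0.02	0.00	-0.02	0	NA	50.00	NA	NA	NA	NA
SJ	0.01	0.00	-0.01	0	NA	12.62	NA	NA	NA	NA
QU	0.07	0.15	-0.06	1	15.2	2.72	66.7	94.3	133.3	210.8
QUA	0.03	0.06	-0.03	1	31.9	3.40	86.4	122.1	172.7	273.1
QUB	0.23	0.14	-0.20	1	4.4	2.03	41.4	58.5	82.8	130.9
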