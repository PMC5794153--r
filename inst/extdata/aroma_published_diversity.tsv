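# Published per-population diversity summaries for the six Acacia aroma
# populations (401 neutral AFLP loci): sample size N, percentage of
# polymorphic loci PPL, gene diversity H_E and its standard error.
pop	N	PPL	H_E	SE_HE
LA	50	60.3	0.21	0.01
MI	20	60.6	0.21	0.01
QU	50	67.1	0.23	0.01
RO	22	65.8	0.21	0.01
SJ	17	62.3	0.24	0.01
TA	11	56.4	0.18	0.01
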