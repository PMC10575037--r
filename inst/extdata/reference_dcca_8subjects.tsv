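# Published per-subject Pearson correlations for the external deep-CCA
# comparison method, on the eight shared subjects of the Natural Speech
# speech-EEG corpus. The lcca_alt column is the linear-CCA column printed
# alongside it (computed under that work's own protocol, hence different from
# the 19-subject table's lcca column). Overall rows as printed.
subject_id	lcca_alt	dcca	proposed
1	0.008	0.275	0.338
6	0.045	0.316	0.436
7	0.020	0.213	0.207
10	0.040	0.403	0.432
11	0.020	0.338	0.332
13	0.008	0.354	0.222
17	0.019	0.292	0.352
19	0.033	0.232	0.365
Overall	0.024	0.303	0.335
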