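# Published per-subject Pearson correlations on the Natural Speech speech-EEG
# corpus (19 subjects, 20 trials each): linear-CCA baseline vs the
# correlation-network method. The Overall row is the value as printed in the
# source table (unweighted mean of the subject rows, display-rounded).
subject_id	lcca	proposed
1	0.020	0.338
2	0.032	0.223
3	0.027	0.218
4	0.034	0.386
5	0.031	0.432
6	0.046	0.436
7	0.026	0.207
8	0.029	0.352
9	0.030	0.318
10	0.049	0.432
11	0.032	0.332
12	0.038	0.398
13	0.031	0.222
14	0.038	0.441
15	0.047	0.306
16	0.032	0.197
17	0.038	0.352
18	0.039	0.235
19	0.037	0.365
Overall	0.035	0.326
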