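name	kd_nM	printed_fold
Wild type	14.6	NA
Turns 1-2	2700	185
Turns 3-4	1100	77
Turns 5-6	14000	962
Turns 7-8	61.5	4
Top Face 2	613.4	42
Top Face 6	NA	NA
Bottom Face 2	34.5	2
Bottom Face 6	52.9	4
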