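name	kd_nM	printed_fold
Wild type	14.6	NA
K290A	37.3	3
K290E	132.3	9
V294A	113.3	8
V294S	319.0	22
K297A	54.1	4
K297E	NA	NA
M298A	323.7	22
M298S	670.6	46
I300A	26.3	2
I300S	35.8	2
L301A	6500	445
L301S	30800	2112
M304A	24.2	2
M304S	20.3	2
K305A	31.1	2
K305E	15900	1071
R312A	27.8	2
R312E	212.1	15
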