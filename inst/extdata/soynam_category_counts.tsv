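group	genes_evaluated	DownCNV/PAV	UpPAV	UpPAV+UpCNV	UpCNV+DownCNV	UpCNV	Multi-Allelic UpCNV
with_paralog	32464	149	4	1	10	71	9
without_paralog	21369	951	96	15	79	122	21
total	53833	1100	100	16	89	193	30
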