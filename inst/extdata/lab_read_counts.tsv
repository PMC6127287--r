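# Sequencing read counts per sample x primer condition from the published
# LAB survey: total reads, reads assigned to target LAB taxa, and the
# printed proportion (integer percent when >= 1, one decimal below 1).
sample	primer	total_reads	target_reads	percent_printed
Koumiss	27f/1492r	4458	3262	73
Koumiss	L1	655	613	94
Koumiss	L2	682	554	81
Koumiss	L5	1293	1199	93
Koumiss	L6	1809	1754	97
Sample1	27f/1492r	6880	56	0.8
Sample1	L5	2551	356	14
Sample1	L6	6221	345	6
Sample2	27f/1492r	7696	60	0.8
Sample2	L5	3405	432	13
Sample2	L6	4463	279	6
Sample3	27f/1492r	3844	90	2
Sample3	L5	3222	327	10
Sample3	L6	3431	299	9
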