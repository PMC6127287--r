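# Published LAB-specific primer panel (six pairs, L1-L6), verbatim.
# position: 1-based start on the 16S reference, f = forward, r = reverse.
# note: the L4 forward entry is printed identical to the 957r reverse
# sequence in the source panel (almost certainly a typesetting error);
# it is carried verbatim and flagged, not corrected.
name	pair	position	orientation	sequence	tm_c	product_size_bp	note
L1_f	L1	13f	forward	TGGCTCAGGAYGAACGCYG	60	1000	
L1_r	L1	957r	reverse	TCGAATTAAACCACATGCTCCA	60	1000	
L2_f	L2	13f	forward	TGGCTCAGGAYGAACGC	60	1000	
L2_r	L2	957r	reverse	GAGGCWGCAGTAGGGAATC	60	1000	
L3_f	L3	361f	forward	TCCGGAWTTATTGGGCGTAAAG	60	600	
L3_r	L3	957r	reverse	TCGAATTAAACCACATGCTCCA	60	600	
L4_f	L4	567f	forward	TCGAATTAAACCACATGCTCCA	60	400	printed_identical_to_957r
L4_r	L4	957r	reverse	TCGAATTAAACCACATGCTCCA	60	400	
L5_f	L5	15f	forward	GCTCAGGAYGAACGCYGG	60	750	
L5_r	L5	687r	reverse	CACCGCTACACATGRADTTC	60	750	
L6_f	L6	19f	forward	AGGAYGAACGCYGGCGGCGTGCC	60	1000	
L6_r	L6	957r	reverse	TCGAATTAAACCACATGCTCCA	60	1000	
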