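library	row	reads	unique
0HAI	18-30nt	22265577	6596317
0HAI	mapped	19203513	4856925
0HAI	CDS	600910	211949
0HAI	noncoding_total	17642144	NA
0HAI	known_miRNA	400047	1724
0HAI	rRNA	2289143	24748
0HAI	tRNA	277627	8121
0HAI	snoRNA	40642	8790
0HAI	snRNA	5956	1679
0HAI	others	14628729	4345729
12HAI	18-30nt	27075645	10712075
12HAI	mapped	22332607	7892704
12HAI	CDS	1570839	338298
12HAI	noncoding_total	19201655	NA
12HAI	known_miRNA	873690	2506
12HAI	rRNA	1388914	23099
12HAI	tRNA	274039	7349
12HAI	snoRNA	44927	6001
12HAI	snRNA	6005	1390
12HAI	others	16614080	7138503
24HAI	18-30nt	21236500	9420781
24HAI	mapped	17359816	7115379
24HAI	CDS	1322306	243265
24HAI	noncoding_total	14737124	NA
24HAI	known_miRNA	781907	2314
24HAI	rRNA	747877	19579
24HAI	tRNA	421275	6878
24HAI	snoRNA	28636	4755
24HAI	snRNA	3623	1079
24HAI	others	12753806	6489573
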