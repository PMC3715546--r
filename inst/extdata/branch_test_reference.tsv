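gene	foreground	n_seq	model	np	lnL	omega0	omegaX	comparison	p_printed
Gja10	rhinolophids	30	A	60	-2451.40	0.290	NA	NA	NA
Gja10	rhinolophids	30	B	61	-2430.85	0.159	0.731	B vs. A	<0.001
Gja10	rhinolophids	30	C	60	-2432.15	0.160	1	C vs. B	0.107
Gja10	vespertilionids	23	A	46	-2117.28	0.307	NA	NA	NA
Gja10	vespertilionids	23	B	47	-2090.36	0.173	1.446	B vs. A	<0.001
Gja10	vespertilionids	23	C	46	-2091.34	0.172	1	C vs. B	0.163
Gja10	desmodus	21	A	42	-1913.35	0.171	NA	NA	NA
Gja10	desmodus	21	B	43	-1913.16	0.168	0.252	B vs. A	0.540
Gja10	desmodus	21	C	42	-1915.63	0.169	1	C vs. B	0.026
Gja10	miniopterus	21	A	42	-1950.11	0.172	NA	NA	NA
Gja10	miniopterus	21	B	43	-1949.88	0.167	0.235	B vs. A	0.502
Gja10	miniopterus	21	C	42	-1954.66	0.168	1	C vs. B	0.002
Rbp3	rhinolophids	15	A	30	-8348.10	0.170	NA	NA	NA
Rbp3	rhinolophids	15	B	31	-8293.72	0.100	0.404	B vs. A	<0.001
Rbp3	rhinolophids	15	C	30	-8328.03	0.098	1	C vs. B	<0.001
Rbp3	pipistrellus	10	A	20	-6686.21	0.141	NA	NA	NA
Rbp3	pipistrellus	10	B	21	-6651.60	0.101	0.438	B vs. A	<0.001
Rbp3	pipistrellus	10	C	20	-6667.57	0.101	1	C vs. B	<0.001
Rbp3	pteronotus	11	A	22	-7088.59	0.163	NA	NA	NA
Rbp3	pteronotus	11	B	23	-7038.36	0.106	0.532	B vs. A	<0.001
Rbp3	pteronotus	11	C	22	-7047.78	0.106	1	C vs. B	<0.001
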