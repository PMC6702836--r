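enzyme	genus	group	hits
3.1.11.6	Haemophilus	AVf	27
3.1.11.6	Haemophilus	AVm	26
4.2.1.51	Haemophilus	AVf	24
4.2.1.51	Haemophilus	AVm	24
2.5.1.54	Haemophilus	AVf	24
2.5.1.54	Haemophilus	AVm	24
2.7.2.11	Haemophilus	AVf	24
2.7.2.11	Haemophilus	AVm	24
3.5.99.6	Haemophilus	AVf	24
3.5.99.6	Haemophilus	AVm	24
3.5.1.18	Haemophilus	AVf	24
3.5.1.18	Haemophilus	AVm	24
2.3.1.47	Aggregatibacter	AVf	24
2.3.1.47	Aggregatibacter	AVm	24
1.5.1.3	Aggregatibacter	AVf	23
1.5.1.3	Aggregatibacter	AVm	22
2.7.4.9	Aggregatibacter	AVf	23
2.7.4.9	Aggregatibacter	AVm	22
2.8.1.6	Aggregatibacter	AVf	23
2.8.1.6	Aggregatibacter	AVm	22
2.7.7.41	Aggregatibacter	AVf	23
2.7.7.41	Aggregatibacter	AVm	22
4.1.3.3	Proteus	AVf	22
4.1.3.3	Proteus	AVm	22
2.7.1.60	Proteus	AVf	21
2.7.1.60	Proteus	AVm	20
5.1.3.9	Proteus	AVf	21
5.1.3.9	Proteus	AVm	20
3.2.1.23	Proteus	AVf	21
3.2.1.23	Proteus	AVm	20
4.1.1.49	Pasteurella	AVf	15
4.1.1.49	Pasteurella	AVm	15
2.6.1.21	Pasteurella	AVf	15
2.6.1.21	Pasteurella	AVm	14
1.5.1.34	Pasteurella	AVf	15
1.5.1.34	Pasteurella	AVm	14
2.7.8.20	Pasteurella	AVf	15
2.7.8.20	Pasteurella	AVm	14
2.7.8.5	Coxiella	AVf	13
2.7.8.5	Coxiella	AVm	12
6.3.4.3	Coxiella	AVf	12
6.3.4.3	Coxiella	AVm	11
3.1.11.6	Coxiella	AVf	12
3.1.11.6	Coxiella	AVm	11
4.2.1.51	Coxiella	AVf	12
4.2.1.51	Coxiella	AVm	11
2.5.1.54	Actinobacillus	AVf	2
2.5.1.54	Actinobacillus	AVm	1
2.7.2.11	Actinobacillus	AVf	2
2.7.2.11	Actinobacillus	AVm	1
3.5.99.6	Basfia	AVf	2
3.5.99.6	Basfia	AVm	1
3.5.1.18	Basfia	AVf	2
3.5.1.18	Basfia	AVm	1
2.3.1.47	Histophilus	AVf	2
2.3.1.47	Histophilus	AVm	1
1.5.1.3	Histophilus	AVf	2
1.5.1.3	Histophilus	AVm	1
2.7.4.9	Mannheimia	AVf	2
2.7.4.9	Mannheimia	AVm	1
2.8.1.6	Mannheimia	AVf	2
2.8.1.6	Mannheimia	AVm	1
2.7.7.41	Lonepinella	AVf	2
2.7.7.41	Lonepinella	AVm	1
4.1.3.3	Lonepinella	AVf	2
4.1.3.3	Lonepinella	AVm	1
2.7.1.60	Staphylococcus	AVf	3
2.7.1.60	Staphylococcus	AVm	3
5.1.3.9	Corynebacterium	AVf	3
5.1.3.9	Corynebacterium	AVm	3
3.2.1.23	Escherichia	AVf	3
3.2.1.23	Escherichia	AVm	3
4.1.1.49	Klebsiella	AVf	3
4.1.1.49	Klebsiella	AVm	3
2.6.1.21	Enterobacter	AVf	3
2.6.1.21	Enterobacter	AVm	3
1.5.1.34	Serratia	AVf	3
1.5.1.34	Serratia	AVm	3
2.7.8.20	Providencia	AVf	3
2.7.8.20	Providencia	AVm	2
2.7.8.5	Morganella	AVf	3
2.7.8.5	Morganella	AVm	2
6.3.4.3	Acinetobacter	AVf	3
6.3.4.3	Acinetobacter	AVm	2
3.1.11.6	Moraxella	AVf	3
3.1.11.6	Moraxella	AVm	2
4.2.1.51	Neisseria	AVf	3
4.2.1.51	Neisseria	AVm	2
2.5.1.54	Bacillus	AVf	3
2.5.1.54	Bacillus	AVm	2
2.7.2.11	Lactococcus	AVf	3
2.7.2.11	Lactococcus	AVm	2
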