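enzyme	genus	group	hits
2.7.7.7	Rickettsia	Ix.f	31
2.7.7.7	Rickettsia	Ix.m	30
1.17.7.1	Rickettsia	Ix.f	28
1.17.7.1	Rickettsia	Ix.m	27
2.5.1.6	Rickettsia	Ix.f	28
2.5.1.6	Rickettsia	Ix.m	27
6.3.4.14	Rickettsia	Ix.f	28
6.3.4.14	Rickettsia	Ix.m	27
6.3.5.5	Rickettsia	Ix.f	28
6.3.5.5	Rickettsia	Ix.m	27
6.3.2.13	Rickettsia	Ix.f	28
6.3.2.13	Rickettsia	Ix.m	27
6.3.2.10	Rickettsia	Ix.f	28
6.3.2.10	Rickettsia	Ix.m	27
1.2.4.1	Candidatus Protochlamydia	Ix.f	28
1.2.4.1	Candidatus Protochlamydia	Ix.m	27
2.7.4.9	Candidatus Protochlamydia	Ix.f	27
2.7.4.9	Candidatus Protochlamydia	Ix.m	27
1.5.1.3	Candidatus Protochlamydia	Ix.f	27
1.5.1.3	Candidatus Protochlamydia	Ix.m	27
2.8.1.6	Chlamydophila	Ix.f	30
2.8.1.6	Chlamydophila	Ix.m	29
4.1.1.49	Chlamydophila	Ix.f	29
4.1.1.49	Chlamydophila	Ix.m	29
2.7.7.7	Waddlia	Ix.f	28
2.7.7.7	Waddlia	Ix.m	27
1.17.7.1	Waddlia	Ix.f	27
1.17.7.1	Waddlia	Ix.m	27
2.5.1.6	Chlamydia	Ix.f	25
2.5.1.6	Chlamydia	Ix.m	24
6.3.4.14	Chlamydia	Ix.f	25
6.3.4.14	Chlamydia	Ix.m	24
6.3.5.5	Wolbachia	Ix.f	3
6.3.5.5	Wolbachia	Ix.m	2
6.3.2.13	Rickettsiella	Ix.f	3
6.3.2.13	Rickettsiella	Ix.m	2
6.3.2.10	Pseudomonas	Ix.f	3
6.3.2.10	Pseudomonas	Ix.m	2
1.2.4.1	Mycoplasma	Ix.f	3
1.2.4.1	Mycoplasma	Ix.m	2
2.7.4.9	Spiroplasma	Ix.f	3
2.7.4.9	Spiroplasma	Ix.m	2
1.5.1.3	Mesoplasma	Ix.f	3
1.5.1.3	Mesoplasma	Ix.m	2
2.8.1.6	Acholeplasma	Ix.f	3
2.8.1.6	Acholeplasma	Ix.m	2
4.1.1.49	Ureaplasma	Ix.f	3
4.1.1.49	Ureaplasma	Ix.m	2
2.7.7.7	Polynucleobacter	Ix.f	3
2.7.7.7	Polynucleobacter	Ix.m	2
1.17.7.1	Photobacterium	Ix.f	3
1.17.7.1	Photobacterium	Ix.m	2
2.5.1.6	Parvibaculum	Ix.f	3
2.5.1.6	Parvibaculum	Ix.m	2
6.3.4.14	Myxococcus	Ix.f	3
6.3.4.14	Myxococcus	Ix.m	2
6.3.5.5	Methylotenera	Ix.f	3
6.3.5.5	Methylotenera	Ix.m	2
6.3.2.13	Methylococcus	Ix.f	3
6.3.2.13	Methylococcus	Ix.m	2
6.3.2.10	Leptothrix	Ix.f	3
6.3.2.10	Leptothrix	Ix.m	2
1.2.4.1	Halorhodospira	Ix.f	3
1.2.4.1	Halorhodospira	Ix.m	2
2.7.4.9	Geobacillus	Ix.f	3
2.7.4.9	Geobacillus	Ix.m	2
1.5.1.3	Burkholderia	Ix.f	3
1.5.1.3	Burkholderia	Ix.m	2
2.8.1.6	Ralstonia	Ix.f	2
2.8.1.6	Ralstonia	Ix.m	2
4.1.1.49	Cupriavidus	Ix.f	2
4.1.1.49	Cupriavidus	Ix.m	2
2.7.7.7	Bordetella	Ix.f	2
2.7.7.7	Bordetella	Ix.m	2
1.17.7.1	Achromobacter	Ix.f	2
1.17.7.1	Achromobacter	Ix.m	2
2.5.1.6	Delftia	Ix.f	2
2.5.1.6	Delftia	Ix.m	2
6.3.4.14	Comamonas	Ix.f	2
6.3.4.14	Comamonas	Ix.m	2
6.3.5.5	Variovorax	Ix.f	2
6.3.5.5	Variovorax	Ix.m	2
6.3.2.13	Herbaspirillum	Ix.f	2
6.3.2.13	Herbaspirillum	Ix.m	2
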