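transcript	chrom	start	end	n_exons	length_bp	homolog
UU537	ECA1	70810673	70814839	6	654	FXYD4
UU759	ECA1	93611754	93614921	4	494	NA
UU976	ECA1	120923885	120927741	5	1397	TMEM202-like
UU1097	ECA1	129776131	129787516	3	421	NA
UU1304	ECA1	147378438	147392725	5	5976	hypothetical protein
UU1795	ECA2	15281173	15286110	3	338	NA
UU1814	ECA2	17589860	17596668	3	643	NA
UU4133	ECA4	94369944	94374962	3	380	NA
UU4544	ECA5	27060113	27081749	4	405	C1orf97
UU5985	ECA7	20765366	20771304	3	1486	C11orf34
UU6001	ECA7	24780964	24782435	3	362	NA
UU6079	ECA7	29491656	29501879	3	1713	uncharacterized transcript
UU6650	ECA7	90169710	90176775	4	492	SVIP
UU6651	ECA7	90187426	90198224	4	422	uncharacterized transcript
UU6720	ECA8	3386523	3389899	4	514	hypothetical protein
UU7648	ECA9	37795498	37818967	4	282	hypothetical protein
UU10179	ECA12	20494123	20515958	4	364	MS4A
UU11376	ECA14	22138968	22142919	3	348	TIMD4
UU11445	ECA14	29718473	29720828	3	182	LOC100335778
UU11917	ECA15	5089445	5092230	3	335	NA
UU12205	ECA15	39457033	39498454	5	392	NA
UU13082	ECA16	41994906	42002761	3	1465	hypothetical protein
UU13779	ECA17	80469119	80479703	8	869	1700029H14Rik
UU14104	ECA18	67071149	67074077	5	793	PRSS58-like
UU15940	ECA22	34285501	34286605	3	389	WFDC15B
UU16194	ECA23	19006045	19011880	3	1093	C9orf57
UU16781	ECA24	42686132	42721148	9	10410	MEG3
UU16784	ECA24	43528445	43546083	3	1142	uncharacterized transcript
UU17491	ECA26	37127724	37141004	4	820	NA
UU17605	ECA27	3312336	3325363	4	829	NA
UU17720	ECA27	23956623	23966552	3	1124	NA
UU17987	ECA28	34400567	34404183	3	291	KCTD17
UU18303	ECA29	21894122	21902694	3	692	NA
UU18376	ECA30	211164	253935	6	747	NA
UU19050	ECAX	54336811	54337514	3	302	uncharacterized transcript
UU19054	ECAX	55430384	55505951	7	2334	NA
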