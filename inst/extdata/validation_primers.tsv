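transcript	primer	sequence	length	tm
UU18303	F	GAAGGAGAGCAGAGCTTGGA	20	59.83
UU18303	R	GAAGGAGAGCAGAGCTTGGA	20	59.84
UU12205	F1	AGGAGTGTGCATCCCACTTT	20	59.58
UU12205	F2	TGAGAAGGAAGCCAAGGAAA	20	59.93
UU12205	R1	TAATGCCTGGCCTATGGAAG	20	60.05
UU12205	R2	TTGTTACTGTGCGAACTCTGC	21	59.14
UU18376	F1	TGTGAAGGAGGTGAACTGGA	20	59.23
UU18376	F2	AACTGCCCAAGTCACACAGTT	21	59.68
UU18376	R1	GAATTTGCTTCTGTGCGTTG	20	59.47
UU18376	R2	AACTGTGTGACTTGGGCAGTT	21	59.68
UU18376	R3	ACTTGCCCTCTCTCGGTCTT	20	60.39
UU1814	F	TTTGTACAGGGCCCTTTGTG	20	60.91
UU1814	R	GCAGTCTCTTCACCCAGCTC	20	60.14
RPLP0	F	CTTCATTGTGGGAGCAGACA	20	59.83
RPLP0	R	GCCTTGACCTTTTCAGCAAG	20	59.99
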