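table	group	pKa
IPC_protein	NH2	9.094
IPC_protein	COOH	2.869
IPC_protein	C	7.555
IPC_protein	D	3.872
IPC_protein	E	4.412
IPC_protein	H	5.637
IPC_protein	K	9.052
IPC_protein	R	11.84
IPC_protein	Y	10.85
EMBOSS	NH2	8.6
EMBOSS	COOH	3.6
EMBOSS	C	8.5
EMBOSS	D	3.9
EMBOSS	E	4.1
EMBOSS	H	6.5
EMBOSS	K	10.8
EMBOSS	R	12.5
EMBOSS	Y	10.1
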