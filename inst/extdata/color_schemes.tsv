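scheme	kind	letter	color	value
nucleotide	discrete	A	#109648	
nucleotide	discrete	C	#255C99	
nucleotide	discrete	G	#F7B32B	
nucleotide	discrete	T	#D62839	
nucleotide	discrete	U	#D62839	
nucleotide2	discrete	A	#66C2A5	
nucleotide2	discrete	C	#8DA0CB	
nucleotide2	discrete	G	#FFD92F	
nucleotide2	discrete	T	#E41A1C	
nucleotide2	discrete	U	#E41A1C	
base_pairing	discrete	A	#1F77B4	
base_pairing	discrete	T	#1F77B4	
base_pairing	discrete	U	#1F77B4	
base_pairing	discrete	C	#FF7F0E	
base_pairing	discrete	G	#FF7F0E	
chemistry	discrete	A	#221E22	
chemistry	discrete	C	#109648	
chemistry	discrete	D	#D62839	
chemistry	discrete	E	#D62839	
chemistry	discrete	F	#221E22	
chemistry	discrete	G	#109648	
chemistry	discrete	H	#255C99	
chemistry	discrete	I	#221E22	
chemistry	discrete	K	#255C99	
chemistry	discrete	L	#221E22	
chemistry	discrete	M	#221E22	
chemistry	discrete	N	#5E239D	
chemistry	discrete	P	#221E22	
chemistry	discrete	Q	#5E239D	
chemistry	discrete	R	#255C99	
chemistry	discrete	S	#109648	
chemistry	discrete	T	#109648	
chemistry	discrete	V	#221E22	
chemistry	discrete	W	#221E22	
chemistry	discrete	Y	#109648	
chemistry2	discrete	A	#7F7F7F	
chemistry2	discrete	C	#2CA02C	
chemistry2	discrete	D	#D62728	
chemistry2	discrete	E	#D62728	
chemistry2	discrete	F	#7F7F7F	
chemistry2	discrete	G	#2CA02C	
chemistry2	discrete	H	#1F77B4	
chemistry2	discrete	I	#7F7F7F	
chemistry2	discrete	K	#1F77B4	
chemistry2	discrete	L	#7F7F7F	
chemistry2	discrete	M	#7F7F7F	
chemistry2	discrete	N	#9467BD	
chemistry2	discrete	P	#7F7F7F	
chemistry2	discrete	Q	#9467BD	
chemistry2	discrete	R	#1F77B4	
chemistry2	discrete	S	#2CA02C	
chemistry2	discrete	T	#2CA02C	
chemistry2	discrete	V	#7F7F7F	
chemistry2	discrete	W	#7F7F7F	
chemistry2	discrete	Y	#2CA02C	
clustalx	discrete	A	#80A0F0	
clustalx	discrete	C	#F08080	
clustalx	discrete	D	#C048C0	
clustalx	discrete	E	#C048C0	
clustalx	discrete	F	#80A0F0	
clustalx	discrete	G	#F09048	
clustalx	discrete	H	#15A4A4	
clustalx	discrete	I	#80A0F0	
clustalx	discrete	K	#F01505	
clustalx	discrete	L	#80A0F0	
clustalx	discrete	M	#80A0F0	
clustalx	discrete	N	#15C015	
clustalx	discrete	P	#C0C000	
clustalx	discrete	Q	#15C015	
clustalx	discrete	R	#F01505	
clustalx	discrete	S	#15C015	
clustalx	discrete	T	#15C015	
clustalx	discrete	V	#80A0F0	
clustalx	discrete	W	#80A0F0	
clustalx	discrete	Y	#15A4A4	
taylor	discrete	A	#CCFF00	
taylor	discrete	C	#FFFF00	
taylor	discrete	D	#FF0000	
taylor	discrete	E	#FF0066	
taylor	discrete	F	#00FF66	
taylor	discrete	G	#FF9900	
taylor	discrete	H	#0066FF	
taylor	discrete	I	#66FF00	
taylor	discrete	K	#6600FF	
taylor	discrete	L	#33FF00	
taylor	discrete	M	#00FF00	
taylor	discrete	N	#CC00FF	
taylor	discrete	P	#FFCC00	
taylor	discrete	Q	#FF00CC	
taylor	discrete	R	#0000FF	
taylor	discrete	S	#FF3300	
taylor	discrete	T	#FF6600	
taylor	discrete	V	#99FF00	
taylor	discrete	W	#00CCFF	
taylor	discrete	Y	#00FFCC	
hydrophobicity	continuous	A		1.8
hydrophobicity	continuous	C		2.5
hydrophobicity	continuous	D		-3.5
hydrophobicity	continuous	E		-3.5
hydrophobicity	continuous	F		2.8
hydrophobicity	continuous	G		-0.4
hydrophobicity	continuous	H		-3.2
hydrophobicity	continuous	I		4.5
hydrophobicity	continuous	K		-3.9
hydrophobicity	continuous	L		3.8
hydrophobicity	continuous	M		1.9
hydrophobicity	continuous	N		-3.5
hydrophobicity	continuous	P		-1.6
hydrophobicity	continuous	Q		-3.5
hydrophobicity	continuous	R		-4.5
hydrophobicity	continuous	S		-0.8
hydrophobicity	continuous	T		-0.7
hydrophobicity	continuous	V		4.2
hydrophobicity	continuous	W		-0.9
hydrophobicity	continuous	Y		-1.3
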