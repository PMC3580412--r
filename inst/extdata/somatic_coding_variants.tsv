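position	gene	codon_change	consequence	class	sift
Chr1:71831141G/A	NEGR1	503C>T	T168I	missense	Damaging
Chr1:149227247C/T	ANXA9	760C>T	R245C	missense	Damaging
Chr1:156702726C/A	OR10K1	751C>A	H251N	missense	Damaging
Chr1:220801358G/T	TAF1A	1211C>A	A404D	missense	Damaging
Chr1:226621463T/G	OBSCN	19592T>G	F6531C	missense	Not scored
Chr1:238137913G/A	CHRM3	539G>A	R180Q	missense	Damaging
Chr2:49235000G/A	FSHR	61C>T	R21W	missense	Tolerated
Chr2:165735207G/C	SCN3A	362C>G	A121G	missense	Damaging
Chr2:178905886C/T	OSBPL6	529C>T	R177X	nonsense	-
Chr3:109658364C/T	MYH15	2137G>A	G713R	missense	Damaging
Chr3:129258301T/G	SEC61A1	280T>G	L94V	missense	Damaging
Chr4:6670038G/A	MAN2B2	2732G>A	R911H	missense	Tolerated
Chr6:28336272A/G	NKAPL	1144A>G	S382G	missense	Damaging
Chr7:2599270C/T	IQCE	1333C>T	R445X	nonsense	-
Chr7:43813258G/A	BLVRA	790G>A	G264S	missense	Tolerated
Chr8:76091857G/T	CRISPLD1	950G>T	C317F	missense	Damaging
Chr9:33301117G/A	NFX1	1240G>A	G414R	missense	Damaging
Chr10:17777173T/C	STAM	364T>C	Y122H	missense	Damaging
Chr10:99328071C/T	ANKRD2	274C>T	R92W	missense	Damaging
Chr11:6368506-6368518del	SMPD1	102-114del	L35WfsX72	frameshift_indel	-
Chr11:92170718A/T	FAT3	4894A>T	M1632L	missense	Not scored
Chr11:116661033A/T	RNF214	2068A>T	T690S	missense	Not scored
Chr12:1854754C/T	CACNA2D4	1730G>A	G577E	missense	Damaging
Chr12:5902149C/A	ANO2	93G>T	Q31H	missense	Damaging
Chr12:25289551C/A	KRAS	35G>T	G12V	missense	Damaging
Chr14:19598288-19598307del	OR4L1	245-264del	I82TfsX104	frameshift_indel	-
Chr15:32142462G/A	CHRM5	252G>A	M84I	missense	Damaging
Chr15:83002258G/C	NMB	130C>G	H44D	missense	Tolerated
Chr17:11543819G/A	DNAH9	4919G>A	R1640Q	missense	Tolerated
Chr17:41416912C/G	MAPT	905C>G	T302R	missense	Damaging
Chr18:42815392C/T	TCEB3B	242G>A	R81Q	missense	Tolerated
Chr18:46845916C/T	SMAD4	1081C>T	R361C	missense	Damaging
Chr20:25405049-25405055del	NINL	2872-2878del	W958HfsX960	frameshift_indel	-
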