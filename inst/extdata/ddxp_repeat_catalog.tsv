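genus	repeat_id	length_aa	size_label	solo	het	terminal_motif
Aeromonas	A1	254	L	FALSE	FALSE	DDVP
Aeromonas	A2	260	L	FALSE	FALSE	DDAP
Aeromonas	A3	178	S	FALSE	FALSE	DDGP
Aeromonas	A4	171	S	FALSE	FALSE	DDVP
Aeromonas	A5	166	S	FALSE	FALSE	DDVP
Aeromonas	A6	158	S	FALSE	FALSE	DDGP
Aeromonas	A7	169	S	TRUE	FALSE	DDGP
Aeromonas	A8	204	S	FALSE	FALSE	DDGP
Aeromonas	A9	267	L	FALSE	FALSE	DDMP
Aeromonas	A10	205	S	FALSE	FALSE	DDGP
Aeromonas	A11	176	S	FALSE	FALSE	DDGP
Aeromonas	A12	144	S	TRUE	FALSE	DDTP
Aeromonas	A13	304	L	TRUE	FALSE	DDGP
Aeromonas	A14	219	S	FALSE	FALSE	DDGP
Aeromonas	A15	138	S	TRUE	FALSE	DDTP
Aeromonas	A16	183	S	TRUE	FALSE	DDGP
Legionella	L1	179	S	FALSE	FALSE	DDGP
Legionella	L2	185	S	FALSE	FALSE	DDGP
Legionella	L3	180	S	FALSE	FALSE	DDGP
Legionella	L4	174	S	FALSE	FALSE	DDGP
Legionella	L5	153	S	FALSE	FALSE	DDTP
Legionella	L6	168	S	FALSE	FALSE	DDGP
Legionella	L7	183	S	FALSE	FALSE	DDGP
Legionella	L8	153	S	TRUE	FALSE	DDVP
Legionella	L9	174	S	TRUE	FALSE	DDGP
Legionella	L10	155	S	FALSE	FALSE	DDGP
Legionella	L11	247	L	FALSE	FALSE	DDVP
Pseudomonas	P1	153	S	FALSE	FALSE	DDTP
Pseudomonas	P2	154	S	FALSE	FALSE	DDGP
Pseudomonas	P3	182	S	FALSE	FALSE	DDGP
Pseudomonas	P4	185	S	FALSE	FALSE	DDGP
Pseudomonas	P5	136	S	TRUE	FALSE	DDTP
Pseudomonas	P6	196	S	FALSE	FALSE	DDGP
Pseudomonas	P7	180	S	FALSE	FALSE	DDGP
Pseudomonas	P8	179	S	TRUE	FALSE	DDGP
Pseudomonas	P9	159	S	FALSE	TRUE	DDGP
Pseudomonas	P10	245	L	FALSE	FALSE	DDVP
Pseudomonas	P11	244	L	FALSE	FALSE	DDVP
Pseudomonas	P12	178	S	FALSE	FALSE	DDTP
Pseudomonas	P13	170	S	FALSE	FALSE	DDTP
Pseudomonas	P15	248	L	FALSE	FALSE	DDVP
Pseudomonas	P16	190	S	TRUE	FALSE	DDAP
Pseudomonas	P17	202	S	FALSE	TRUE	DDGP
Pseudomonas	P18	144	S	TRUE	FALSE	DDTP
Pseudomonas	P19	309	L	TRUE	FALSE	DDAP
Pseudomonas	P20	158	S	FALSE	TRUE	DDAP
Pseudomonas	P21	183	S	TRUE	FALSE	DDGP
Pseudomonas	P22	268	L	FALSE	TRUE	DDMP
Pseudomonas	P23	204	S	FALSE	FALSE	DDGP
Vibrio	Vi1	144	S	FALSE	TRUE	DDKP
Vibrio	Vi2	142	S	FALSE	TRUE	DDxP
Nitrosomonas	N1	161	S	FALSE	TRUE	DDGP
Nitrosomonas	N2	137	S	FALSE	FALSE	DDTP
Nitrosomonas	N3	172	S	FALSE	FALSE	DDGP
Variovorax	Va1	167	S	FALSE	FALSE	DDGP
Variovorax	Va2	177	S	FALSE	FALSE	DDGP
Bradyrhizobium	Rb1	181	S	FALSE	FALSE	DDGP
Bradyrhizobium	Rb2	200	S	FALSE	FALSE	DDGP
Bradyrhizobium	Rb3	215	S	TRUE	FALSE	DDGP
Bradyrhizobium	Rb4	186	S	FALSE	FALSE	DSGP
Bradyrhizobium	Rb5	172	S	FALSE	FALSE	DDGP
Bradyrhizobium	Rb6	185	S	FALSE	FALSE	DDGP
Bradyrhizobium	Rb7	181	S	FALSE	FALSE	DDGP
Bradyrhizobium	Rb8	177	S	FALSE	FALSE	DDGP
Mesorhizobium	Rm0	267	L	TRUE	FALSE	DDVP
Mesorhizobium	Rm1	269	L	FALSE	FALSE	DDAP
Mesorhizobium	Rm2	172	S	FALSE	FALSE	DDIP
Mesorhizobium	Rm3	153	S	FALSE	FALSE	DDGP
Mesorhizobium	Rm4	195	S	FALSE	FALSE	DDGP
Mesorhizobium	Rm5	243	L	FALSE	FALSE	DDVP
Mesorhizobium	Rm6	245	L	FALSE	FALSE	DDVP
Mesorhizobium	Rm7	157	S	FALSE	FALSE	DDGP
Mesorhizobium	Rm8	189	S	FALSE	FALSE	DDGP
Mesorhizobium	Rm9	269	L	FALSE	FALSE	DDVP
Mesorhizobium	Rm10	162	S	TRUE	FALSE	DTGP
Mesorhizobium	Rm11	160	S	FALSE	FALSE	DVGP
Mesorhizobium	Rm12	157	S	FALSE	FALSE	DDGP
Mesorhizobium	Rm13	180	S	FALSE	FALSE	DDGP
Mesorhizobium	Rm14	244	L	FALSE	FALSE	DDVP
Sinorhizobium	Rs1	183	S	FALSE	FALSE	DDGP
Sinorhizobium	Rs2	177	S	FALSE	FALSE	DDGP
Multispecies	M1	154	S	FALSE	FALSE	DDGP
Multispecies	M2	168	S	FALSE	FALSE	DDTP
Halomonas	H1	184	S	FALSE	FALSE	DDGP
Halomonas	H2	201	S	FALSE	FALSE	DDGP
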