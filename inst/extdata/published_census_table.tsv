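superfamily	clade	families_genome	copies_genome	families_database	note
Copia	GalEa	15	183	57	published census table, Copia section, GalEa row
Copia	Hydra	6	125	37	published census table, Copia section, Hydra row
Copia	CoMol	1	185	3	published census table, Copia section, CoMol row; bracketed copy number typographically unreliable (text gives 11 copies)
BELPao	Sparrow	70	425	60	published census table, BEL/Pao section, Sparrow row
BELPao	Sinbad	24	241	32	published census table, BEL/Pao section, Sinbad row
BELPao	Surcouf	8	28	15	published census table, BEL/Pao section, Surcouf row
BELPao	TAS	16	91	76	published census table, BEL/Pao section, TAS row
BELPao	Suzu	12	127	19	published census table, BEL/Pao section, Suzu row
BELPao	Flow	2	9	12	published census table, BEL/Pao section, Flow row
BELPao	Dan	0	0	5	published census table, BEL/Pao section, Dan row
Gypsy	C-clade	111	3021	114	published census table, Gypsy section, C-clade row
Gypsy	MolGy1	73	539	66	published census table, Gypsy section, MolGy1 row
Gypsy	AB-clade	32	3031	43	published census table, Gypsy section, AB-clade row
Gypsy	MolGy2	149	2302	83	published census table, Gypsy section, MolGy2 row
Gypsy	MolGy3	38	264	20	published census table, Gypsy section, MolGy3 row
Gypsy	MolGy4	9	916	17	published census table, Gypsy section, MolGy4 row
Gypsy	MolGy5	9	5111	17	published census table, Gypsy section, MolGy5 row
Gypsy	CsRN1	24	3115	31	published census table, Gypsy section, CsRN1 row
Gypsy	MolGy6	41	302	20	published census table, Gypsy section, MolGy6 row
Gypsy	MolGy12	9	284	16	published census table, Gypsy section, MolGy12 row
Gypsy	Cigr-1	12	1476	3	published census table, Gypsy section, Cigr-1 row
Gypsy	MolGy7	3	85	7	published census table, Gypsy section, MolGy7 row
Gypsy	MolGy9	0	0	10	published census table, Gypsy section, MolGy9 row
Gypsy	MolGy13	8	31	0	published census table, Gypsy section, MolGy13 row
Gypsy	MolGy8	2	780	5	published census table, Gypsy section, MolGy8 row
Gypsy	MolGy10	3	43	4	published census table, Gypsy section, MolGy10 row
Gypsy	MolGy11	5	53	2	published census table, Gypsy section, MolGy11 row
Gypsy	MolGy16	7	1029	1	published census table, Gypsy section, MolGy16 row
Gypsy	MolGy14	3	32	2	published census table, Gypsy section, MolGy14 row
Gypsy	MolGy15	0	0	4	published census table, Gypsy section, MolGy15 row
Gypsy	Tor2	0	0	4	published census table, Gypsy section, Tor2 row
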