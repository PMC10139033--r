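name	smarts	family
quinone_a	O=C1C=CC(=O)C=C1	A
catechol_a	c1ccc(O)c(O)c1	A
rhodanine_a	O=C1CSC(=S)N1	A
hzone_phenol_a	c1ccccc1C=NN	A
mannich_a	NCc1ccccc1O	A
azo_b	c1ccccc1N=Nc1ccccc1	B
alkylidene_barbiturate_b	O=C1NC(=O)NC(=O)C1	B
anil_di_alk_b	Nc1ccc(N)cc1	B
thiophene_amino_c	c1cc(sc1)N	C
ene_one_c	C=CC(=O)C	C
imine_one_c	C(=O)C=N	C
hydroquinone_c	Oc1ccc(O)cc1	C
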