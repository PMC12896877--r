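mirna	term_id	description	k	n	K	N	p_adjust_printed
novel73	GO:0007156	homophilic cell adhesion via plasma membrane adhesion molecules	18	90	172	21081	3.16e-17
csi-miR482e-3p	GO:0016936	galactoside binding	3	91	13	20616	6.98e-03
csi-miR482d-5p	GO:0048820	hair follicle maturation	3	92	16	21081	8.42e-03
novel85	GO:0014704	intercalated disc	4	91	51	21872	1.31e-02
csi-miR482e-3p	GO:0035739	CD4-positive, alpha-beta T cell proliferation	3	89	16	21081	1.61e-02
csi-miR390a-5p	GO:0031252	cell leading edge	9	96	449	21872	2.50e-02
csi-miR390a-5p	GO:0005925	focal adhesion	9	96	475	21872	2.50e-02
csi-miR390a-5p	GO:0030055	cell-substrate junction	9	96	483	21872	2.50e-02
csi-miR390a-5p	GO:0005901	caveola	4	96	92	21872	4.23e-02
csi-miR390a-5p	GO:0031256	leading edge membrane	5	96	187	21872	4.23e-02
novel90	GO:0032432	actin filament bundle	4	97	79	21872	4.60e-02
novel90	GO:0030027	lamellipodium	6	97	220	21872	4.60e-02
novel88	GO:0032526	response to retinoic acid	5	92	126	21081	4.71e-02
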