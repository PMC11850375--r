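term	type	canonical_id	source
idiopathic pulmonary fibrosis	DI	MESH:D054990	mesh
IPF	DI	MESH:D054990	mesh
pulmonary fibrosis	DI	MESH:D011658	mesh
emphysema	DI	MESH:D004646	mesh
COPD	DI	MESH:D029424	mesh
sarcoidosis	DI	MESH:D012507	mesh
pneumonia	DI	MESH:D011014	mesh
rheumatoid arthritis	DI	MESH:D001172	mesh
cough	DI	MESH:D003371	mesh
cough	SY	SYMP:0000614	symp
fatigue	SY	SYMP:0019177	symp
clubbing	SY	SYMP:0000572	symp
shortness of breath	SY	SYMP:0000013	symp
pirfenidone	DR	DRON:00018455	dron
nintedanib	DR	DRON:00073619	dron
prednisone	DR	DRON:00018635	dron
azathioprine	DR	DRON:00010619	dron
lung transplant	TR	WD:Q1074569	wikidata
oxygen therapy	TR	WD:Q1325510	wikidata
pulmonary rehabilitation	TR	WD:Q7259717	wikidata
application	TR	WD:Q166142	wikidata
group	TR	WD:Q16887380	wikidata
role	TR	WD:Q4897819	wikidata
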