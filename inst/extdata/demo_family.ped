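family_id	id	father_id	mother_id	sex	affected	age	carrier	proband
DEMO	1	0	0	1	2	72	C	0
DEMO	2	0	0	2	1	75	N	0
DEMO	3	1	2	2	2	48	C	1
DEMO	4	1	2	1	2	51	C	0
DEMO	5	1	2	2	1	46	N	0
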