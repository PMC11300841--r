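mondo_id	parent_mondo_id	mesh_id	umls_id
MONDO:0005027		D004827	C0014544
MONDO:0006680	MONDO:0005027	D004833	C0014556
MONDO:0005737	MONDO:0005027	D012640	C0036572
MONDO:0004975		D000544	C0002395
MONDO:0005180		D010300	C0030567
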