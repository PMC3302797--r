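accession_id	c01_s0001	c01_s0002	c01_s0003	c01_s0004	c01_s0005	c01_s0006	c01_s0007	c01_s0008	c01_s0009	c02_s0001	c02_s0002	c02_s0003	c02_s0004
G1_IRR_001	A	A	B	B	B	B	B	A	B	A	A	A	A
G1_IRR_002	A	A	B	A	A	A	B	B	A	A	A	A	A
G1_IRR_003	B	A	B	A	A	B	B	B	A	A	B	A	A
G1_IRR_004	N	A	A	A	A	B	A	B	A	B	A	A	A
G1_IRR_005	N	N	B	B	A	B	A	B	B	B	B	A	A
G1_NIR_001	B	A	B	B	A	A	A	A	B	A	B	A	A
G1_NIR_002	A	A	B	A	B	B	B	B	A	A	A	A	A
G2_IRR_001	A	B	B	B	B	B	B	B	A	A	A	B	A
G2_IRR_002	A	B	B	B	A	B	A	B	B	A	A	B	A
G2_IRR_003	A	B	B	B	B	B	B	A	B	B	B	B	A
G2_IRR_004	A	B	B	N	A	B	A	B	B	A	A	B	A
G3_IRR_001	A	B	B	B	B	B	B	A	B	B	B	B	A
G3_IRR_002	A	B	B	B	B	B	B	A	B	B	B	B	A
G3_IRR_003	A	B	B	B	B	B	B	A	B	B	B	B	A
G3_IRR_004	A	B	B	B	A	B	A	B	B	A	A	B	A
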