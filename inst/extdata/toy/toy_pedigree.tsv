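child	parent1	parent2	recurrent_parent
G2_IRR_001	G1_IRR_002	G1_IRR_001	G1_IRR_001
G2_IRR_002	G2_IRR_001	G1_IRR_005	
G2_IRR_003	G1_IRR_005	G1_IRR_001	G1_IRR_001
G2_IRR_004	G1_IRR_002	G2_IRR_002	
G3_IRR_001	G2_IRR_003	G2_IRR_004	
G3_IRR_002	G3_IRR_001	G2_IRR_003	
G3_IRR_003	G2_IRR_003	G3_IRR_002	G3_IRR_002
G3_IRR_004	G2_IRR_004	G2_IRR_003	
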