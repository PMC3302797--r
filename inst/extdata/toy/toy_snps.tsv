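snp_id	chromosome	position_bp	source_panel
c01_s0001	1	859400	koshihikari
c01_s0002	1	907881	koshihikari
c01_s0003	1	1126050	rikuu132
c01_s0004	1	1352894	koshihikari
c01_s0005	1	1421635	koshihikari
c01_s0006	1	1421718	koshihikari
c01_s0007	1	1593175	koshihikari
c01_s0008	1	1799356	eiko
c01_s0009	1	1982915	koshihikari
c02_s0001	2	252321	eiko
c02_s0002	2	834357	koshihikari
c02_s0003	2	1415311	koshihikari
c02_s0004	2	1486425	eiko
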