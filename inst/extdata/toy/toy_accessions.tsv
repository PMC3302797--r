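accession_id	group	water_regime	registration_year	region
G1_IRR_001	group1	irrigated	NA	NA
G1_IRR_002	group1	irrigated	NA	NA
G1_IRR_003	group1	irrigated	NA	NA
G1_IRR_004	group1	irrigated	NA	NA
G1_IRR_005	group1	irrigated	NA	NA
G1_NIR_001	group1	non_irrigated	NA	NA
G1_NIR_002	group1	non_irrigated	NA	NA
G2_IRR_001	group2	irrigated	1932	NA
G2_IRR_002	group2	irrigated	1943	NA
G2_IRR_003	group2	irrigated	1961	NA
G2_IRR_004	group2	irrigated	1974	NA
G3_IRR_001	group3	irrigated	1982	NA
G3_IRR_002	group3	irrigated	1990	NA
G3_IRR_003	group3	irrigated	1992	NA
G3_IRR_004	group3	irrigated	1994	NA
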