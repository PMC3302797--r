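{"novel_snps":[{"snp_id":"c02_s0003","year":1932,"accession":"G2_IRR_001"},{"snp_id":"c01_s0002","year":1932,"accession":"G2_IRR_001"},{"snp_id":"c01_s0002","year":1943,"accession":"G2_IRR_002"},{"snp_id":"c02_s0003","year":1961,"accession":"G2_IRR_003"},{"snp_id":"c01_s0002","year":1961,"accession":"G2_IRR_003"},{"snp_id":"c02_s0003","year":1974,"accession":"G2_IRR_004"}],"n_missing_applied":3,"n_het_applied":1,"seed":20260921}
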