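chr1	800000	1200000	cen1	centromere
chr1	999	250000	qtl_yield1	qtl
chr2	499	200000	qtl_quality2	qtl
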