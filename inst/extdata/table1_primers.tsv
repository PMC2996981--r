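# Splicing-test primers; expected_length and annealing_temp are informational.
# Two product lengths (434 and 494 bp) have been reported for the 3'-portion
# primer set; 494 is recorded here and the discrepancy is noted, not resolved.
region	name	sequence	role	expected_length	annealing_temp
5_portion	mt168-F	GGATTCTGTTTGTCCGCAGCATT	forward	233	50
5_portion	mt169-R	CACCATATAGCTATCTTTAGTTGA	reverse	233	50
3_portion	mt89-F	CAGTACCTGCCCAGTGCGACAA	forward	494	58
3_portion	16SBR	CCGGTCTGAACTCAGATCACGT	reverse	494	58
full_LSU	dCv-Ai-LSU-f	CTTTWGCAKMATGGCYTTWTGAG	forward	773	55
full_LSU	dCv-Ai-LSU-r	CACGGGGTCTTCTTGTCTWWCTTT	reverse	748	55
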