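# Published LSU rRNA fragment coordinates (GenBank-style 1-based inclusive)
# genome_length: total length of the GenBank record where recorded here
# (AY905542 = 17244 nt); NA where not recorded.  For C. gigas both reported
# 5' starts are listed (inferred gene start 5103; extreme transcript 5' 5117).
species	accession	frag5_start	frag5_end	frag3_start	frag3_end	genome_length
C_virginica	AY905542	8250	8997	1712	2430	17244
C_gigas	AF177226	5117	5703	17265	17977	NA
C_gigas_gene_start	AF177226	5103	5703	17265	17977	NA
C_hongkongensis	EU672834	7780	8384	1761	2472	NA
C_hongkongensis_yu	EU266073	NA	NA	1764	2475	NA
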