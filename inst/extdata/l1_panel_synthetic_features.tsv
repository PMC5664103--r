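family	feature	start	end
L1_consensus	5UTR	1	900
L1_consensus	ORF1	901	1917
L1_consensus	ORF2	1981	5808
L1_consensus	3UTR	5809	6000
L1HS_like	5UTR	1	900
L1HS_like	ORF1	901	1917
L1HS_like	ORF2	1981	5808
L1HS_like	3UTR	5809	6000
L1PA2_like	5UTR	1	900
L1PA2_like	ORF1	901	1917
L1PA2_like	ORF2	1981	5808
L1PA2_like	3UTR	5809	6000
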