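contig_id	L_ctrl	L_cd	H_ctrl	H_cd	annotation
contig13191	0.1	0.3	97.8	34.2	aquaporin pip1-2 (AT1G01620)
contig17660	0.3	0.2	148.0	65.1	aquaporin pip1-5 (AT4G00430)
contig17681	0.0	0.1	33.2	27.0	no hits - unknown
contig20402	0.1	0.0	62.1	58.1	no hits - unknown
contig35423	0.0	0.1	70.6	43.7	Ribosomal protein (AT1G33140)
contig3675	0.4	0.4	104.1	84.4	no hits - unknown
contig48835	4.4	4.4	62.9	103.4	no hits - unknown
contig5342	3.3	3.9	52.2	67.4	RNA ligase (AT4G18930)
contig1280	3.1	1.9	30.9	32.6	transcription elongation factor (AT1G32130)
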