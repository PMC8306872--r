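contig_id	L_ctrl	L_cd	fc_L	H_ctrl	H_cd	fc_H	agi_code	annotation
contig24852	0.7	246.9	356.6	23.8	103.0	4.3	AT2G20610	NAAT
contig7573	1.0	209.9	209.6	10.9	117.3	10.7	AT5G53970	NAAT
contig20039	3.2	462.9	145.4	49.6	287.9	5.8	AT5G53970	NAAT
contig40067	21.9	274.7	12.6	33.9	175.8	5.2	AT1G59960	DMAS
contig10233	11.4	253.8	22.3	22.9	139.9	6.1	AT1G59960	DMAS
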