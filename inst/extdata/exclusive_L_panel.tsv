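contig_id	L_ctrl	L_cd	H_ctrl	H_cd	annotation
contig19712	27.4	31.2	2.4	2.1	Cyclophilin (AT3G66654)
contig23984	76.5	49.8	0.1	0.1	no hits - unknown
contig5761	36.4	25.7	4.9	4.0	3-mercaptopyruvate sulfurtransferase (AT1G79230)
contig90107	57.1	30.7	0.0	0.0	no hits - unknown
contig9490	53.2	43.9	2.8	0.2	ABC transporter 3-like (AT1G64550)
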