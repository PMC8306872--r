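contig_id	L_ctrl	L_cd	fc_L	H_ctrl	H_cd	fc_H	agi_code	annotation
contig26634	7.8	604.5	77.1	24.3	240.7	9.9		NAS 1
contig55580	3.6	707.5	195.8	20.5	383.4	18.7		NAS 1
contig44671	5.4	774.2	143.6	49.4	437.2	8.8		NAS 2
contig18293	1.8	502.3	278.2	11.1	149.3	13.5	AT5G56080	NAS 2
contig18375	23.5	653.3	27.8	64.6	386.0	6.0	AT5G56080	NAS 2
contig18424	10.6	1178.3	111.5	41.5	522.9	12.6	AT1G09240	NAS 3
contig33892	1.1	623.2	572.5	10.0	262.0	26.3	AT1G09240	NAS 3
contig40805	9.8	629.4	64.2	55.9	348.5	6.2	AT1G09240	NAS 3
contig5670	1.1	179.2	158.9	5.2	23.2	4.5	AT1G09240	NAS 3
contig6866	7.6	663.0	87.8	51.9	281.9	5.4	AT1G09240	NAS 3
contig16879	0.8	155.6	204.0	5.2	68.2	13.0		NAS 4
contig36649	7.8	482.7	61.8	19.6	183.5	9.4		NAS 4
contig13016	2.1	391.5	186.2	30.2	114.6	3.8	AT1G56430	NAS 4
contig18348	2.4	626.8	264.5	25.2	257.9	10.2	AT1G56430	NAS 4
contig27606	7.4	321.2	43.7	31.3	106.5	3.4	AT1G56430	NAS 4
contig46013	7.5	1488.7	197.4	64.4	306.9	4.8	AT1G56430	NAS 4
contig51008	1.2	369.2	318.0	19.5	85.3	4.4	AT1G56430	NAS 4
contig5669	12.5	845.6	67.6	44.2	248.1	5.6	AT1G56430	NAS 4
contig56695	1.7	169.2	102.4	12.5	75.1	6.0	AT1G56430	NAS 4
contig62096	6.4	778.0	122.2	39.4	270.5	6.9	AT1G56430	NAS 4
contig6432	5.3	1071.6	200.7	81.6	218.6	2.7	AT1G56430	NAS 4
contig35044	10.3	691.1	67.3	49.2	419.8	8.5		NAS 5B
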