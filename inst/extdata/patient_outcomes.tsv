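patient_id	etiology	resection_area	followup_months	ilae	pre_max_rate	post_max_rate
1	DNET	L medial parietal	33	1	3	<1
2	FCD 2b	L dorsal medial prefrontal	24	1	10	<1
3	Sturge Weber	L lateral occipital	30	1	1	<1
4	Ganglioglioma	R post. fusiform gyrus (occipital)	18	1	12	<1
5	FCD 2a	R post. temporal	13	1	30	<1
6	Sturge Weber	R lateral post. temporal & lateral occipital	20	3	45	14
7	Astrocytoma	R post. middle frontal gyrus	29	1	1	<1
8	FCD 2a	R post. cingulate gyrus, post. hippocampus	12	1	2	<1
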