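retro_id	pattern	tissue
retro_hsap_2	ubiquitous
retro_hsap_4	ubiquitous
retro_hsap_36	ubiquitous
retro_hsap_57	ubiquitous
retro_hsap_64	ubiquitous
retro_hsap_75	ubiquitous
retro_hsap_100	ubiquitous
retro_hsap_105	ubiquitous
retro_hsap_108	ubiquitous
retro_hsap_217	ubiquitous
retro_hsap_774	ubiquitous
retro_hsap_901	ubiquitous
retro_hsap_1605	ubiquitous
retro_hsap_3990	ubiquitous
retro_hsap_1725	cancer_only
retro_hsap_1817	cancer_only
retro_hsap_2646	cancer_only
retro_hsap_912	tissue_specific	fetal brain
retro_hsap_913	tissue_specific	fetal brain
retro_hsap_1813	tissue_specific	fetal brain
retro_hsap_1883	tissue_specific	fetal brain
retro_hsap_2045	tissue_specific	fetal brain
retro_hsap_316	tissue_specific	heart and aorta
retro_hsap_3488	tissue_specific	heart and aorta
retro_hsap_623	tissue_specific	liver
retro_hsap_4127	tissue_specific	liver
retro_hsap_3266	tissue_specific	lung
retro_hsap_4877	tissue_specific	lung
retro_hsap_2759	tissue_specific	omental fat pad
retro_hsap_25	tissue_specific	peyers patch
retro_hsap_101	tissue_specific	prostate gland
retro_hsap_743	tissue_specific	prostate gland
retro_hsap_770	tissue_specific	prostate gland
retro_hsap_2122	tissue_specific	prostate gland
retro_hsap_4833	tissue_specific	prostate gland
retro_hsap_178	tissue_specific	skin
retro_hsap_734	tissue_specific	skin
retro_hsap_1483	tissue_specific	skin
retro_hsap_1713	tissue_specific	skin
retro_hsap_2147	tissue_specific	skin
retro_hsap_2266	tissue_specific	skin
retro_hsap_3080	tissue_specific	skin
retro_hsap_3112	tissue_specific	skin
retro_hsap_241	tissue_specific	spleen
retro_hsap_396	tissue_specific	spleen
retro_hsap_671	tissue_specific	spleen
retro_hsap_877	tissue_specific	spleen
retro_hsap_1801	tissue_specific	spleen
retro_hsap_2073	tissue_specific	spleen
retro_hsap_2092	tissue_specific	spleen
retro_hsap_2576	tissue_specific	spleen
retro_hsap_2666	tissue_specific	spleen
retro_hsap_2799	tissue_specific	spleen
retro_hsap_3524	tissue_specific	spleen
retro_hsap_3613	tissue_specific	spleen
retro_hsap_3678	tissue_specific	spleen
retro_hsap_3917	tissue_specific	spleen
retro_hsap_4800	tissue_specific	tibial nerve
retro_hsap_2044	tissue_specific	transverse colon
retro_hsap_4063	tissue_specific	transverse colon
retro_hsap_4139	tissue_specific	uterus
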