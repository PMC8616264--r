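region	size_bp	coefficient	gene	location	cancer_type
chr2:29337984-29338909	926	-9.83	CLIP4	Promoter	colorectal
chr2:100937780-100939059	1280	-29.19	LONRF2	Promoter	colorectal
chr6:125283125-125284389	1265	7.04	RNF217	Promoter	colorectal
chr2:66672432-66673636	1205	-9.04	MEIS1	Gene body	lung
chr2:71503548-71504233	686	-5.54	ZNF638	Promoter	lung
chr2:219736133-219736592	460	5.80	WNT6	Gene body	lung
chr4:140655963-140657135	1173	13.48	MGST2	Gene body	lung
chr4:174427892-174428192	301	7.82	NA	Intergenic	lung
chr5:40679503-40682081	2579	-43.06	PTGER4	Promoter	lung
chr7:27265159-27265493	335	-7.47	NA	Intergenic	lung
chr7:65037625-65037864	240	-14.04	NA	Intergenic	lung
chr8:124172801-124173541	741	-14.47	NA	Intergenic	lung
chr9:96108467-96108992	526	12.82	C9orf129	Promoter	lung
chr12:54408427-54408713	287	-5.11	NA	Intergenic	lung
chr12:58021295-58022037	743	15.82	B4GALNT1	Gene body	lung
chr13:28549840-28550246	407	5.60	NA	Intergenic	lung
chr17:46691521-46692097	577	-4.75	HOXB8	Gene body	lung
chr17:59539363-59539834	472	-12.18	TBX4	Gene body	lung
chr17:70112825-70114271	1447	9.87	SOX9	Promoter	lung
chr1:44883137-44884272	1136	-10.54	RNF220	Gene body	pancreatic
chr1:50798668-50799536	869	8.22	NA	Intergenic	pancreatic
chr5:92939796-92940216	421	7.85	NA	Intergenic	pancreatic
chr10:11059443-11060524	1082	10.34	CELF2	Promoter	pancreatic
chr11:20177609-20178824	1216	6.63	DBX1	Gene body	pancreatic
chr12:114881650-114881937	288	-27.52	NA	Intergenic	pancreatic
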