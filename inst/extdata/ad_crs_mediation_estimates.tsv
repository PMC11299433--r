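exposure	mediator	outcome	beta_total	ci_total_low	ci_total_high	beta1	ci1_low	ci1_high	beta2	ci2_low	ci2_high
multiple_sclerosis	IL-10	chronic_rhinosinusitis	0.0357	0.0069	0.0647	-0.0301	-0.0506	-0.0096	0.1383	0.0347	0.2419
rheumatoid_arthritis	IL-10	chronic_rhinosinusitis	0.0458	0.0052	0.0864	0.0355	0.0141	0.0569	0.1383	0.0347	0.2419
hypothyroidism	IL-10	chronic_rhinosinusitis	0.0679	0.0191	0.1167	0.0515	0.0230	0.0799	0.1383	0.0347	0.2419
hypothyroidism	CXCL10	chronic_rhinosinusitis	0.0679	0.0191	0.1167	0.0466	0.0172	0.0760	0.1788	0.0618	0.2958
hypothyroidism	CD6	chronic_rhinosinusitis	0.0679	0.0191	0.1167	0.0304	0.0001	0.0607	0.1472	0.0329	0.2616
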