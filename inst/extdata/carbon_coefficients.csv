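source,factor,unit,to_1e4t,provenance
fertilizer,0.8956,kg C per kg applied (quantity in 1e4 t),1,West & Marland lineage; standard value in the agricultural carbon accounting literature. Replaceable default.
pesticide,4.9341,kg C per kg used (quantity in t),1e-4,Standard literature value (pesticide production and use). Replaceable default.
film,5.18,kg C per kg used (quantity in t),1e-4,Standard literature value (agricultural plastic film). Replaceable default.
diesel,0.5927,kg C per kg burned (quantity in 1e4 t),1,IPCC-derived diesel combustion factor; standard in this literature. Replaceable default.
plowing,312.6,kg C per km2 plowed (quantity in thousand ha = 10 km2),1e-6,Standard tillage disturbance factor; conversion = 10 km2 per thousand ha x 1e-7 (kg to 1e4 t). Replaceable default.
irrigation,20.476,kg C per ha irrigated (quantity in thousand ha),1e-4,Standard electricity-for-irrigation factor; conversion = 1000 ha per thousand ha x 1e-7 (kg to 1e4 t). Replaceable default.
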