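sample_id	site_name	biome	location
CAM_S001	Baltic station 12	sea water	Sweden
CAM_S002	North Atlantic transect	water	Reykjavik
CAM_S003	Estuary mudflat	soil	Plymouth
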