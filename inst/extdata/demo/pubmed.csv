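pmid,title,abstract
100001,Microbial diversity of kefir grains,"We characterized Leuconostoc strains from kefir, a fermented dairy product, sampled in Stockholm, Sweden."
100002,Soil bacterial communities of boreal forests,"Soil and forest soil samples collected across Norway were profiled for Bacteria and Archaea."
100003,Starter cultures for cheese ripening,"Starter cultures for cheese were isolated from raw milk collected at a creamery in Ghent."
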