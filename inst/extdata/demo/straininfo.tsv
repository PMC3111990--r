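accession	organism	habitat	location
LMG:101	Lactococcus lactis	raw milk	Ghent
LMG:102	Penicillium commune	cheese rind	Paris
LMG:103	Bacillus subtilis	soil	Kiel
LMG:104	Leuconostoc mesenteroides	kefir	Stockholm
LMG:105	Streptococcus thermophilus	milk	Zurich
LMG:106	Pseudomonas fluorescens	forest soil	Bergen
LMG:107	Vibrio alginolyticus	sea water	Plymouth
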