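gold_id	project_name	habitat	geography
Gp0001	Fjord sediment survey	soil	Norway
Gp0002	Creamery starter genome	milk	Ghent
Gp0003	Alpine meadow metagenome	forest soil	Innsbruck
Gp0004	Harbour water sampling	sea water	Plymouth
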