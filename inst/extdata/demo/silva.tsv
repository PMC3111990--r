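accession	organism	isolation_source	body_site
AB00001	Leuconostoc pseudomesenteroides	fermented dairy product	none
AB00002	Bacillus subtilis	soil	none
AB00003	Helicobacter pylori	clinical isolate	epithelium
AB00004	Archaea incertae sedis	sea water	none
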