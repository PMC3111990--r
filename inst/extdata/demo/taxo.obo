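format-version: 1.2
ontology: demo/taxo
remark: miniature species taxonomy for the demo instance (synthetic)

[Term]
id: TAXO:0000001
name: cellular organisms

[Term]
id: TAXO:0000002
name: Bacteria
is_a: TAXO:0000001 ! cellular organisms

[Term]
id: TAXO:0000003
name: Archaea
is_a: TAXO:0000001 ! cellular organisms

[Term]
id: TAXO:0000004
name: Firmicutes
is_a: TAXO:0000002 ! Bacteria

[Term]
id: TAXO:0000005
name: Leuconostoc
is_a: TAXO:0000004 ! Firmicutes
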