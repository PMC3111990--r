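format-version: 1.2
ontology: demo/envo
remark: miniature environment ontology for the demo instance (synthetic)

[Term]
id: ENVO:0000001
name: environmental material

[Term]
id: ENVO:0000002
name: dairy product
is_a: ENVO:0000001 ! environmental material

[Term]
id: ENVO:0000003
name: cheese
is_a: ENVO:0000002 ! dairy product

[Term]
id: ENVO:0000004
name: milk
synonym: "cow milk" EXACT []
is_a: ENVO:0000002 ! dairy product

[Term]
id: ENVO:0000005
name: fermented dairy product
is_a: ENVO:0000002 ! dairy product

[Term]
id: ENVO:0000006
name: kefir
is_a: ENVO:0000005 ! fermented dairy product

[Term]
id: ENVO:0000007
name: soil
is_a: ENVO:0000001 ! environmental material

[Term]
id: ENVO:0000008
name: forest soil
is_a: ENVO:0000007 ! soil

[Term]
id: ENVO:0000009
name: water
synonym: "aqueous environment" RELATED []
is_a: ENVO:0000001 ! environmental material
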