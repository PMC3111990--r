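format-version: 1.2
ontology: demo/gaz
remark: miniature gazetteer for the demo instance (synthetic); geographic containment encoded as is_a parent edges

[Term]
id: GAZ:0000001
name: Earth

[Term]
id: GAZ:0000002
name: Europe
is_a: GAZ:0000001 ! Earth

[Term]
id: GAZ:0000003
name: Scandinavian Peninsula
is_a: GAZ:0000002 ! Europe

[Term]
id: GAZ:0000004
name: Sweden
is_a: GAZ:0000003 ! Scandinavian Peninsula

[Term]
id: GAZ:0000005
name: Norway
is_a: GAZ:0000003 ! Scandinavian Peninsula

[Term]
id: GAZ:0000006
name: Stockholm
is_a: GAZ:0000004 ! Sweden
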