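format-version: 1.2
ontology: demo/anat
remark: miniature anatomy facet for the demo instance (synthetic placeholder branch)

[Term]
id: ANAT:0000001
name: anatomical structure

[Term]
id: ANAT:0000002
name: organ
is_a: ANAT:0000001 ! anatomical structure

[Term]
id: ANAT:0000003
name: liver
is_a: ANAT:0000002 ! organ

[Term]
id: ANAT:0000004
name: tissue
is_a: ANAT:0000001 ! anatomical structure

[Term]
id: ANAT:0000005
name: epithelium
is_a: ANAT:0000004 ! tissue
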