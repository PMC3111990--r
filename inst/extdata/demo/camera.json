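{
  "source_id": "camera",
  "display_name": "Marine metagenome samples",
  "file": "camera.tsv",
  "delimiter": "\t",
  "key_columns": ["sample_id"],
  "scan_map": {
    "biome": ["envo"],
    "location": ["gaz"]
  },
  "url_template": "https://example.org/camera/{sample_id}"
}
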