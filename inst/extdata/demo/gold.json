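{
  "source_id": "gold",
  "display_name": "Genome project catalogue",
  "file": "gold.tsv",
  "delimiter": "\t",
  "key_columns": ["gold_id"],
  "scan_map": {
    "habitat": ["envo"],
    "geography": ["gaz"]
  },
  "url_template": "https://example.org/gold/{gold_id}"
}
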