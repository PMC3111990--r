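{
  "source_id": "straininfo",
  "display_name": "Strain collection",
  "file": "straininfo.tsv",
  "delimiter": "\t",
  "key_columns": ["accession"],
  "scan_map": {
    "organism": ["taxo"],
    "habitat": ["envo"],
    "location": ["gaz"]
  },
  "url_template": "https://example.org/strain/{accession}"
}
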