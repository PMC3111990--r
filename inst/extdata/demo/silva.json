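{
  "source_id": "silva",
  "display_name": "rRNA sequence database",
  "file": "silva.tsv",
  "delimiter": "\t",
  "key_columns": ["accession"],
  "scan_map": {
    "organism": ["taxo"],
    "isolation_source": ["envo"],
    "body_site": ["anat"]
  },
  "url_template": "https://example.org/silva/{accession}"
}
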