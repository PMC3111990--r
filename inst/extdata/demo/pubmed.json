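{
  "source_id": "pubmed",
  "display_name": "Literature abstracts",
  "file": "pubmed.csv",
  "delimiter": ",",
  "key_columns": ["pmid"],
  "scan_map": {
    "title": ["envo", "gaz", "taxo"],
    "abstract": ["envo", "gaz", "taxo"]
  },
  "url_template": "https://example.org/pubmed/{pmid}"
}
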