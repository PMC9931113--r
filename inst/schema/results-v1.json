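{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "intlik/results-v1",
  "title": "intlik results artefact",
  "type": "object",
  "required": ["schema", "package_version", "seed", "results"],
  "properties": {
    "schema": {"const": "intlik/results-v1"},
    "package_version": {"type": "string"},
    "seed": {"type": "integer"},
    "config": {"type": "object"},
    "results": {}
  }
}
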