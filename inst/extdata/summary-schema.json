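{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "polyconform run summary",
  "type": "object",
  "required": ["classification", "final", "config", "package_version"],
  "properties": {
    "classification": {
      "type": "string",
      "enum": ["fixed_point", "cycle", "nonconvergent", "unclassified"]
    },
    "period": {"type": ["integer", "null"]},
    "cycle_points": {
      "type": ["array", "null"],
      "items": {"type": "array", "items": {"type": "number"}}
    },
    "final": {"type": "array", "items": {"type": "number"}},
    "ergodic_mean": {
      "type": ["array", "null"],
      "items": {"type": "number"}
    },
    "config": {
      "type": "object",
      "required": ["n", "m", "scheme", "p0", "generations"],
      "properties": {
        "n": {"type": "integer"},
        "m": {"type": "integer"},
        "scheme": {"type": "object"},
        "p0": {"type": "array", "items": {"type": "number"}},
        "generations": {"type": "integer"},
        "seed": {"type": ["integer", "null"]}
      }
    },
    "package_version": {"type": "string"}
  }
}
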